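#' Actuator profile of the oscillatory shaking platform
#'
#' Motion parameters of the motor-driven elliptical-cam platform: a brushless
#' DC motor (rated 43,200 rpm) driven in velocity-control mode at a target
#' speed of 8000 rpm through a 103:1 gear reduction, ramping at
#' 523.6 rad/s^2 so the target is reached in 1.6 s. The elliptical cam
#' (major axis 15 mm, minor 10 mm) converts cam rotation into vertical
#' platform oscillation.
#'
#' @param motor_rated_rpm rated motor speed (rpm).
#' @param target_rpm commanded motor speed (rpm; must not exceed rated).
#' @param gear_ratio gear reduction ratio (> 0).
#' @param accel_rad_s2 motor acceleration (rad/s^2).
#' @param accel_time_s nominal time to reach target speed (s); must be
#'   consistent with `accel_rad_s2` within 1 %.
#' @param cam_major_mm,cam_minor_mm elliptical cam axis lengths (mm).
#' @param displacement_reported_mm the platform peak-to-peak displacement as
#'   reported by the hardware characterization (see [cam_kinematics()] for
#'   why this is kept separately from the cam-geometry value).
#' @return object of class `remloop_profile`.
#' @export
actuator_profile <- function(motor_rated_rpm = 43200,
                             target_rpm = 8000,
                             gear_ratio = 103,
                             accel_rad_s2 = 523.6,
                             accel_time_s = 1.6,
                             cam_major_mm = 15,
                             cam_minor_mm = 10,
                             displacement_reported_mm = 10) {
  if (target_rpm > motor_rated_rpm) rlang::abort("target speed exceeds rated speed")
  if (gear_ratio <= 0) rlang::abort("gear_ratio must be > 0")
  target_rad_s <- target_rpm * 2 * pi / 60
  if (abs(accel_time_s * accel_rad_s2 - target_rad_s) / target_rad_s > 0.01) {
    rlang::abort("accel_time_s * accel_rad_s2 must equal the target speed in rad/s (+/- 1 %)")
  }
  structure(
    list(motor_rated_rpm = motor_rated_rpm, target_rpm = target_rpm,
         gear_ratio = gear_ratio, accel_rad_s2 = accel_rad_s2,
         accel_time_s = accel_time_s, cam_major_mm = cam_major_mm,
         cam_minor_mm = cam_minor_mm,
         displacement_reported_mm = displacement_reported_mm),
    class = "remloop_profile"
  )
}

#' Kinematic summary of the actuation subsystem
#'
#' Derived quantities of the motion profile: cam rotational speed
#' (`target_rpm / gear_ratio`), platform oscillation frequency (one
#' oscillation per cam revolution, so `cam_rpm / 60` Hz), peak-to-peak
#' displacement from the cam geometry (`cam_major - cam_minor`), and the
#' motor acceleration implied by the ramp (`target speed in rad/s /
#' accel_time`).
#'
#' The geometric displacement (5 mm for the 15/10 mm cam) and the reported
#' hardware characterization (10 mm) disagree — as does one-vs-two
#' oscillations per revolution for a symmetric ellipse. Both displacement
#' values are therefore reported side by side rather than silently
#' reconciled.
#'
#' @param profile an [actuator_profile()].
#' @return one-row tibble: `cam_speed_rpm`, `oscillation_hz`,
#'   `displacement_pp_mm` (cam geometry), `displacement_reported_mm`,
#'   `accel_rad_s2`.
#' @examples
#' cam_kinematics(actuator_profile())
#' @export
cam_kinematics <- function(profile = actuator_profile()) {
  stopifnot(inherits(profile, "remloop_profile"))
  cam_rpm <- profile$target_rpm / profile$gear_ratio
  tibble::tibble(
    cam_speed_rpm = cam_rpm,
    oscillation_hz = cam_rpm / 60,
    displacement_pp_mm = profile$cam_major_mm - profile$cam_minor_mm,
    displacement_reported_mm = profile$displacement_reported_mm,
    accel_rad_s2 = (profile$target_rpm * 2 * pi / 60) / profile$accel_time_s
  )
}

#' Actuator state machine
#'
#' The simulated servo drive: a high TTL trigger from idle starts a linear
#' velocity ramp at the profile's acceleration (mode `accelerating`) until
#' the target speed is reached (mode `running`); when the trigger returns to
#' low, motor output ceases within one control cycle (speed 0, mode `idle`).
#' Mode transitions follow idle -> accelerating -> running -> idle only.
#'
#' @param mode one of `"idle"`, `"accelerating"`, `"running"`.
#' @param speed_rpm current motor speed.
#' @param trigger TTL level, `"low"` or `"high"`.
#' @param since time (s) the current mode was entered.
#' @return list of class `remloop_actuator`.
#' @export
actuator_state <- function(mode = "idle", speed_rpm = 0, trigger = "low",
                           since = 0) {
  mode <- match.arg(mode, c("idle", "accelerating", "running"))
  trigger <- match.arg(trigger, c("low", "high"))
  structure(list(mode = mode, speed_rpm = speed_rpm, trigger = trigger,
                 since = since),
            class = "remloop_actuator")
}

#' @rdname actuator_state
#' @param state a `remloop_actuator`.
#' @param trigger TTL level commanded this cycle (`"low"`/`"high"`).
#' @param dt control interval in seconds.
#' @param profile an [actuator_profile()].
#' @param now current time in seconds (for the `since` bookkeeping).
#' @return `update_actuator()` returns the advanced `remloop_actuator`.
#' @examples
#' a <- actuator_state()
#' for (i in 1:16) a <- update_actuator(a, "high", now = i * 0.1)
#' a$mode; a$speed_rpm
#' @export
update_actuator <- function(state, trigger, dt = 0.1,
                            profile = actuator_profile(), now = state$since + dt) {
  stopifnot(inherits(state, "remloop_actuator"))
  trigger <- match.arg(trigger, c("low", "high"))
  if (trigger == "low") {
    mode <- "idle"
    speed <- 0
    since <- if (state$mode == "idle") state$since else now
  } else {
    ramp_rpm_per_s <- profile$accel_rad_s2 * 60 / (2 * pi)
    speed <- min(state$speed_rpm + ramp_rpm_per_s * dt, profile$target_rpm)
    if (speed >= profile$target_rpm) {
      mode <- "running"
      since <- if (state$mode == "running") state$since else now
    } else {
      mode <- "accelerating"
      since <- if (state$mode == "accelerating") state$since else now
    }
  }
  actuator_state(mode, speed, trigger, since)
}
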