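test_that("cam kinematics reproduce the actuation design constants", {
  k <- cam_kinematics(actuator_profile())
  expect_equal(k$cam_speed_rpm, 8000 / 103)
  expect_lt(abs(k$cam_speed_rpm - 77.7), 0.05)      # printed value
  expect_lt(abs(k$oscillation_hz - 1.3), 0.05)
  expect_lt(abs(k$accel_rad_s2 - 523.6), 0.5)
  expect_equal(k$displacement_pp_mm, 5)             # cam geometry: 15 - 10 mm
  expect_equal(k$displacement_reported_mm, 10)      # reported characterization
})

test_that("actuator profile invariants are enforced", {
  expect_error(actuator_profile(target_rpm = 50000), "rated")
  expect_error(actuator_profile(accel_time_s = 2.5), "1 %")
  expect_error(actuator_profile(gear_ratio = 0), "gear_ratio")
})

test_that("the actuator ramps linearly to target and stops within one cycle", {
  p <- actuator_profile()
  a <- actuator_state()
  modes <- character(0)
  for (i in 1:16) {
    a <- update_actuator(a, "high", dt = 0.1, profile = p, now = i * 0.1)
    modes <- c(modes, a$mode)
  }
  expect_equal(a$mode, "running")
  expect_equal(a$speed_rpm, 8000)
  expect_true(all(modes[1:15] == "accelerating"))   # idle -> accelerating -> running

  half <- actuator_state()
  for (i in 1:8) half <- update_actuator(half, "high", dt = 0.1, profile = p)
  expect_lt(abs(half$speed_rpm - 4000) / 4000, 0.01)  # linear ramp closed form

  a <- update_actuator(a, "low", dt = 0.1, profile = p)
  expect_equal(a$mode, "idle")
  expect_equal(a$speed_rpm, 0)
})

test_that("self check passes on a valid configuration with a ~5 s actuation burst", {
  chk <- self_check(default_animal_model())
  expect_true(attr(chk, "passed"))
  ev <- attr(chk, "events")
  expect_equal(ev$event, c("TRIGGER_HIGH", "TRIGGER_LOW"))
  expect_equal(diff(ev$time_s), 5, tolerance = 0.05)
})

test_that("self check fails on a dead signal source or a stuck actuator", {
  dead <- tone_model(amp = 0)
  dead$emg_rms[] <- 0
  chk <- self_check(dead)
  expect_false(chk$pass[chk$check == "data_stream"])
  expect_false(attr(chk, "passed"))

  stuck <- function(state, trigger, dt, profile, now) actuator_state()  # never moves
  chk2 <- self_check(default_animal_model(), actuator_update = stuck)
  expect_false(chk2$pass[chk2$check == "trigger_path"])
  expect_error(
    run_control_loop(tone_model(amp = 0), cached_baseline()$thresholds, 60),
    "refused"
  )
})

test_that("a REM-free plant never raises the trigger", {
  m <- default_animal_model()
  m$transition_matrix <- matrix(c(
    0, 1, 0,
    0, 0.98, 0.02,
    0, 0.02, 0.98), 3, 3, byrow = TRUE,
    dimnames = list(vigilance_states(), vigilance_states()))
  sess <- run_control_loop(m, cached_baseline()$thresholds, 600, seed = 4,
                           run_self_check = FALSE)
  expect_true(all(sess$cycles$plant_state != "REM"))
  expect_true(all(sess$cycles$trigger == "low"))
  expect_equal(nrow(sess$events[sess$events$event == "TRIGGER_HIGH", ]), 0)
})

test_that("TTL semantics: trigger is high during exactly the REM-decided cycles", {
  fx <- cached_baseline()
  sess <- run_control_loop(fx$model, fx$thresholds, 900, seed = 6,
                           run_self_check = FALSE)
  expect_identical(sess$cycles$trigger == "high",
                   sess$cycles$decision == "REM" & !sess$cycles$flag)
  # warmup: first 5 s flagged Wake, trigger low
  warm <- sess$cycles[sess$cycles$time_s < 5, ]
  expect_true(all(warm$flag))
  expect_true(all(warm$decision == "Wake"))
  expect_true(all(warm$trigger == "low"))
  # cycle spacing exactly 100 ms, monotone timestamps
  expect_equal(diff(sess$cycles$time_s), rep(0.1, nrow(sess$cycles) - 1))
})

test_that("sessions are deterministic given the seed", {
  fx <- cached_baseline()
  s1 <- run_control_loop(fx$model, fx$thresholds, 300, seed = 12, run_self_check = FALSE)
  s2 <- run_control_loop(fx$model, fx$thresholds, 300, seed = 12, run_self_check = FALSE)
  expect_identical(s1$cycles, s2$cycles)
})

test_that("with arousal_prob = 0 the plant follows the unstimulated chain exactly", {
  fx <- cached_baseline()
  sess <- run_control_loop(fx$model, fx$thresholds, 1200, seed = 31,
                           arousal_prob = 0, run_self_check = FALSE)
  h <- generate_hypnogram(fx$model, 1200, seed = 31)
  expect_identical(as.character(sess$epochs$truth), as.character(h$state))
})

test_that("certain arousal terminates every REM bout within an epoch of the trigger", {
  fx <- cached_baseline()
  m <- fx$model
  m$arousal_prob <- 1
  sess <- run_control_loop(m, fx$thresholds, 2700, seed = 21, run_self_check = FALSE)
  ups <- sess$events$time_s[sess$events$event == "TRIGGER_HIGH"]
  expect_gt(length(ups), 0)
  for (t0 in ups) {
    after <- sess$cycles[sess$cycles$time_s > t0 & sess$cycles$time_s <= t0 + 2.5, ]
    expect_true(any(after$plant_state != "REM"))  # bout ends within one epoch
  }
  occ <- occupancy(sess$epochs$truth)
  expect_lt(occ$pct[occ$state == "REM"], 1.5)
})

test_that("REM occupancy under closed loop is monotone in arousal probability", {
  fx <- cached_baseline()
  rem_occ <- function(p, seed) {
    s <- run_control_loop(fx$model, fx$thresholds, 2700, seed = seed,
                          arousal_prob = p, run_self_check = FALSE)
    o <- occupancy(s$epochs$truth)
    o$pct[o$state == "REM"]
  }
  occs <- sapply(c(0, 0.15, 1), function(p) mean(c(rem_occ(p, 51), rem_occ(p, 52))))
  # allow a small Monte-Carlo slack between the two stimulated levels
  expect_gt(occs[1], occs[2])
  expect_lte(occs[3], occs[2] + 0.3)
})

test_that("declining arousal efficacy (REM pressure) attenuates suppression over time", {
  fx <- cached_baseline()
  run <- function(decline) {
    run_control_loop(fx$model, fx$thresholds, 3600, seed = 61,
                     arousal_prob = 0.4, arousal_decline_per_h = decline,
                     run_self_check = FALSE)
  }
  occ_rem <- function(s) {
    o <- occupancy(s$epochs$truth)
    o$pct[o$state == "REM"]
  }
  s_flat <- run(0)
  s_decl <- run(20)   # efficacy quickly pinned at its 10 % floor
  expect_gte(occ_rem(s_decl), occ_rem(s_flat))
  # still suppressed relative to the chain's 7 % stationary occupancy
  expect_lt(occ_rem(s_decl), 5)
})

test_that("termination conditions bound the session and are logged", {
  fx <- cached_baseline()
  s <- run_control_loop(fx$model, fx$thresholds, 1800, seed = 73,
                        arousal_prob = 0, max_rem_s = 10, run_self_check = FALSE)
  expect_equal(s$termination, "rem_cap")
  expect_lt(nrow(s$cycles), 18000)

  s2 <- run_control_loop(fx$model, fx$thresholds, 300, seed = 72,
                         max_rem_s = 1e6, run_self_check = FALSE)
  expect_equal(s2$termination, "max_duration")
  expect_true("WARN_TERMINATION_NOT_REACHED" %in% s2$events$event)
})
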