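#' Pre-run self check
#'
#' Before closed-loop entry the system verifies itself: (i) the signal
#' source yields non-constant samples, (ii) the feature pipeline returns
#' finite values on a test window, and (iii) a ~5 s simulated actuation
#' burst toggles the actuator through its full trigger path (idle ->
#' accelerating -> running -> idle). Any failure refuses closed-loop entry.
#'
#' @param model a `remloop_model` (the signal source under test).
#' @param profile an [actuator_profile()].
#' @param seed integer seed for the test signal.
#' @param burst_s duration of the actuation test burst in seconds.
#' @param step_s control interval in seconds.
#' @param actuator_update the actuator transition function; replaceable so a
#'   faulty drive can be simulated.
#' @return tibble of class `remloop_check` (`check`, `pass`, `detail`);
#'   attributes `passed` (overall) and `events` (the actuation-test TTL log).
#' @export
self_check <- function(model, profile = actuator_profile(), seed = 1L,
                       burst_s = 5, step_s = 0.1,
                       actuator_update = update_actuator) {
  # (i) + (ii): 5 s of signal from the most common state, then features
  h <- hypnogram(rep("NREM", 2), epoch_s = 2.5)
  sig <- synthesize_signals(h, model, seed = seed)
  x <- as.numeric(sig$eeg)[1:5000]
  stream_ok <- stats::sd(x) > 0
  feat_ok <- FALSE
  feat_detail <- "skipped: constant signal"
  if (stream_ok) {
    f <- extract_features(compute_psd(x))
    feat_ok <- is.finite(f$r_theta_delta) && is.finite(f$r_hf) && !f$undefined
    feat_detail <- sprintf("r_theta_delta = %.3g, r_hf = %.3g", f$r_theta_delta, f$r_hf)
  }
  # (iii): trigger path through a ~5 s burst
  n_burst <- round(burst_s / step_s)
  a <- actuator_state()
  events <- list(tibble::tibble(time_s = 0, event = "TRIGGER_HIGH"))
  left_idle <- FALSE
  reached_running <- FALSE
  for (k in seq_len(n_burst)) {
    a <- actuator_update(a, "high", dt = step_s, profile = profile, now = k * step_s)
    if (a$mode != "idle") left_idle <- TRUE
    if (a$mode == "running") reached_running <- TRUE
  }
  a <- actuator_update(a, "low", dt = step_s, profile = profile,
                       now = (n_burst + 1) * step_s)
  events <- c(events, list(tibble::tibble(time_s = n_burst * step_s,
                                          event = "TRIGGER_LOW")))
  returned_idle <- a$mode == "idle" && a$speed_rpm == 0
  trig_ok <- left_idle && reached_running && returned_idle

  out <- tibble::tibble(
    check = c("data_stream", "feature_pipeline", "trigger_path"),
    pass = c(stream_ok, feat_ok, trig_ok),
    detail = c(
      sprintf("signal SD = %.3g mV over %g s", stats::sd(x), burst_s),
      feat_detail,
      sprintf("left idle: %s; reached running: %s; returned idle: %s",
              left_idle, reached_running, returned_idle)
    )
  )
  attr(out, "passed") <- all(out$pass)
  attr(out, "events") <- dplyr::bind_rows(events)
  class(out) <- c("remloop_check", class(out))
  out
}

#' Run a simulated closed-loop REM deprivation session
#'
#' The fixed-interval control engine against the virtual-mouse plant, one
#' 100 ms cycle at a time in simulated time: plant step (Markov transitions
#' at 2.5 s epoch boundaries; stimulation-induced arousal every cycle) ->
#' synthesis of the next 100 EEG/EMG samples (with motion artifact while the
#' platform moves) -> sliding-window update -> PSD -> features -> threshold
#' classification -> TTL trigger high iff the decision is REM -> actuator
#' update. The first 5 s (partial window) are emitted as flagged Wake
#' decisions with the trigger held low.
#'
#' The plant's Markov transitions consume a dedicated uniform stream drawn
#' from `seed`, identical to [generate_hypnogram()]'s: with
#' `arousal_prob = 0` the plant trajectory equals the unstimulated hypnogram
#' for the same seed, epoch for epoch.
#'
#' @param model a `remloop_model`.
#' @param thresholds calibrated `remloop_thresholds` for this animal.
#' @param duration_s session length in seconds (truncated to whole epochs).
#' @param seed integer seed.
#' @param profile an [actuator_profile()].
#' @param fs,window_s,step_s,epoch_s,n_fft,bands acquisition and analysis
#'   parameters (defaults are the system's design constants).
#' @param arousal_prob override of `model$arousal_prob`.
#' @param arousal_decline_per_h optional linear decline of the arousal
#'   probability with elapsed time (fraction per hour, floor 10 % of the
#'   initial value), emulating rising REM pressure during prolonged
#'   deprivation; 0 disables it.
#' @param max_rem_s optional termination condition: stop once cumulative
#'   plant REM time reaches this many seconds. Sessions are always bounded
#'   by `duration_s`; if the cap is set but never reached a warning event is
#'   logged.
#' @param run_self_check run [self_check()] first and refuse to start on
#'   failure.
#' @return object of class `remloop_session`: list with `cycles` (per-cycle
#'   tibble: time, features, decision, flag, trigger, actuator mode/speed,
#'   plant state), `epochs` (per-epoch predicted vs plant-truth labels),
#'   `events`, `config`, `termination`, `clipped`.
#' @examples
#' \donttest{
#' m <- default_animal_model()
#' h <- generate_hypnogram(m, 1800, seed = 2)
#' sig <- synthesize_signals(h, m, seed = 2)
#' th <- calibrate_animal(sig$eeg, h, "demo")
#' sess <- run_control_loop(m, th, duration_s = 600, seed = 3)
#' glance(sess)
#' }
#' @export
run_control_loop <- function(model, thresholds, duration_s, seed = 1L,
                             profile = actuator_profile(),
                             fs = 1000, window_s = 5, step_s = 0.1,
                             epoch_s = 2.5, n_fft = 10000,
                             bands = default_bands(),
                             arousal_prob = model$arousal_prob,
                             arousal_decline_per_h = 0,
                             max_rem_s = Inf,
                             run_self_check = TRUE) {
  stopifnot(inherits(model, "remloop_model"))
  if (run_self_check) {
    chk <- self_check(model, profile, seed = seed)
    if (!attr(chk, "passed")) {
      rlang::abort("self check failed; closed-loop entry refused (see self_check())")
    }
  }
  cyc_per_ep <- round(epoch_s / step_s)
  n_epochs <- floor(duration_s / epoch_s)
  if (n_epochs < 1) rlang::abort("duration_s must cover at least one epoch")
  n_cycles <- n_epochs * cyc_per_ep
  n_block <- round(step_s * fs)
  n_win <- round(window_s * fs)
  warmup_cycles <- round(window_s / step_s)

  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)

  # chain stream: identical to generate_hypnogram()
  set.seed(as.integer(seed))
  u_chain <- stats::runif(n_epochs)
  cumP <- t(apply(model$transition_matrix, 1, cumsum))
  plant <- as.integer(draw_cdf(cumsum(stationary_distribution(model$transition_matrix)),
                               u_chain[1]))
  # signal + arousal stream
  set.seed((as.integer(seed) + 1013L) %% .Machine$integer.max)
  gen <- make_synthesizer(model, fs)
  plan <- spectral_plan(fs, n_win, n_fft, bands)

  buf <- numeric(n_win)
  tau_td <- thresholds$tau_theta_delta
  tau_hf <- thresholds$tau_hf
  accel_rpm <- profile$accel_rad_s2 * 60 / (2 * pi) * step_s
  target_rpm <- profile$target_rpm

  v_rtd <- numeric(n_cycles); v_rhf <- numeric(n_cycles)
  v_dec <- integer(n_cycles); v_flag <- logical(n_cycles)
  v_trig <- logical(n_cycles); v_mode <- integer(n_cycles)
  v_rpm <- numeric(n_cycles); v_plant <- integer(n_cycles)
  mode <- 1L  # 1 idle, 2 accelerating, 3 running
  rpm <- 0
  n_clip <- 0L
  cum_rem_s <- 0
  terminated <- "max_duration"
  last <- n_cycles

  for (c_i in seq_len(n_cycles)) {
    t_now <- c_i * step_s
    ep <- (c_i - 1L) %/% cyc_per_ep + 1L
    if (ep > 1L && (c_i - 1L) %% cyc_per_ep == 0L) {
      plant <- draw_cdf(cumP[plant, ], u_chain[ep])
    }
    stimulating <- mode != 1L
    if (stimulating && plant == 1L && arousal_prob > 0) {
      p_eff <- arousal_prob
      if (arousal_decline_per_h > 0) {
        p_eff <- arousal_prob *
          max(0.1, 1 - arousal_decline_per_h * t_now / 3600)
      }
      if (stats::runif(1) < p_eff) plant <- 2L
    }
    blk <- gen(vigilance_states()[plant], n_block,
               artifact_rms = if (stimulating) model$artifact_hf_gain else 0)
    x <- blk$eeg
    oob <- abs(x) > 5
    if (any(oob)) { n_clip <- n_clip + sum(oob); x <- pmin(pmax(x, -5), 5) }
    buf <- c(buf[-seq_len(n_block)], x)

    if (c_i < warmup_cycles) {
      dec <- 2L; flag <- TRUE; v_rtd[c_i] <- NA_real_; v_rhf[c_i] <- NA_real_
    } else {
      f <- plan_features(plan, buf)
      v_rtd[c_i] <- f[1]; v_rhf[c_i] <- f[2]
      if (is.na(f[1]) || is.na(f[2])) {
        dec <- 2L; flag <- TRUE
      } else {
        flag <- FALSE
        dec <- if (f[2] >= tau_hf) 2L else if (f[1] >= tau_td) 1L else 3L
      }
    }
    trig <- (dec == 1L) && !flag
    # actuator update (same rule as update_actuator(), inlined for speed)
    if (!trig) {
      mode <- 1L; rpm <- 0
    } else {
      rpm <- min(rpm + accel_rpm, target_rpm)
      mode <- if (rpm >= target_rpm) 3L else 2L
    }
    v_dec[c_i] <- dec; v_flag[c_i] <- flag; v_trig[c_i] <- trig
    v_mode[c_i] <- mode; v_rpm[c_i] <- rpm; v_plant[c_i] <- plant

    if (plant == 1L) cum_rem_s <- cum_rem_s + step_s
    if (cum_rem_s >= max_rem_s) {
      terminated <- "rem_cap"
      last <- c_i
      break
    }
  }

  keep <- seq_len(last)
  cycles <- tibble::tibble(
    time_s = keep * step_s,
    r_theta_delta = v_rtd[keep], r_hf = v_rhf[keep],
    decision = code_state(v_dec[keep]), flag = v_flag[keep],
    trigger = ifelse(v_trig[keep], "high", "low"),
    actuator_mode = c("idle", "accelerating", "running")[v_mode[keep]],
    actuator_rpm = v_rpm[keep],
    plant_state = code_state(v_plant[keep])
  )

  ev <- session_events(cycles)
  if (is.finite(max_rem_s) && terminated != "rem_cap") {
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      time_s = last * step_s,
      event = "WARN_TERMINATION_NOT_REACHED"))
  }
  n_full_ep <- last %/% cyc_per_ep
  dec_used <- cycles$decision[seq_len(n_full_ep * cyc_per_ep)]
  pla_used <- cycles$plant_state[seq_len(n_full_ep * cyc_per_ep)]
  pred <- epochize(dec_used, epoch_s, step_s)
  truth <- epochize(pla_used, epoch_s, step_s)
  epochs <- tibble::tibble(
    epoch_index = pred$epoch_index, start_s = pred$start_s,
    predicted = pred$state, truth = truth$state
  )

  structure(
    list(
      cycles = cycles, epochs = epochs, events = ev,
      config = list(fs = fs, window_s = window_s, step_s = step_s,
                    epoch_s = epoch_s, n_fft = n_fft, bands = bands,
                    seed = seed, duration_s = duration_s,
                    arousal_prob = arousal_prob,
                    arousal_decline_per_h = arousal_decline_per_h,
                    animal_id = model$animal_id,
                    thresholds = list(tau_theta_delta = tau_td, tau_hf = tau_hf),
                    profile = unclass(profile)),
      termination = terminated, clipped = n_clip
    ),
    class = "remloop_session"
  )
}

session_events <- function(cycles) {
  trig <- cycles$trigger == "high"
  run <- cycles$actuator_mode == "running"
  up <- which(trig & !dplyr::lag(trig, default = FALSE))
  down <- which(!trig & dplyr::lag(trig, default = FALSE))
  mot <- which(run & !dplyr::lag(run, default = FALSE))
  idle <- which(cycles$actuator_mode == "idle" &
                  dplyr::lag(cycles$actuator_mode, default = "idle") != "idle")
  dplyr::bind_rows(
    tibble::tibble(time_s = cycles$time_s[up], event = "TRIGGER_HIGH"),
    tibble::tibble(time_s = cycles$time_s[down], event = "TRIGGER_LOW"),
    tibble::tibble(time_s = cycles$time_s[mot], event = "MOTOR_RUNNING"),
    tibble::tibble(time_s = cycles$time_s[idle], event = "MOTOR_IDLE")
  ) |> dplyr::arrange(.data$time_s)
}

#' @export
print.remloop_session <- function(x, ...) {
  occ <- 100 * mean(x$cycles$plant_state == "REM")
  cat(sprintf("<remloop_session> %s: %d cycles (%.1f min), plant REM %.2f%%, %d trigger events, termination: %s\n",
              x$config$animal_id, nrow(x$cycles),
              max(x$cycles$time_s) / 60, occ,
              sum(x$events$event == "TRIGGER_HIGH"), x$termination))
  invisible(x)
}
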