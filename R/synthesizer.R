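#' Signal trace container
#'
#' A single-channel signal at a fixed sampling rate, in mV, as acquired by a
#' 16-bit front end with a +/- 5 mV input range: samples outside that range
#' are clipped and the number of clipped samples is recorded.
#'
#' @param samples numeric vector of sample values (mV).
#' @param fs sampling rate in Hz.
#' @param channel `"EEG"` or `"EMG"`.
#' @param clip_mv ADC full-scale (samples are clipped to `[-clip_mv, clip_mv]`).
#' @return an object of class `remloop_trace` (numeric vector with
#'   attributes `fs`, `channel`, `units`, `clipped`).
#' @export
signal_trace <- function(samples, fs = 1000, channel = c("EEG", "EMG"),
                         clip_mv = 5) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  n_clip <- sum(abs(samples) > clip_mv)
  samples <- pmin(pmax(samples, -clip_mv), clip_mv)
  structure(samples, fs = fs, channel = channel, units = "mV",
            clipped = n_clip, class = "remloop_trace")
}

#' @export
print.remloop_trace <- function(x, ...) {
  cat(sprintf("<remloop_trace> %s: %d samples @ %g Hz (%.1f s), %d clipped\n",
              attr(x, "channel"), length(x), attr(x, "fs"),
              length(x) / attr(x, "fs"), attr(x, "clipped")))
  invisible(x)
}

#' @export
`[.remloop_trace` <- function(x, i) unclass(x)[i]

trace_fs <- function(x) attr(x, "fs", exact = TRUE) %||% 1000

# Streaming state-dependent EEG/EMG synthesizer.
#
# Oscillatory components are sinusoids whose frequency is redrawn uniformly
# within the component bandwidth at each bout (state entry) and whose phase
# is continuous in absolute time within a bout. The background is a shared
# AR(1) process (coefficient `a`, unit stationary SD, scaled per state) plus
# a white floor. All randomness comes from the ambient RNG stream, so a
# single upstream set.seed() makes the whole synthesis reproducible.
make_synthesizer <- function(model, fs = 1000, ar1_coef = 0.98) {
  t0 <- 0L            # absolute sample counter
  cur_state <- NA_character_
  tone_freq <- numeric(0)
  tone_amp <- numeric(0)
  tone_phase <- numeric(0)
  ar1_x <- 0
  ar1_innov_sd <- sqrt(1 - ar1_coef^2)

  enter_state <- function(state) {
    p <- model$state_profiles[[state]]
    k <- nrow(p$tones)
    tone_freq <<- p$tones$freq_hz + stats::runif(k, -p$tones$bw_hz / 2, p$tones$bw_hz / 2)
    tone_amp <<- p$tones$amp_mv
    tone_phase <<- stats::runif(k, 0, 2 * pi)
    cur_state <<- state
  }

  gen <- function(state, n, artifact_rms = 0) {
    state <- as.character(state)
    if (!identical(state, cur_state)) enter_state(state)
    p <- model$state_profiles[[state]]
    tt <- (t0 + seq_len(n)) / fs
    eeg <- numeric(n)
    for (j in seq_along(tone_freq)) {
      eeg <- eeg + tone_amp[j] * sqrt(2) *
        sin(2 * pi * tone_freq[j] * tt + tone_phase[j])
    }
    e <- stats::rnorm(n, sd = ar1_innov_sd)
    bg <- as.numeric(stats::filter(e, ar1_coef, method = "recursive", init = ar1_x))
    ar1_x <<- bg[n]
    eeg <- eeg + p$ar1_mv * bg + stats::rnorm(n, sd = p$white_mv)
    if (artifact_rms > 0) {
      eeg <- eeg + bandlimited_noise(n, fs, 90, 200, artifact_rms)
    }
    emg <- stats::rnorm(n, sd = model$emg_rms[[state]])
    t0 <<- t0 + n
    list(eeg = eeg, emg = emg)
  }
  gen
}

# Band-limited Gaussian noise with exact RMS: white noise FFT-masked to
# [f_lo, f_hi] (both spectral half-planes), rescaled to the requested RMS.
bandlimited_noise <- function(n, fs, f_lo, f_hi, rms) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  fmir <- pmin(f, fs - f)               # analog frequency of each bin
  X[fmir < f_lo | fmir > f_hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) return(numeric(n))
  y * (rms / r)
}

#' Synthesize EEG and EMG traces for a hypnogram
#'
#' Renders the ground-truth hypnogram into continuous signals using the
#' model's per-state spectral profiles: REM epochs are theta-dominant
#' (4-8 Hz), NREM delta-dominant (0.5-4 Hz), Wake carries a broadband floor
#' that elevates 90-200 Hz power, and EMG amplitude follows
#' Wake > NREM >= REM. Output is clipped to the +/- 5 mV ADC range (clipped
#' sample counts are recorded on each trace). Deterministic given `seed`.
#'
#' @param hyp a `remloop_hypnogram`.
#' @param model a `remloop_model`.
#' @param fs sampling rate in Hz (must exceed twice the highest tone
#'   frequency).
#' @param seed integer seed.
#' @return list with elements `eeg` and `emg`, both `remloop_trace`.
#' @examples
#' m <- default_animal_model()
#' h <- generate_hypnogram(m, 60, seed = 1)
#' sig <- synthesize_signals(h, m, seed = 1)
#' sig$eeg
#' @export
synthesize_signals <- function(hyp, model, fs = 1000, seed = 1L) {
  stopifnot(inherits(model, "remloop_model"))
  if (!is.data.frame(hyp) || nrow(hyp) == 0) rlang::abort("hypnogram is empty")
  fmax <- max(vapply(model$state_profiles,
                     function(p) max(p$tones$freq_hz + p$tones$bw_hz / 2, 0),
                     numeric(1)))
  if (fs < 2 * fmax) rlang::abort("fs must be at least twice the highest profile frequency")
  epoch_s <- epoch_duration(hyp)
  n_ep <- round(epoch_s * fs)
  if (abs(n_ep - epoch_s * fs) > 1e-9) rlang::abort("epoch_s * fs must be an integer")

  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  gen <- make_synthesizer(model, fs)
  eeg <- vector("list", nrow(hyp))
  emg <- vector("list", nrow(hyp))
  states <- as.character(hyp$state)
  for (i in seq_len(nrow(hyp))) {
    b <- gen(states[i], n_ep)
    eeg[[i]] <- b$eeg
    emg[[i]] <- b$emg
  }
  list(
    eeg = signal_trace(unlist(eeg), fs, "EEG"),
    emg = signal_trace(unlist(emg), fs, "EMG")
  )
}

#' Inject motion artifacts into a trace
#'
#' Mechanical actuation contaminates the EEG with broadband high-frequency
#' noise; this adds band-limited (90-200 Hz) Gaussian noise of RMS
#' `model$artifact_hf_gain` inside each interval, leaving all other samples
#' untouched. Downstream, the elevated high-frequency fraction pushes such
#' windows over the Wake threshold — the fail-safe that keeps movement
#' artifacts from being read as REM.
#'
#' @param trace a `remloop_trace` (EEG).
#' @param intervals two-column matrix/data frame (or list of length-2
#'   vectors) of `(start_s, end_s)` intervals, non-overlapping, within the
#'   trace duration.
#' @param model a `remloop_model` (supplies `artifact_hf_gain`).
#' @param seed integer seed.
#' @return a `remloop_trace` with artifacts added (re-clipped to +/- 5 mV).
#' @export
inject_motion_artifact <- function(trace, intervals, model, seed = 1L) {
  stopifnot(inherits(trace, "remloop_trace"))
  fs <- trace_fs(trace)
  iv <- if (is.list(intervals) && !is.data.frame(intervals)) {
    do.call(rbind, intervals)
  } else as.matrix(intervals)
  if (ncol(iv) != 2) rlang::abort("intervals must have two columns (start_s, end_s)")
  if (any(iv[, 1] >= iv[, 2])) rlang::abort("inverted interval: start must be < end")
  o <- order(iv[, 1]); iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
    rlang::abort("overlapping intervals")
  }
  dur <- length(trace) / fs
  if (any(iv[, 1] < 0) || any(iv[, 2] > dur + 1e-9)) {
    rlang::abort("intervals must lie within the trace duration")
  }
  if (model$artifact_hf_gain == 0) return(trace)
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  x <- as.numeric(trace)
  for (r in seq_len(nrow(iv))) {
    idx <- (floor(iv[r, 1] * fs) + 1):min(length(x), ceiling(iv[r, 2] * fs))
    x[idx] <- x[idx] + bandlimited_noise(length(idx), fs, 90, 200,
                                         model$artifact_hf_gain)
  }
  signal_trace(x, fs, attr(trace, "channel"))
}
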