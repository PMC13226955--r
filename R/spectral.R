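#' Default analysis bands (Hz)
#'
#' Band edges of the two spectral features: the theta/delta ratio uses theta
#' 4-8 Hz over delta 0.5-4 Hz; the normalized high-frequency power uses
#' 90-200 Hz over the total 0.5-500 Hz recording bandwidth. Bands are closed
#' on the left and open on the right, except that the terminal Nyquist bin
#' (500 Hz) is included in the total band; the DC bin is excluded from every
#' band (the analog front end is high-passed at 0.5 Hz).
#'
#' @return named list of `c(lo, hi)` band edges.
#' @export
default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), hf = c(90, 200), total = c(0.5, 500))
}

#' Sliding signal buffer (5 s window, 100 ms step)
#'
#' The unit of real-time analysis is a 5 s window of 5000 samples at 1 kHz,
#' advanced every 100 ms by appending the newest 100 samples and discarding
#' the oldest — a 98 % overlap between consecutive windows. The buffer starts
#' filled with zeros and reports `full = FALSE` until 5 s of real samples
#' have been pushed (the classifier treats such warmup windows as Wake).
#'
#' @param capacity window length in samples.
#' @param fs sampling rate in Hz.
#' @param step step size in samples; every push must supply exactly this
#'   many samples (the fixed-step contract of the control loop).
#' @return an object of class `remloop_buffer`.
#' @examples
#' b <- signal_buffer()
#' w <- push_samples(b, rnorm(100))
#' w$end_time
#' @export
signal_buffer <- function(capacity = 5000, fs = 1000, step = 100) {
  env <- new.env(parent = emptyenv())
  env$samples <- numeric(capacity)
  env$seen <- 0L
  env$capacity <- as.integer(capacity)
  env$fs <- fs
  env$step <- as.integer(step)
  class(env) <- "remloop_buffer"
  env
}

#' @rdname signal_buffer
#' @param buffer a `remloop_buffer`.
#' @param new_samples numeric vector of exactly `step` new samples.
#' @return `push_samples()` returns the advanced window: a list of class
#'   `remloop_window` with elements `samples`, `fs`, `end_time`, `full`.
#' @export
push_samples <- function(buffer, new_samples) {
  stopifnot(inherits(buffer, "remloop_buffer"))
  if (length(new_samples) != buffer$step) {
    rlang::abort(sprintf("push_samples() requires exactly %d samples (got %d): fixed-step contract",
                         buffer$step, length(new_samples)))
  }
  buffer$samples <- c(buffer$samples[-seq_len(buffer$step)], as.numeric(new_samples))
  buffer$seen <- buffer$seen + buffer$step
  structure(
    list(samples = buffer$samples, fs = buffer$fs,
         end_time = buffer$seen / buffer$fs,
         full = buffer$seen >= buffer$capacity),
    class = "remloop_window"
  )
}

hanning_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

#' One-sided power spectral density of a signal window
#'
#' Periodogram of the Hanning-tapered window, zero-padded to `n_fft` points
#' (10,000 by default, giving a 0.1 Hz bin spacing at 1 kHz): density scaling
#' `2 |X(f)|^2 / (fs * sum(w^2))` with the DC and Nyquist bins not doubled,
#' so that `sum(psd) * df` integrates power in mV^2. Since both downstream
#' features are ratios of band powers, any consistent scaling would do; the
#' density convention makes the `p(f) * df` Riemann sums meaningful on their
#' own.
#'
#' @param window a `remloop_window`, or a numeric vector (then supply `fs`).
#' @param n_fft FFT length (>= window length; zero-padded).
#' @param taper `"hanning"` (default) or `"rectangular"`.
#' @param fs sampling rate, used when `window` is a bare vector.
#' @return an object of class `remloop_psd`: list with `freqs` (0 to `fs/2`,
#'   spacing `fs/n_fft`), `psd` (mV^2/Hz), `df`, `n_fft`, `fs`, `end_time`.
#' @examples
#' x <- sin(2 * pi * 100 * (1:5000) / 1000)
#' p <- compute_psd(x)
#' p$freqs[which.max(p$psd)]
#' @export
compute_psd <- function(window, n_fft = 10000,
                        taper = c("hanning", "rectangular"), fs = 1000) {
  taper <- match.arg(taper)
  end_time <- NA_real_
  if (inherits(window, "remloop_window")) {
    x <- window$samples
    fs <- window$fs
    end_time <- window$end_time
  } else {
    x <- as.numeric(window)
  }
  if (any(!is.finite(x))) rlang::abort("window contains NaN/Inf samples")
  n <- length(x)
  if (n_fft < n) rlang::abort("n_fft must be >= window length")
  w <- if (taper == "hanning") hanning_window(n) else rep(1, n)
  padded <- numeric(n_fft)
  padded[seq_len(n)] <- x * w
  X <- stats::fft(padded)
  half <- n_fft %/% 2
  p <- Mod(X[seq_len(half + 1)])^2 * (2 / (fs * sum(w^2)))
  p[1] <- p[1] / 2
  if (n_fft %% 2 == 0) p[half + 1] <- p[half + 1] / 2
  structure(
    list(freqs = (0:half) * fs / n_fft, psd = p, df = fs / n_fft,
         n_fft = n_fft, fs = fs, end_time = end_time),
    class = "remloop_psd"
  )
}

#' @export
print.remloop_psd <- function(x, ...) {
  cat(sprintf("<remloop_psd> %d bins, 0-%g Hz at %g Hz spacing\n",
              length(x$freqs), max(x$freqs), x$df))
  invisible(x)
}

#' @export
as_tibble.remloop_psd <- function(x, ...) {
  tibble::tibble(freq_hz = x$freqs, psd = x$psd)
}

# Bin indices of [f_lo, f_hi) on the grid k * df; hi bin included only when
# f_hi reaches the Nyquist frequency; DC always excluded.
band_bins <- function(freqs, f_lo, f_hi, fs) {
  inc_hi <- f_hi >= fs / 2 - 1e-9
  which(freqs >= f_lo - 1e-9 & freqs > 1e-12 &
          (freqs < f_hi - 1e-9 | (inc_hi & freqs <= f_hi + 1e-9)))
}

#' Band power by Riemann summation of the PSD
#'
#' `sum(p(f_k) * df)` over the bins of `[f_lo, f_hi)` (left-closed,
#' right-open; the terminal Nyquist bin is included when `f_hi` is the
#' Nyquist frequency, and the DC bin is always excluded). The half-open
#' convention makes band power additive over bands sharing an edge, e.g.
#' delta `[0.5, 4)` and theta `[4, 8)`.
#'
#' @param spectrum a `remloop_psd`.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return band power in mV^2.
#' @export
band_power <- function(spectrum, f_lo, f_hi) {
  stopifnot(inherits(spectrum, "remloop_psd"))
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= spectrum$fs / 2 + 1e-9)) {
    rlang::abort("require 0 <= f_lo < f_hi <= fs/2")
  }
  idx <- band_bins(spectrum$freqs, f_lo, f_hi, spectrum$fs)
  sum(spectrum$psd[idx]) * spectrum$df
}

#' Spectral features of a window: theta/delta ratio and normalized HF power
#'
#' The classifier's entire input: `r_theta_delta`, the theta (4-8 Hz) to
#' delta (0.5-4 Hz) band-power ratio separating REM from NREM, and `r_hf`,
#' the 90-200 Hz power as a fraction of the total 0.5-500 Hz power,
#' separating wakefulness (and movement artifact) from sleep. If a
#' denominator is zero the features are returned as `NA` with
#' `undefined = TRUE`; the classifier maps such windows to Wake so no
#' stimulation decision ever rests on degenerate input.
#'
#' @param spectrum a `remloop_psd`.
#' @param bands band-edge list as from [default_bands()].
#' @return one-row tibble: `end_time`, `r_theta_delta`, `r_hf`, `undefined`.
#' @export
extract_features <- function(spectrum, bands = default_bands()) {
  p_delta <- band_power(spectrum, bands$delta[1], bands$delta[2])
  p_theta <- band_power(spectrum, bands$theta[1], bands$theta[2])
  p_hf <- band_power(spectrum, bands$hf[1], bands$hf[2])
  p_total <- band_power(spectrum, bands$total[1], bands$total[2])
  undefined <- (p_delta <= 0) || (p_total <= 0)
  tibble::tibble(
    end_time = spectrum$end_time,
    r_theta_delta = if (p_delta > 0) p_theta / p_delta else NA_real_,
    r_hf = if (p_total > 0) p_hf / p_total else NA_real_,
    undefined = undefined
  )
}

#' Per-epoch features of a continuous recording
#'
#' Offline analogue of the real-time pipeline: for each complete 2.5 s epoch
#' the features of the 5 s window *ending* at the epoch's end are computed
#' (matching what the online classifier sees at that moment). Epochs whose
#' window would reach before the recording start are flagged
#' `undefined = TRUE` with `NA` features (the online warmup).
#'
#' @param eeg a `remloop_trace` or numeric vector of EEG samples.
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch duration in seconds.
#' @param window_s analysis window length in seconds.
#' @param n_fft FFT length.
#' @param bands band-edge list.
#' @return tibble: `epoch_index`, `end_time_s`, `r_theta_delta`, `r_hf`,
#'   `undefined`.
#' @export
epoch_features <- function(eeg, fs = 1000, epoch_s = 2.5, window_s = 5,
                           n_fft = 10000, bands = default_bands()) {
  if (inherits(eeg, "remloop_trace")) {
    fs <- trace_fs(eeg)
    eeg <- as.numeric(eeg)
  }
  n_ep <- floor(length(eeg) / (epoch_s * fs))
  n_win <- round(window_s * fs)
  sp <- spectral_plan(fs, n_win, n_fft, bands)
  out <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    end_samp <- round(i * epoch_s * fs)
    end_t <- i * epoch_s
    if (end_samp < n_win) {
      out[[i]] <- tibble::tibble(end_time = end_t, r_theta_delta = NA_real_,
                                 r_hf = NA_real_, undefined = TRUE)
    } else {
      f <- plan_features(sp, eeg[(end_samp - n_win + 1):end_samp])
      out[[i]] <- tibble::tibble(end_time = end_t, r_theta_delta = f[1],
                                 r_hf = f[2], undefined = is.na(f[1]) || is.na(f[2]))
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(epoch_index = seq_len(n_ep) - 1L, .before = 1) |>
    dplyr::rename(end_time_s = "end_time")
}

# Precomputed taper + band-bin indices: the hot path shared by the offline
# per-epoch extractor and the 100 ms control loop.
spectral_plan <- function(fs, n_win, n_fft, bands = default_bands()) {
  freqs <- (0:(n_fft %/% 2)) * fs / n_fft
  list(
    fs = fs, n_win = n_win, n_fft = n_fft,
    taper = hanning_window(n_win),
    pad = numeric(n_fft),
    half1 = n_fft %/% 2 + 1,
    i_delta = band_bins(freqs, bands$delta[1], bands$delta[2], fs),
    i_theta = band_bins(freqs, bands$theta[1], bands$theta[2], fs),
    i_hf = band_bins(freqs, bands$hf[1], bands$hf[2], fs),
    i_total = band_bins(freqs, bands$total[1], bands$total[2], fs)
  )
}

# Returns c(r_theta_delta, r_hf); scaling constants cancel in the ratios so
# the raw |X|^2 sums are used directly.
plan_features <- function(plan, x) {
  plan$pad[seq_len(plan$n_win)] <- x * plan$taper
  P <- Mod(stats::fft(plan$pad)[seq_len(plan$half1)])^2
  p_delta <- sum(P[plan$i_delta])
  p_total <- sum(P[plan$i_total])
  c(
    if (p_delta > 0) sum(P[plan$i_theta]) / p_delta else NA_real_,
    if (p_total > 0) sum(P[plan$i_hf]) / p_total else NA_real_
  )
}

#' Per-epoch EMG RMS amplitude
#'
#' @param emg a `remloop_trace` or numeric vector of EMG samples.
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch duration in seconds.
#' @return tibble: `epoch_index`, `emg_rms` (mV).
#' @export
epoch_emg_rms <- function(emg, fs = 1000, epoch_s = 2.5) {
  if (inherits(emg, "remloop_trace")) {
    fs <- trace_fs(emg)
    emg <- as.numeric(emg)
  }
  n_ep <- floor(length(emg) / (epoch_s * fs))
  n <- round(epoch_s * fs)
  rms <- vapply(seq_len(n_ep), function(i) {
    sqrt(mean(emg[((i - 1) * n + 1):(i * n)]^2))
  }, numeric(1))
  tibble::tibble(epoch_index = seq_len(n_ep) - 1L, emg_rms = rms)
}
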