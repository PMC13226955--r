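# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# 30 min default-animal baseline with signals, features and thresholds;
# enough REM/NREM epochs for calibration at the chosen seed.
cached_baseline <- function() {
  if (is.null(.fixtures$baseline)) {
    model <- default_animal_model()
    hyp <- generate_hypnogram(model, 1800, seed = 42)
    sig <- synthesize_signals(hyp, model, seed = 42)
    feats <- epoch_features(sig$eeg)
    stats <- state_feature_stats(feats, hyp)
    th <- estimate_thresholds(stats, "fixture-animal")
    .fixtures$baseline <- list(model = model, hyp = hyp, sig = sig,
                               feats = feats, stats = stats, thresholds = th)
  }
  .fixtures$baseline
}

# Minimal one-tone model: a single oscillator per state, no background.
tone_model <- function(rem_freq = 6, amp = 0.1, arousal_prob = 0.4) {
  profile <- function(freq, a = amp) {
    list(tones = tibble::tibble(freq_hz = freq, bw_hz = 0, amp_mv = a),
         ar1_mv = 0, white_mv = 0)
  }
  animal_model(
    state_profiles = list(REM = profile(rem_freq), Wake = profile(20),
                          NREM = profile(2)),
    emg_rms = c(REM = 0.01, Wake = 0.1, NREM = 0.03),
    transition_matrix = default_transition_matrix(),
    arousal_prob = arousal_prob,
    artifact_hf_gain = 0.1,
    animal_id = "tone-model"
  )
}

# Gaussian per-epoch feature sampler with known population parameters,
# for threshold-recovery checks at large n without signal synthesis.
gaussian_features <- function(n_per_state, mu_td, sd_td, mu_hf, sd_hf,
                              seed = 1) {
  set.seed(seed)
  states <- rep(names(n_per_state), times = n_per_state)
  idx <- seq_along(states) - 1L
  f <- tibble::tibble(
    epoch_index = idx,
    end_time_s = (idx + 1) * 2.5,
    r_theta_delta = stats::rnorm(length(states), mu_td[states], sd_td[states]),
    r_hf = stats::rnorm(length(states), mu_hf[states], sd_hf[states]),
    undefined = FALSE
  )
  list(features = f, labels = hypnogram(states))
}

# Hand-rolled one-sided periodogram by direct DFT summation (no fft());
# the independent oracle for compute_psd()/band_power().
oracle_psd_bins <- function(x, bins, n_fft = 10000, fs = 1000,
                            taper = c("hanning", "rectangular")) {
  taper <- match.arg(taper)
  n <- length(x)
  w <- if (taper == "hanning") 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
       else rep(1, n)
  xw <- x * w
  t_idx <- 0:(n - 1)
  vapply(bins, function(k) {
    ang <- -2 * pi * k * t_idx / n_fft
    re <- sum(xw * cos(ang))
    im <- sum(xw * sin(ang))
    scale <- 2 / (fs * sum(w^2))
    p <- (re^2 + im^2) * scale
    if (k == 0 || k == n_fft / 2) p <- p / 2
    p
  }, numeric(1))
}

# Fresh scratch directory for file round-trip tests.
local_dir <- function() {
  d <- tempfile("remloop-")
  dir.create(d)
  d
}
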