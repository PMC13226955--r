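test_that("state codes follow the scoring convention and round-trip", {
  expect_equal(state_code(c("REM", "Wake", "NREM")), 1:3)
  expect_equal(as.character(code_state(c(3L, 1L, 2L))), c("NREM", "REM", "Wake"))
  expect_error(code_state(4L), "invalid state code")
  expect_error(state_code("Drowsy"), "invalid vigilance state")
})

test_that("animal model validation rejects malformed inputs", {
  m <- default_animal_model()
  bad_P <- m$transition_matrix
  bad_P[1, 1] <- bad_P[1, 1] + 0.1
  expect_error(animal_model(m$state_profiles, m$emg_rms, bad_P), "sum to 1")
  expect_error(animal_model(m$state_profiles, m$emg_rms, m$transition_matrix,
                            arousal_prob = 1.5), "arousal_prob")
  expect_error(generate_hypnogram(m, duration_s = 1), "duration_s")
})

test_that("an identity transition matrix is absorbing", {
  m <- default_animal_model()
  m$transition_matrix <- diag(3)
  dimnames(m$transition_matrix) <- list(vigilance_states(), vigilance_states())
  h <- generate_hypnogram(m, 250, seed = 3, init = "NREM")
  expect_equal(nrow(h), 100)
  expect_true(all(h$state == "NREM"))
})

test_that("hypnograms are seed-deterministic and carry valid epochs", {
  m <- default_animal_model()
  h1 <- generate_hypnogram(m, 3600, seed = 9)
  h2 <- generate_hypnogram(m, 3600, seed = 9)
  expect_identical(h1, h2)
  h3 <- generate_hypnogram(m, 3600, seed = 10)
  expect_false(identical(h1$state, h3$state))
  expect_equal(h1$start_s, h1$epoch_index * 2.5)
  expect_equal(epoch_duration(h1), 2.5)
})

test_that("stationary distribution matches a power-iteration oracle and 24 h occupancy converges to it", {
  P <- default_transition_matrix()
  # independent oracle: brute-force power iteration from a uniform start
  v <- rep(1 / 3, 3)
  for (k in 1:20000) v <- as.numeric(v %*% P)
  pi_eig <- stationary_distribution(P)
  expect_equal(unname(pi_eig), v, tolerance = 1e-10)
  expect_equal(unname(pi_eig), c(0.07, 0.45, 0.48), tolerance = 1e-9)

  h <- generate_hypnogram(default_animal_model(), 86400, seed = 5)
  occ <- occupancy(h)
  rem_pct <- occ$pct[occ$state == "REM"]
  expect_lt(abs(rem_pct - 100 * pi_eig[["REM"]]), 3)  # within 3 pp
})

test_that("a pure 6 Hz REM window yields extreme theta/delta ratio and negligible HF power", {
  m <- tone_model(rem_freq = 6)
  m$state_profiles$REM$tones$bw_hz <- 0
  h <- hypnogram(rep("REM", 2))  # one full 5 s window
  sig <- synthesize_signals(h, m, seed = 1)
  f <- extract_features(compute_psd(as.numeric(sig$eeg)[1:5000]))
  expect_gt(f$r_theta_delta, 10)
  expect_lt(f$r_hf, 0.01)
})

test_that("an all-zero model produces all-zero traces", {
  m <- tone_model(amp = 0)
  m$emg_rms[] <- 0
  h <- hypnogram(rep(c("REM", "NREM", "Wake"), 4))
  sig <- synthesize_signals(h, m, seed = 1)
  expect_true(all(as.numeric(sig$eeg) == 0))
  expect_true(all(as.numeric(sig$emg) == 0))
})

test_that("synthesis is seed-deterministic and honors the ADC clip range", {
  m <- default_animal_model()
  h <- generate_hypnogram(m, 120, seed = 2)
  s1 <- synthesize_signals(h, m, seed = 7)
  s2 <- synthesize_signals(h, m, seed = 7)
  expect_identical(as.numeric(s1$eeg), as.numeric(s2$eeg))
  expect_identical(as.numeric(s1$emg), as.numeric(s2$emg))

  big <- m
  big$state_profiles$NREM$tones$amp_mv[1] <- 50
  sb <- synthesize_signals(hypnogram(rep("NREM", 4)), big, seed = 1)
  expect_lte(max(abs(as.numeric(sb$eeg))), 5)
  expect_gt(attr(sb$eeg, "clipped"), 0)
})

test_that("per-state spectra honor the ordering contract over a 30 min run", {
  fx <- cached_baseline()
  d <- dplyr::inner_join(fx$feats, tibble::as_tibble(fx$hyp)[, c("epoch_index", "state")],
                         by = "epoch_index") |>
    dplyr::filter(is.finite(r_theta_delta)) |>
    dplyr::group_by(state) |>
    dplyr::summarise(td = mean(r_theta_delta), hf = mean(r_hf))
  td <- setNames(d$td, as.character(d$state))
  hf <- setNames(d$hf, as.character(d$state))
  expect_gt(td[["REM"]], td[["NREM"]])          # REM theta-dominant
  expect_gt(hf[["Wake"]], hf[["REM"]])          # Wake HF-elevated
  expect_gt(hf[["Wake"]], hf[["NREM"]])
  emg <- dplyr::inner_join(epoch_emg_rms(fx$sig$emg),
                           tibble::as_tibble(fx$hyp)[, c("epoch_index", "state")],
                           by = "epoch_index") |>
    dplyr::group_by(state) |>
    dplyr::summarise(rms = mean(emg_rms))
  rms <- setNames(emg$rms, as.character(emg$state))
  expect_gt(rms[["Wake"]], rms[["NREM"]])       # EMG: Wake > NREM >= REM
  expect_gte(rms[["NREM"]], rms[["REM"]])
})

test_that("step_plant arouses from REM under stimulation and follows the chain otherwise", {
  m <- default_animal_model(arousal_prob = 1)
  set.seed(1)
  expect_equal(as.character(step_plant("REM", TRUE, m)), "Wake")

  # not stimulating at a boundary: follows the REM transition row
  m2 <- default_animal_model()
  m2$transition_matrix <- matrix(c(0, 1, 0,  0, 1, 0,  0, 1, 0), 3, 3, byrow = TRUE)
  dimnames(m2$transition_matrix) <- list(vigilance_states(), vigilance_states())
  set.seed(1)
  expect_equal(as.character(step_plant("REM", FALSE, m2)), "Wake")

  # off-boundary, no stimulation: state unchanged
  set.seed(1)
  expect_equal(as.character(step_plant("REM", FALSE, m, at_epoch_boundary = FALSE)), "REM")
})

test_that("empirical arousal fraction matches the binomial rate", {
  m <- default_animal_model(arousal_prob = 0.3)
  set.seed(99)
  aroused <- vapply(1:10000, function(i) {
    as.character(step_plant("REM", TRUE, m, at_epoch_boundary = FALSE)) == "Wake"
  }, logical(1))
  expect_lt(abs(mean(aroused) - 0.3), 0.02)
})

test_that("motion artifacts raise 90-200 Hz power only inside the intervals", {
  fx <- cached_baseline()
  m <- fx$model
  h <- hypnogram(rep("NREM", 8))  # 20 s
  sig <- synthesize_signals(h, m, seed = 3)
  out <- inject_motion_artifact(sig$eeg, list(c(5, 10)), m, seed = 4)
  fs <- 1000
  inside <- (5 * fs + 1):(10 * fs)
  expect_false(isTRUE(all.equal(as.numeric(out)[inside], as.numeric(sig$eeg)[inside])))
  expect_identical(as.numeric(out)[-inside], as.numeric(sig$eeg)[-inside])

  hf_power <- function(x) band_power(compute_psd(x), 90, 200)
  expect_gt(hf_power(as.numeric(out)[inside]), hf_power(as.numeric(sig$eeg)[inside]))

  # the contaminated window crosses the calibrated Wake threshold
  f_art <- extract_features(compute_psd(as.numeric(out)[inside]))
  expect_gt(f_art$r_hf, fx$thresholds$tau_hf)
  expect_equal(as.character(classify(f_art, fx$thresholds)), "Wake")

  # inside/outside band-power ratio agrees with the direct-summation oracle
  bins <- 900:2000  # 90.0-200.0 Hz at 0.1 Hz spacing
  p_in <- sum(oracle_psd_bins(as.numeric(out)[inside], bins)) * 0.1
  p_out <- sum(oracle_psd_bins(as.numeric(out)[(10 * fs + 1):(15 * fs)], bins)) * 0.1
  ratio_pkg <- hf_power(as.numeric(out)[inside]) /
    hf_power(as.numeric(out)[(10 * fs + 1):(15 * fs)])
  expect_equal(ratio_pkg, p_in / p_out, tolerance = 0.05)
})

test_that("artifact injection validates intervals and respects zero gain", {
  m <- default_animal_model()
  h <- hypnogram(rep("NREM", 4))
  sig <- synthesize_signals(h, m, seed = 1)
  expect_error(inject_motion_artifact(sig$eeg, list(c(4, 2)), m), "inverted")
  expect_error(inject_motion_artifact(sig$eeg, list(c(0, 3), c(2, 5)), m), "overlapping")
  expect_error(inject_motion_artifact(sig$eeg, list(c(5, 20)), m), "within the trace")
  m0 <- m; m0$artifact_hf_gain <- 0
  expect_identical(inject_motion_artifact(sig$eeg, list(c(1, 2)), m0), sig$eeg)
})
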