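test_that("confusion matrix: identity, total miss, and a loop-counting oracle", {
  truth <- hypnogram(c("REM", "REM", "Wake", "NREM", "NREM", "NREM"))
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(cm$row_pct), c(100, 100, 100), ignore_attr = TRUE)
  expect_equal(sum(cm$counts) , 6)

  all_rem <- hypnogram(rep("REM", 10))
  all_wake <- hypnogram(rep("Wake", 10))
  cm2 <- confusion_matrix(all_rem, all_wake)
  expect_equal(unname(cm2$row_pct["REM", ]), c(0, 100, 0))

  set.seed(2)
  a <- hypnogram(sample(c("REM", "Wake", "NREM"), 500, replace = TRUE))
  b <- hypnogram(sample(c("REM", "Wake", "NREM"), 500, replace = TRUE))
  cm3 <- confusion_matrix(a, b)
  oracle <- matrix(0L, 3, 3)
  for (i in 1:500) {
    oracle[state_code(a$state[i]), state_code(b$state[i])] <-
      oracle[state_code(a$state[i]), state_code(b$state[i])] + 1L
  }
  expect_equal(unname(cm3$counts), oracle)
  expect_equal(unname(rowSums(cm3$row_pct)), rep(100, 3), tolerance = 1e-6)

  expect_error(confusion_matrix(a, b[1:100, ]), "length")
})

test_that("recall/precision/F1 match textbook formulas and flag empty classes", {
  truth <- hypnogram(rep(c("REM", "Wake", "NREM"), c(5, 3, 2)))
  m <- recall_f1(confusion_matrix(truth, truth))
  expect_equal(m$recall, rep(1, 3))
  expect_equal(m$f1, rep(1, 3))

  # the REM row of the pooled device confusion, scaled to integer epochs
  cm <- structure(list(counts = matrix(c(886, 60, 54,
                                         10, 804, 27,
                                         5, 149, 891), 3, 3, byrow = TRUE,
                                       dimnames = list(truth = vigilance_states(),
                                                       predicted = vigilance_states())),
                       row_pct = NULL), class = "remloop_confusion")
  m2 <- recall_f1(cm)
  expect_equal(m2$recall[m2$state == "REM"], 0.886)

  set.seed(4)
  for (i in 1:10) {
    counts <- matrix(rpois(9, 40), 3, 3,
                     dimnames = list(truth = vigilance_states(),
                                     predicted = vigilance_states()))
    mm <- recall_f1(structure(list(counts = counts, row_pct = NULL),
                              class = "remloop_confusion"))
    for (s in 1:3) {
      r <- counts[s, s] / sum(counts[s, ])
      p <- counts[s, s] / sum(counts[, s])
      expect_equal(mm$recall[s], r)
      expect_equal(mm$precision[s], p)
      expect_equal(mm$f1[s], 2 * r * p / (r + p))
    }
  }

  none <- structure(list(counts = matrix(c(0L, 0L, 0L, 0L, 5L, 0L, 0L, 0L, 5L), 3, 3,
                                         byrow = TRUE,
                                         dimnames = list(truth = vigilance_states(),
                                                         predicted = vigilance_states())),
                         row_pct = NULL), class = "remloop_confusion")
  m3 <- recall_f1(none)
  expect_true(is.na(m3$recall[m3$state == "REM"]))
})

test_that("occupancy percentages are exact and conserve 100 %", {
  expect_equal(occupancy(hypnogram(rep("NREM", 8)))$pct, c(0, 0, 100))
  h <- hypnogram(rep(c("REM", "Wake", "NREM"), c(7, 45, 48)))
  expect_equal(occupancy(h)$pct, c(7, 45, 48))
  set.seed(6)
  for (i in 1:10) {
    h <- hypnogram(sample(c("REM", "Wake", "NREM"), sample(5:500, 1), replace = TRUE))
    expect_equal(sum(occupancy(h)$pct), 100)
  }
  expect_error(occupancy(hypnogram(character(0))), "empty")
})

test_that("a multi-seed baseline cohort sits at the chain's stationary REM mass", {
  m <- default_animal_model()
  target <- 100 * stationary_distribution(m$transition_matrix)[["REM"]]
  rem <- vapply(1:8, function(s) {
    o <- occupancy(generate_hypnogram(m, 43200, seed = 100 + s))
    o$pct[o$state == "REM"]
  }, numeric(1))
  expect_lt(abs(mean(rem) - target), 1.5)
})

test_that("fold change: geometric mean identities and antisymmetry", {
  expect_equal(fold_change(c(2, 8), c(1, 1))$geometric_mean, 4)
  x <- c(7.2, 6.8, 7.5, 8.1)
  same <- fold_change(x, x)
  expect_identical(same$geometric_mean, 1)
  expect_true(same$ci_lo <= 1 && same$ci_hi >= 1)
  a <- c(7, 8, 6, 9); b <- c(0.5, 0.7, 0.4, 0.6)
  expect_equal(fold_change(a, b)$geometric_mean,
               1 / fold_change(b, a)$geometric_mean, tolerance = 1e-12)
  expect_error(fold_change(c(1, 0), c(1, 1)), "zero")
  expect_equal(fold_change(c(1, 0), c(1, 1), zero_adjust = 0.5)$zero_adjusted, 1L)
  expect_error(fold_change(1:3, 1:2), "paired")
})

test_that("strong suppression gives GM >> 1 with a CI excluding 1, near a plain bootstrap oracle", {
  set.seed(10)
  base <- rnorm(8, 7, 1.5)
  rsd <- rnorm(8, 0.45, 0.15)
  fc <- fold_change(base, rsd, seed = 3)
  expect_gt(fc$geometric_mean, 10)
  expect_gt(fc$ci_lo, 1)
  # independent plain-percentile bootstrap oracle on the log ratios
  lr <- log(base / rsd)
  set.seed(99)
  boot <- replicate(20000, mean(sample(lr, 8, replace = TRUE)))
  oracle_ci <- exp(quantile(boot, c(0.025, 0.975)))
  expect_equal(fc$ci_lo, unname(oracle_ci[1]), tolerance = 0.1)
  expect_equal(fc$ci_hi, unname(oracle_ci[2]), tolerance = 0.1)
})

test_that("wilcoxon: closed-form extreme case and two-sided symmetry", {
  b <- c(8, 7, 6, 5, 9, 8.5, 7.5, 6.5)
  r <- c(1, 2, 1.2, 2.2, 1.4, 2.4, 1.6, 2.6)
  w <- wilcoxon_paired(b, r)
  expect_equal(w$statistic, 36)           # all positive ranks
  expect_equal(w$p_value, 2 / 256)        # 0.0078125 exactly
  w_flip <- wilcoxon_paired(r, b)
  expect_equal(w_flip$p_value, w$p_value)
  expect_error(wilcoxon_paired(c(1, 2), c(1, 2)), "degenerate")
})

test_that("wilcoxon agrees with exhaustive sign enumeration for n <= 12", {
  set.seed(14)
  for (rep in 1:12) {
    n <- sample(5:12, 1)
    b <- round(rnorm(n, 5, 2), 1)
    r <- round(rnorm(n, 4, 2), 1)   # rounding induces ties and zeros
    if (all(b == r)) next
    got <- wilcoxon_paired(b, r)
    d <- b - r
    rk <- rank(abs(d))
    rk_nz <- rk[d != 0]
    if (length(rk_nz) == 0) next
    v_obs <- sum(rk_nz[d[d != 0] > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(rk_nz))))
    v_all <- signs %*% rk_nz
    p_le <- mean(v_all <= v_obs + 1e-9)
    p_ge <- mean(v_all >= v_obs - 1e-9)
    expect_equal(got$statistic, v_obs)
    expect_equal(got$p_value, min(1, 2 * min(p_le, p_ge)), tolerance = 1e-12)
  }
})

test_that("wilcoxon matches stats::wilcox.test when ties and zeros are absent", {
  set.seed(15)
  for (rep in 1:8) {
    n <- sample(6:20, 1)
    b <- rnorm(n); r <- rnorm(n)
    got <- wilcoxon_paired(b, r)
    ref <- stats::wilcox.test(b, r, paired = TRUE, exact = TRUE, correct = FALSE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("state-space export joins per-epoch series and rejects misalignment", {
  fx <- gaussian_features(c(REM = 1, Wake = 1, NREM = 1),
                          c(REM = 2, Wake = 1, NREM = 0.3),
                          c(REM = 0.1, Wake = 0.1, NREM = 0.1),
                          c(REM = 0.01, Wake = 0.2, NREM = 0.03),
                          c(REM = 0.001, Wake = 0.01, NREM = 0.003))
  emg <- tibble::tibble(epoch_index = 0:2, emg_rms = c(0.01, 0.15, 0.03))
  tab <- state_space_export(fx$features, emg, fx$labels)
  expect_equal(nrow(tab), 3)
  expect_equal(names(tab), c("epoch_index", "r_theta_delta", "emg_rms", "state"))
  expect_equal(tab$emg_rms[tab$state == "Wake"], 0.15)
  expect_error(state_space_export(fx$features, emg[1:2, ], fx$labels), "same epochs")
})

test_that("baseline REM epochs cluster at high theta/delta and low EMG", {
  fx <- cached_baseline()
  tab <- state_space_export(fx$feats[!fx$feats$undefined, ],
                            epoch_emg_rms(fx$sig$emg)[!fx$feats$undefined, ],
                            fx$hyp[!fx$feats$undefined, ])
  med <- tab |> dplyr::group_by(state) |>
    dplyr::summarise(td = median(r_theta_delta), emg = median(emg_rms))
  expect_gt(med$td[med$state == "REM"], med$td[med$state == "NREM"])
  expect_lt(med$emg[med$state == "REM"], med$emg[med$state == "Wake"])
})

test_that("efficacy report summarizes a cohort with zero-adjusted ratios", {
  set.seed(20)
  mk <- function(p_rem) {
    n <- 800
    n_rem <- round(n * p_rem)
    hypnogram(sample(rep(c("REM", "Wake", "NREM"),
                         c(n_rem, 360, n - 360 - n_rem))))
  }
  base <- lapply(c(.07, .08, .06, .07), mk)
  rsd <- lapply(c(.005, 0, .004, .006), mk)
  names(base) <- names(rsd) <- paste0("m", 1:4)
  rep_ <- efficacy_report(base, rsd, n_boot = 2000)
  per <- rep_$per_state
  expect_equal(as.character(per$state), c("REM", "Wake", "NREM"))
  rem <- per[per$state == "REM", ]
  expect_gt(rem$fold_gm, 5)
  expect_equal(rem$zero_adjusted, 1L)
  expect_true(rem$fold_ci_lo <= rem$fold_gm && rem$fold_gm <= rem$fold_ci_hi)
  expect_equal(rep_$zero_adjust, 0.5 * 100 / 800)
  occ_sums <- rep_$occupancy |> dplyr::group_by(animal, condition) |>
    dplyr::summarise(s = sum(pct), .groups = "drop")
  expect_equal(occ_sums$s, rep(100, 8), tolerance = 1e-6)
})
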