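#' Confusion matrix between a ground-truth and a predicted hypnogram
#'
#' Counts epochs by (true state, predicted state), rows = truth, columns =
#' prediction, plus row-normalized percentages (each row sums to 100). Both
#' hypnograms must cover the same epochs at the same epoch duration.
#'
#' @param truth,predicted `remloop_hypnogram` tibbles (or factors of equal
#'   length).
#' @return object of class `remloop_confusion`: list with `counts` (3x3
#'   integer) and `row_pct`.
#' @export
confusion_matrix <- function(truth, predicted) {
  tr <- if (is.data.frame(truth)) truth$state else truth
  pr <- if (is.data.frame(predicted)) predicted$state else predicted
  if (length(tr) != length(pr)) rlang::abort("truth and predicted differ in length")
  if (is.data.frame(truth) && is.data.frame(predicted)) {
    if (abs(epoch_duration(truth) - epoch_duration(predicted)) > 1e-9) {
      rlang::abort("truth and predicted differ in epoch duration")
    }
    if (any(truth$epoch_index != predicted$epoch_index)) {
      rlang::abort("truth and predicted are not aligned on epoch_index")
    }
  }
  tr <- state_factor(tr)
  pr <- state_factor(pr)
  counts <- table(truth = tr, predicted = pr)
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(truth = vigilance_states(),
                                   predicted = vigilance_states()))
  rs <- rowSums(counts)
  row_pct <- counts / ifelse(rs == 0, NA_real_, rs) * 100
  structure(list(counts = counts, row_pct = row_pct),
            class = "remloop_confusion")
}

#' @export
print.remloop_confusion <- function(x, ...) {
  cat("<remloop_confusion> row %, truth x predicted:\n")
  print(round(x$row_pct, 1))
  invisible(x)
}

#' Per-state recall, precision and F1
#'
#' Recall = diagonal / row sum (fraction of true epochs of a state that were
#' predicted as that state), precision = diagonal / column sum, F1 their
#' harmonic mean. Empty denominators yield `NA` (flagged, never silent
#' zeros).
#'
#' @param x a `remloop_confusion`.
#' @return tibble: `state`, `n_true`, `recall`, `precision`, `f1`.
#' @export
recall_f1 <- function(x) {
  stopifnot(inherits(x, "remloop_confusion"))
  cm <- x$counts
  d <- diag(cm); rs <- rowSums(cm); cs <- colSums(cm)
  recall <- ifelse(rs > 0, d / rs, NA_real_)
  precision <- ifelse(cs > 0, d / cs, NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
               2 * recall * precision / (recall + precision), NA_real_)
  tibble::tibble(
    state = factor(vigilance_states(), levels = vigilance_states()),
    n_true = as.integer(rs), recall = unname(recall),
    precision = unname(precision), f1 = unname(f1)
  )
}

#' State occupancy of a hypnogram
#'
#' Percentage of total recording time spent in each vigilance state; the
#' three percentages sum to 100.
#'
#' @param hyp a `remloop_hypnogram` (or a factor of states).
#' @return tibble: `state`, `n_epochs`, `pct`.
#' @export
occupancy <- function(hyp) {
  st <- if (is.data.frame(hyp)) hyp$state else hyp
  st <- state_factor(st)
  if (length(st) == 0) rlang::abort("empty hypnogram")
  n <- tabulate(as.integer(st), nbins = 3)
  tibble::tibble(
    state = factor(vigilance_states(), levels = vigilance_states()),
    n_epochs = n, pct = 100 * n / length(st)
  )
}

#' Baseline-to-deprivation fold change with geometric-mean summary
#'
#' Per-animal fold ratios `baseline_i / rsd_i` (so selective REM suppression
#' yields a large REM ratio), summarized by the geometric mean
#' `exp(mean(log ratio))` with a bias-corrected percentile bootstrap
#' confidence interval on the log ratios. The same baseline/deprivation
#' orientation is used for every state.
#'
#' When an occupancy is zero (an animal with no REM epochs at all during
#' deprivation), `zero_adjust` — half of one epoch's worth of occupancy, in
#' the caller's units — is added to both members of that animal's pair so
#' the ratio stays finite; the adjustment is recorded in the result.
#'
#' @param baseline,rsd paired per-animal occupancy values (same length,
#'   same animal order), typically percentages.
#' @param zero_adjust value added to both members of a pair containing a
#'   zero; 0 (default) makes zeros an error.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed seed for the bootstrap.
#' @return list of class `remloop_fold`: `ratios`, `geometric_mean`,
#'   `ci_lo`, `ci_hi`, `conf`, `n`, `zero_adjusted`.
#' @examples
#' fold_change(c(2, 8), c(1, 1))$geometric_mean  # 4
#' @export
fold_change <- function(baseline, rsd, zero_adjust = 0, n_boot = 10000,
                        conf = 0.95, seed = 1L) {
  if (length(baseline) != length(rsd)) {
    rlang::abort("baseline and rsd must be paired per-animal vectors of equal length")
  }
  zeroed <- baseline <= 0 | rsd <= 0
  if (any(zeroed)) {
    if (zero_adjust <= 0) {
      rlang::abort("zero occupancy encountered; supply a positive zero_adjust")
    }
    baseline[zeroed] <- baseline[zeroed] + zero_adjust
    rsd[zeroed] <- rsd[zeroed] + zero_adjust
  }
  lr <- log(baseline / rsd)
  gm <- exp(mean(lr))
  n <- length(lr)
  if (n < 2 || stats::sd(lr) == 0) {
    ci <- c(gm, gm)
  } else {
    old <- save_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    boot <- vapply(seq_len(n_boot),
                   function(i) mean(lr[sample.int(n, n, replace = TRUE)]),
                   numeric(1))
    # bias-corrected percentile interval
    z0 <- stats::qnorm(mean(boot < mean(lr)))
    a <- (1 - conf) / 2
    lo_p <- stats::pnorm(2 * z0 + stats::qnorm(a))
    hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - a))
    ci <- exp(stats::quantile(boot, c(lo_p, hi_p), names = FALSE))
  }
  structure(
    list(ratios = baseline / rsd, geometric_mean = gm,
         ci_lo = ci[1], ci_hi = ci[2], conf = conf, n = n,
         zero_adjusted = sum(zeroed)),
    class = "remloop_fold"
  )
}

#' @export
print.remloop_fold <- function(x, ...) {
  cat(sprintf("<remloop_fold> GM = %.3g (%.0f%% CI %.3g-%.3g, n = %d%s)\n",
              x$geometric_mean, 100 * x$conf, x$ci_lo, x$ci_hi, x$n,
              if (x$zero_adjusted > 0)
                sprintf(", %d zero-adjusted pair(s)", x$zero_adjusted) else ""))
  invisible(x)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired per-animal values, with the exact
#' null distribution (enumerated by dynamic programming over sign flips) for
#' up to `exact_max` pairs and a normal approximation beyond. Zero
#' differences are handled by the Pratt method: they participate in the
#' ranking of absolute differences but are excluded from the statistic and
#' from the sign flips. Tied absolute differences receive midranks.
#'
#' @param baseline,rsd paired numeric vectors.
#' @param exact_max largest number of informative pairs for which the exact
#'   null is enumerated.
#' @return list: `statistic` (V, sum of positive ranks), `p_value`
#'   (two-sided), `n`, `n_zero`, `method`.
#' @examples
#' wilcoxon_paired(c(8, 7, 6, 5, 9, 8, 7, 6), c(1, 2, 1, 2, 1, 2, 1, 2))$p_value
#' # 2/256 = 0.0078125: all eight differences positive
#' @export
wilcoxon_paired <- function(baseline, rsd, exact_max = 25) {
  if (length(baseline) != length(rsd)) rlang::abort("inputs must be paired")
  d <- baseline - rsd
  if (all(d == 0)) rlang::abort("all differences are zero; test is degenerate")
  r <- rank(abs(d))               # Pratt: zeros included in the ranking
  nz <- d != 0
  r_nz <- r[nz]
  v <- sum(r_nz[d[nz] > 0])
  n_inf <- sum(nz)
  if (n_inf <= exact_max) {
    # exact null over 2^n sign assignments via convolution on doubled ranks
    # (midranks may be half-integers)
    r2 <- as.integer(round(2 * r_nz))
    tot <- sum(r2)
    f <- numeric(tot + 1)
    f[1] <- 1
    for (w in r2) {
      g <- f
      g[(w + 1):(tot + 1)] <- g[(w + 1):(tot + 1)] + f[1:(tot + 1 - w)]
      f <- g
    }
    f <- f / 2^length(r2)
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[1:(v2 + 1)])
    p_ge <- sum(f[(v2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (Pratt)"
  } else {
    # normal approximation with Pratt zero correction and tie correction
    n <- length(d)
    n0 <- n - n_inf
    mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
    ties <- table(r_nz)
    sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (Pratt)"
  }
  list(statistic = v, p_value = p, n = length(d), n_zero = sum(!nz),
       method = method)
}

#' Feature-space export for state-space plots
#'
#' Long-format table of per-epoch theta/delta ratio against EMG RMS, labeled
#' by vigilance state — the two-dimensional state space in which REM forms a
#' distinct high-theta/low-EMG cluster under baseline conditions and empties
#' out under closed-loop deprivation. No statistics are computed.
#'
#' @param features per-epoch feature tibble (needs `epoch_index`,
#'   `r_theta_delta`).
#' @param emg per-epoch EMG tibble from [epoch_emg_rms()] (needs
#'   `epoch_index`, `emg_rms`).
#' @param labels `remloop_hypnogram` for the same epochs.
#' @return tibble: `epoch_index`, `r_theta_delta`, `emg_rms`, `state`.
#' @export
state_space_export <- function(features, emg, labels) {
  f <- tibble::as_tibble(features)[, c("epoch_index", "r_theta_delta")]
  e <- tibble::as_tibble(emg)[, c("epoch_index", "emg_rms")]
  l <- tibble::as_tibble(labels)[, c("epoch_index", "state")]
  if (!setequal(f$epoch_index, e$epoch_index) ||
      !setequal(f$epoch_index, l$epoch_index)) {
    rlang::abort("features, emg and labels must cover the same epochs")
  }
  dplyr::inner_join(f, e, by = "epoch_index") |>
    dplyr::inner_join(l, by = "epoch_index") |>
    dplyr::mutate(state = state_factor(.data$state))
}

#' Cohort efficacy report: occupancy, fold changes, Wilcoxon tests
#'
#' The deprivation-efficacy summary for a cohort: per-animal state occupancy
#' under baseline and deprivation, per-animal baseline-to-deprivation fold
#' ratios per state with geometric means and bootstrap CIs, and a paired
#' Wilcoxon signed-rank test per state. Zero occupancies are adjusted by
#' half of one epoch's worth (see [fold_change()]); the adjustment is
#' reported.
#'
#' @param baseline,rsd named lists (one element per animal, same names and
#'   order) of `remloop_hypnogram` tibbles for the baseline and deprivation
#'   sessions.
#' @param n_boot,conf,seed bootstrap settings passed to [fold_change()].
#' @return object of class `remloop_efficacy`: list with `occupancy`
#'   (per-animal long table), `per_state` (GM, CI, Wilcoxon per state),
#'   `zero_adjust`.
#' @export
efficacy_report <- function(baseline, rsd, n_boot = 10000, conf = 0.95,
                            seed = 1L) {
  if (length(baseline) != length(rsd)) {
    rlang::abort("baseline and rsd must have one session per animal, paired")
  }
  animals <- names(baseline) %||% paste0("animal-", seq_along(baseline))
  names(baseline) <- names(rsd) <- animals
  occ_tbl <- function(sessions, condition) {
    purrr::imap(sessions, function(h, nm) {
      occupancy(h) |> dplyr::mutate(animal = nm, condition = condition)
    }) |> purrr::list_rbind()
  }
  occ <- dplyr::bind_rows(occ_tbl(baseline, "baseline"), occ_tbl(rsd, "rsd"))
  # smallest observable occupancy: half of one epoch, per the shortest session
  min_ep <- min(vapply(c(baseline, rsd), nrow, integer(1)))
  zero_adjust <- 0.5 * 100 / min_ep
  wide <- occ |>
    dplyr::select("state", "animal", "condition", "pct") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "pct")
  per_state <- wide |>
    dplyr::group_by(.data$state) |>
    dplyr::group_modify(function(g, key) {
      fc <- fold_change(g$baseline, g$rsd,
                        zero_adjust = if (any(g$baseline <= 0 | g$rsd <= 0)) zero_adjust else 0,
                        n_boot = n_boot, conf = conf, seed = seed)
      wt <- tryCatch(wilcoxon_paired(g$baseline, g$rsd),
                     error = function(e) list(statistic = NA_real_, p_value = NA_real_))
      tibble::tibble(
        n_animals = length(g$baseline),
        mean_baseline_pct = mean(g$baseline), sd_baseline_pct = stats::sd(g$baseline),
        mean_rsd_pct = mean(g$rsd), sd_rsd_pct = stats::sd(g$rsd),
        fold_gm = fc$geometric_mean, fold_ci_lo = fc$ci_lo,
        fold_ci_hi = fc$ci_hi, zero_adjusted = fc$zero_adjusted,
        wilcoxon_v = wt$statistic, p_value = wt$p_value
      )
    }) |>
    dplyr::ungroup()
  structure(
    list(occupancy = occ, per_state = per_state, zero_adjust = zero_adjust,
         conf = conf),
    class = "remloop_efficacy"
  )
}

#' @export
print.remloop_efficacy <- function(x, ...) {
  cat("<remloop_efficacy> baseline-to-RSD fold change (geometric mean):\n")
  print(as.data.frame(x$per_state[, c("state", "mean_baseline_pct", "mean_rsd_pct",
                                      "fold_gm", "fold_ci_lo", "fold_ci_hi",
                                      "p_value")]), digits = 3, row.names = FALSE)
  invisible(x)
}
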