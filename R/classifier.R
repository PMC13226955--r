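#' Threshold-based vigilance-state classification
#'
#' The decision rule applied at every 100 ms control cycle, as a total,
#' mutually exclusive partition of the feature plane:
#' \itemize{
#'   \item Wake if \eqn{R_{HF} \ge \tau_{HF}} (regardless of the
#'     theta/delta ratio: elevated high-frequency power, including movement
#'     artifact, always reads as wakefulness);
#'   \item otherwise REM if \eqn{R_{\theta/\delta} \ge \tau_{\theta/\delta}};
#'   \item otherwise NREM.
#' }
#' Undefined features (degenerate denominators, warmup) are classified Wake
#' with `undefined = TRUE` — the fail-safe that never stimulates on garbage.
#'
#' `classify()` is vectorized: it accepts a feature tibble (one row per
#' window/epoch) and returns a factor of the same length.
#'
#' @param features a tibble with columns `r_theta_delta`, `r_hf` and
#'   optionally `undefined`, or a numeric length-2 vector
#'   `c(r_theta_delta, r_hf)`.
#' @param thresholds a `remloop_thresholds` (or list with `tau_theta_delta`,
#'   `tau_hf`).
#' @return factor of states with levels REM, Wake, NREM.
#' @examples
#' th <- list(tau_theta_delta = 1.5, tau_hf = 0.05)
#' classify(tibble::tibble(r_theta_delta = c(2, 3, 1), r_hf = c(.01, .06, .01)), th)
#' @export
classify <- function(features, thresholds) {
  if (is.numeric(features) && length(features) == 2) {
    features <- tibble::tibble(r_theta_delta = features[1], r_hf = features[2])
  }
  r_td <- features$r_theta_delta
  r_hf <- features$r_hf
  undef <- if ("undefined" %in% names(features)) features$undefined else FALSE
  undef <- undef | !is.finite(r_td) | !is.finite(r_hf)
  code <- ifelse(undef, 2L,                                  # fail-safe Wake
          ifelse(r_hf >= thresholds$tau_hf, 2L,              # Wake
          ifelse(r_td >= thresholds$tau_theta_delta, 1L,     # REM
                 3L)))                                       # NREM
  code_state(code)
}

#' Majority vote over the 25 decisions of one epoch
#'
#' Each 2.5 s epoch contains 25 classifier outputs (one per 100 ms cycle);
#' the epoch label is the modal state. Ties are broken by the fixed priority
#' REM > NREM > Wake: in a deprivation device the costly error is missing
#' REM, so ambiguous epochs lean toward the target state.
#'
#' @param decisions vector of exactly `n` states (factor/character/codes).
#' @param n required number of decisions per epoch.
#' @return a length-1 factor.
#' @export
majority_vote <- function(decisions, n = 25) {
  if (length(decisions) != n) {
    rlang::abort(sprintf("majority_vote() requires exactly %d decisions (got %d)",
                         n, length(decisions)))
  }
  st <- state_factor(decisions)
  counts <- tabulate(as.integer(st), nbins = 3)
  # priority on ties: REM (1) > NREM (3) > Wake (2)
  priority <- c(1L, 3L, 2L)
  winner <- priority[which.max(counts[priority])]
  code_state(winner)
}

#' Aggregate a 10 Hz decision stream into a 2.5 s epoch hypnogram
#'
#' Groups consecutive decisions into complete epochs (25 decisions per epoch
#' at the default rates), applies the majority vote to each, and drops any
#' trailing partial epoch. Output is aligned to the session start and uses
#' the same schema as ground-truth hypnograms so the two can be compared
#' directly.
#'
#' @param decisions vector of per-cycle states, in time order, at
#'   `step_s` spacing.
#' @param epoch_s epoch duration in seconds.
#' @param step_s decision interval in seconds.
#' @return a `remloop_hypnogram`.
#' @examples
#' epochize(rep("NREM", 260))  # 10 epochs; trailing 10 decisions dropped
#' @export
epochize <- function(decisions, epoch_s = 2.5, step_s = 0.1) {
  k <- epoch_s / step_s
  if (abs(k - round(k)) > 1e-9) rlang::abort("epoch_s must be an integer multiple of step_s")
  k <- as.integer(round(k))
  st <- state_factor(decisions)
  n_ep <- length(st) %/% k
  if (n_ep == 0) return(hypnogram(character(0), epoch_s = epoch_s))
  labels <- vapply(seq_len(n_ep), function(i) {
    as.integer(majority_vote(st[((i - 1) * k + 1):(i * k)], n = k))
  }, integer(1))
  hypnogram(code_state(labels), epoch_s = epoch_s)
}
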