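#' Per-state feature statistics from a labeled baseline recording
#'
#' For every vigilance state present in the labels, the number of epochs and
#' the mean and sample SD (`n - 1` denominator) of both spectral features
#' over exactly the epochs carrying that label. Epochs with undefined
#' features are dropped; epochs recorded during active shaking must be
#' excluded upstream (thresholds are estimated from undisturbed baseline
#' only).
#'
#' @param features per-epoch feature tibble as from [epoch_features()],
#'   aligned 1:1 with `labels` on `epoch_index`.
#' @param labels a `remloop_hypnogram` (or tibble with `epoch_index`,
#'   `state`).
#' @param require character vector of states that must have at least
#'   `min_epochs` epochs; the Eq.-style thresholds need REM and NREM.
#' @param min_epochs minimum epochs per required state (an SD needs 2).
#' @return tibble of class `remloop_state_stats`: `state`, `n_epochs`,
#'   `mean_r_theta_delta`, `sd_r_theta_delta`, `mean_r_hf`, `sd_r_hf`.
#' @export
state_feature_stats <- function(features, labels,
                                require = c("REM", "NREM"),
                                min_epochs = 2) {
  if (!all(c("epoch_index", "r_theta_delta", "r_hf") %in% names(features))) {
    rlang::abort("features must have epoch_index, r_theta_delta, r_hf")
  }
  lab <- tibble::as_tibble(labels)[, c("epoch_index", "state")]
  joined <- dplyr::inner_join(tibble::as_tibble(features), lab, by = "epoch_index")
  if (nrow(joined) != nrow(features) || nrow(joined) != nrow(lab)) {
    rlang::abort("features and labels must align 1:1 on epoch_index")
  }
  usable <- dplyr::filter(joined, is.finite(.data$r_theta_delta), is.finite(.data$r_hf))
  stats <- usable |>
    dplyr::group_by(state = factor(.data$state, levels = vigilance_states())) |>
    dplyr::summarise(
      n_epochs = dplyr::n(),
      mean_r_theta_delta = mean(.data$r_theta_delta),
      sd_r_theta_delta = stats::sd(.data$r_theta_delta),
      mean_r_hf = mean(.data$r_hf),
      sd_r_hf = stats::sd(.data$r_hf),
      .groups = "drop"
    )
  for (s in require) {
    n_s <- stats$n_epochs[stats$state == s]
    if (length(n_s) == 0 || n_s < min_epochs) {
      rlang::abort(sprintf(
        "calibration requires >= %d %s epochs with defined features (found %d)",
        min_epochs, s, if (length(n_s)) n_s else 0L))
    }
  }
  class(stats) <- c("remloop_state_stats", class(stats))
  stats
}

#' Per-animal classification thresholds
#'
#' The two decision boundaries of the threshold classifier, derived from the
#' baseline feature statistics:
#' \deqn{\tau_{\theta/\delta} = \mathrm{mean}(R_{\theta/\delta}^{REM}) -
#'       \mathrm{sd}(R_{\theta/\delta}^{REM})}
#' \deqn{\tau_{HF} = \mathrm{mean}(R_{HF}^{NREM}) +
#'       \mathrm{sd}(R_{HF}^{NREM})}
#' i.e. the REM theta/delta threshold sits one SD below the REM mean and the
#' high-frequency Wake threshold one SD above the NREM mean, compensating
#' for inter-animal variability in signal amplitude and electrode impedance.
#'
#' @param stats a `remloop_state_stats` (needs REM and NREM rows).
#' @param animal_id identifier stored with the thresholds.
#' @return object of class `remloop_thresholds`: list with
#'   `tau_theta_delta`, `tau_hf`, `animal_id`, `source_stats`.
#' @examples
#' s <- tibble::tibble(
#'   state = factor(c("REM", "NREM"), levels = vigilance_states()),
#'   n_epochs = c(3L, 3L),
#'   mean_r_theta_delta = c(2.0, 0.3), sd_r_theta_delta = c(0.2, 0.1),
#'   mean_r_hf = c(0.01, 0.05), sd_r_hf = c(0.005, 0.01)
#' )
#' class(s) <- c("remloop_state_stats", class(s))
#' estimate_thresholds(s)  # tau_theta_delta 1.8, tau_hf 0.06
#' @export
estimate_thresholds <- function(stats, animal_id = "animal") {
  stopifnot(inherits(stats, "remloop_state_stats") || is.data.frame(stats))
  rem <- stats[stats$state == "REM", ]
  nrem <- stats[stats$state == "NREM", ]
  if (nrow(rem) != 1 || nrow(nrem) != 1) {
    rlang::abort("threshold estimation needs REM and NREM statistics")
  }
  tau_td <- rem$mean_r_theta_delta - rem$sd_r_theta_delta
  tau_hf <- nrem$mean_r_hf + nrem$sd_r_hf
  if (!is.finite(tau_td) || !is.finite(tau_hf)) {
    rlang::abort("non-finite feature statistics; cannot estimate thresholds")
  }
  structure(
    list(animal_id = animal_id, tau_theta_delta = tau_td, tau_hf = tau_hf,
         source_stats = tibble::as_tibble(stats)),
    class = "remloop_thresholds"
  )
}

#' @export
print.remloop_thresholds <- function(x, ...) {
  cat(sprintf("<remloop_thresholds> %s: tau_theta_delta = %.4g, tau_hf = %.4g\n",
              x$animal_id, x$tau_theta_delta, x$tau_hf))
  invisible(x)
}

#' Validate calibrated thresholds on a held-out labeled session
#'
#' Classifies the held-out per-epoch features with the calibrated thresholds
#' and compares per-state recall against a configured acceptance gate;
#' closed-loop operation should proceed only when the gate passes. Errors
#' rather than silently passing when a gated state is absent from the
#' validation labels.
#'
#' @param features per-epoch features of the validation session.
#' @param labels ground-truth `remloop_hypnogram` for the same session.
#' @param thresholds a `remloop_thresholds`.
#' @param gate named numeric: minimum recall per state. The gate values are
#'   configuration, not constants of the method.
#' @return tibble of class `remloop_gate`: `state`, `n_true`, `n_correct`,
#'   `recall`, `gate`, `pass`; attribute `passed` gives the overall verdict.
#' @export
validate_thresholds <- function(features, labels, thresholds,
                                gate = c(REM = 0.8, Wake = 0.7, NREM = 0.8)) {
  if (nrow(features) == 0) rlang::abort("empty validation session")
  pred <- classify(features, thresholds)
  lab <- tibble::as_tibble(labels)
  truth <- state_factor(lab$state[match(features$epoch_index, lab$epoch_index)])
  if (anyNA(truth)) rlang::abort("validation labels do not cover all feature epochs")
  out <- tibble::tibble(state = factor(names(gate), levels = vigilance_states()),
                        gate = unname(gate)) |>
    dplyr::arrange(.data$state) |>
    dplyr::mutate(
      n_true = vapply(as.character(.data$state), function(s) sum(truth == s),
                      integer(1), USE.NAMES = FALSE),
      n_correct = vapply(as.character(.data$state),
                         function(s) sum(truth == s & pred == s),
                         integer(1), USE.NAMES = FALSE),
      recall = .data$n_correct / .data$n_true
    ) |>
    dplyr::relocate("gate", .after = "recall") |>
    dplyr::mutate(pass = .data$recall >= .data$gate)
  if (any(out$n_true == 0)) {
    rlang::abort(paste0("validation session has no epochs of state(s): ",
                        paste(out$state[out$n_true == 0], collapse = ", ")))
  }
  attr(out, "passed") <- all(out$pass)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("remloop_gate", class(out))
  out
}

#' Calibrate an animal end to end from a labeled baseline recording
#'
#' Convenience wrapper: per-epoch features of the baseline EEG, per-state
#' statistics, thresholds. Returns the thresholds with the feature table
#' attached.
#'
#' @param eeg baseline EEG `remloop_trace`.
#' @param labels ground-truth `remloop_hypnogram` for the baseline.
#' @param animal_id identifier.
#' @inheritParams epoch_features
#' @return a `remloop_thresholds` (with attribute `features`).
#' @export
calibrate_animal <- function(eeg, labels, animal_id = "animal",
                             fs = 1000, epoch_s = 2.5) {
  feats <- epoch_features(eeg, fs = fs, epoch_s = epoch_s)
  st <- state_feature_stats(feats, labels)
  th <- estimate_thresholds(st, animal_id = animal_id)
  attr(th, "features") <- feats
  th
}
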