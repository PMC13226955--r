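#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidiers for remloop result objects
#'
#' `tidy()` returns one row per component (per state, per animal, per
#' event); `glance()` returns a one-row summary.
#'
#' @param x a remloop result object.
#' @param ... unused.
#' @return a tibble.
#' @name remloop-tidiers
NULL

#' @rdname remloop-tidiers
#' @export
tidy.remloop_thresholds <- function(x, ...) {
  tibble::as_tibble(x$source_stats)
}

#' @rdname remloop-tidiers
#' @export
glance.remloop_thresholds <- function(x, ...) {
  tibble::tibble(animal_id = x$animal_id,
                 tau_theta_delta = x$tau_theta_delta, tau_hf = x$tau_hf)
}

#' @rdname remloop-tidiers
#' @export
tidy.remloop_confusion <- function(x, ...) {
  tibble::as_tibble(as.table(x$counts)) |>
    dplyr::mutate(
      truth = factor(.data$truth, levels = vigilance_states()),
      predicted = factor(.data$predicted, levels = vigilance_states())
    ) |>
    dplyr::group_by(.data$truth) |>
    dplyr::mutate(row_pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n)
                  else NA_real_) |>
    dplyr::ungroup()
}

#' @rdname remloop-tidiers
#' @export
glance.remloop_confusion <- function(x, ...) {
  m <- recall_f1(x)
  tibble::tibble(
    n_epochs = sum(x$counts),
    accuracy = sum(diag(x$counts)) / sum(x$counts),
    macro_recall = mean(m$recall, na.rm = TRUE),
    macro_f1 = mean(m$f1, na.rm = TRUE)
  )
}

#' @rdname remloop-tidiers
#' @export
tidy.remloop_fold <- function(x, ...) {
  tibble::tibble(animal = seq_along(x$ratios), ratio = x$ratios)
}

#' @rdname remloop-tidiers
#' @export
glance.remloop_fold <- function(x, ...) {
  tibble::tibble(geometric_mean = x$geometric_mean, ci_lo = x$ci_lo,
                 ci_hi = x$ci_hi, conf = x$conf, n = x$n,
                 zero_adjusted = x$zero_adjusted)
}

#' @rdname remloop-tidiers
#' @export
tidy.remloop_efficacy <- function(x, ...) {
  x$per_state
}

#' @rdname remloop-tidiers
#' @export
glance.remloop_efficacy <- function(x, ...) {
  rem <- x$per_state[x$per_state$state == "REM", ]
  tibble::tibble(
    n_animals = rem$n_animals,
    rem_baseline_pct = rem$mean_baseline_pct,
    rem_rsd_pct = rem$mean_rsd_pct,
    rem_fold_gm = rem$fold_gm,
    rem_p_value = rem$p_value
  )
}

#' @rdname remloop-tidiers
#' @export
tidy.remloop_session <- function(x, ...) {
  x$epochs
}

#' @rdname remloop-tidiers
#' @export
glance.remloop_session <- function(x, ...) {
  occ <- occupancy(x$epochs$truth)
  tibble::tibble(
    animal_id = x$config$animal_id,
    n_cycles = nrow(x$cycles),
    duration_s = max(x$cycles$time_s),
    rem_pct = occ$pct[occ$state == "REM"],
    wake_pct = occ$pct[occ$state == "Wake"],
    nrem_pct = occ$pct[occ$state == "NREM"],
    trigger_high_pct = 100 * mean(x$cycles$trigger == "high"),
    n_trigger_events = sum(x$events$event == "TRIGGER_HIGH"),
    clipped = x$clipped,
    termination = x$termination
  )
}

#' @rdname remloop-tidiers
#' @export
tidy.remloop_gate <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname remloop-tidiers
#' @export
glance.remloop_gate <- function(x, ...) {
  tibble::tibble(passed = attr(x, "passed"), min_recall = min(x$recall))
}
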