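#' Simulate a full deprivation study on a cohort of virtual animals
#'
#' The complete experimental workflow, one virtual animal at a time:
#' (1) a baseline recording without actuation, used to calibrate the
#' per-animal thresholds; (2) a separate labeled validation session, scored
#' by the calibrated classifier and gated on per-state recall; (3) a
#' closed-loop deprivation session. Per-animal state occupancy is computed
#' from the ground-truth baseline hypnogram and the plant-truth epochs of
#' the closed-loop session, and summarized as baseline-to-deprivation fold
#' changes with geometric means, bootstrap CIs and paired Wilcoxon tests.
#' The validation sessions are pooled into a cohort confusion matrix.
#'
#' Each animal gets its own jittered model (inter-animal variability in
#' signal amplitude) and its own seed stream derived from `seed`.
#'
#' Baseline occupancy is measured on a full 24 h ground-truth hypnogram (the
#' baseline duration of the underlying protocol); continuous signals are only
#' materialized for the calibration and validation slices, whose length is
#' extended automatically (in whole epochs) until they contain enough REM and
#' NREM epochs for stable statistics — mirroring the practice of acquiring
#' additional baseline data when a session under-samples a state.
#'
#' @param n_animals number of virtual animals.
#' @param baseline_s baseline hypnogram length in seconds (occupancy
#'   reference).
#' @param calib_min_s minimum length of the synthesized calibration slice.
#' @param validation_min_s minimum length of the held-out validation session.
#' @param session_s closed-loop deprivation session length in seconds.
#' @param min_state_epochs named vector: minimum REM/NREM epochs a
#'   calibration or validation slice must contain before it is used.
#' @param seed master seed; animal `i` uses `seed + 1000 * i` offsets.
#' @param arousal_prob per-cycle arousal probability of every animal.
#' @param gate per-state minimum recall for the validation gate.
#' @return object of class `remloop_cohort`: list with `animals` (per-animal
#'   tibble: thresholds, gate verdict, occupancies), `confusion` (pooled
#'   `remloop_confusion`), `recall` (per-state pooled recall/F1), `efficacy`
#'   (a `remloop_efficacy`), and `session_glances`.
#' @examples
#' \donttest{
#' cohort <- simulate_deprivation_cohort(n_animals = 2, session_s = 900,
#'                                       calib_min_s = 1800,
#'                                       validation_min_s = 900, seed = 1)
#' tidy(cohort$efficacy)
#' }
#' @export
simulate_deprivation_cohort <- function(n_animals = 8,
                                        baseline_s = 86400,
                                        calib_min_s = 5400,
                                        validation_min_s = 5400,
                                        session_s = 5400,
                                        min_state_epochs = c(REM = 50, NREM = 200),
                                        seed = 1L,
                                        arousal_prob = 0.4,
                                        gate = c(REM = 0.8, Wake = 0.7, NREM = 0.8)) {
  seed <- as.integer(seed)
  animals <- sprintf("animal-%02d", seq_len(n_animals))
  rows <- vector("list", n_animals)
  base_hyps <- rsd_hyps <- stats::setNames(vector("list", n_animals), animals)
  cms <- vector("list", n_animals)
  glances <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    s0 <- (seed + 1000L * i) %% .Machine$integer.max
    model <- default_animal_model(animals[i], arousal_prob = arousal_prob,
                                  seed = s0)
    # (1) 24 h baseline; calibrate on an adequately sampled leading slice
    h_base <- generate_hypnogram(model, baseline_s, seed = s0 + 1L)
    h_cal <- adequate_slice(h_base, calib_min_s, min_state_epochs)
    sig <- synthesize_signals(h_cal, model, seed = s0 + 1L)
    th <- calibrate_animal(sig$eeg, h_cal, animal_id = animals[i])
    # (2) held-out validation session, gated
    h_val_full <- generate_hypnogram(model, baseline_s, seed = s0 + 2L)
    h_val <- adequate_slice(h_val_full, validation_min_s, min_state_epochs)
    sig_val <- synthesize_signals(h_val, model, seed = s0 + 2L)
    f_val <- epoch_features(sig_val$eeg)
    gate_res <- validate_thresholds(f_val, h_val, th, gate = gate)
    pred_val <- classify(f_val, th)
    cms[[i]] <- table(truth = h_val$state, predicted = pred_val)
    # (3) closed-loop deprivation
    sess <- run_control_loop(model, th, session_s, seed = s0 + 3L,
                             run_self_check = (i == 1L))
    base_hyps[[i]] <- h_base
    rsd_hyps[[i]] <- hypnogram(sess$epochs$truth,
                               epoch_s = epoch_duration(h_base))
    glances[[i]] <- glance(sess)
    occ_b <- occupancy(h_base)
    occ_r <- occupancy(rsd_hyps[[i]])
    rows[[i]] <- tibble::tibble(
      animal = animals[i],
      tau_theta_delta = th$tau_theta_delta, tau_hf = th$tau_hf,
      calib_s = nrow(h_cal) * epoch_duration(h_cal),
      gate_passed = attr(gate_res, "passed"),
      rem_recall = gate_res$recall[gate_res$state == "REM"],
      baseline_rem_pct = occ_b$pct[occ_b$state == "REM"],
      rsd_rem_pct = occ_r$pct[occ_r$state == "REM"]
    )
  }
  pooled <- Reduce(`+`, lapply(cms, function(x) matrix(as.integer(x), 3, 3)))
  dimnames(pooled) <- list(truth = vigilance_states(),
                           predicted = vigilance_states())
  rs <- rowSums(pooled)
  confusion <- structure(
    list(counts = pooled,
         row_pct = pooled / ifelse(rs == 0, NA_real_, rs) * 100),
    class = "remloop_confusion"
  )
  structure(
    list(
      animals = purrr::list_rbind(rows),
      confusion = confusion,
      recall = recall_f1(confusion),
      efficacy = efficacy_report(base_hyps, rsd_hyps, seed = seed),
      session_glances = purrr::list_rbind(glances)
    ),
    class = "remloop_cohort"
  )
}

# Leading slice of a hypnogram, at least min_s long, extended in whole
# epochs until every required state has its minimum epoch count (or the
# hypnogram is exhausted, in which case calibration will error loudly).
adequate_slice <- function(hyp, min_s, min_state_epochs) {
  epoch_s <- epoch_duration(hyp)
  k <- min(nrow(hyp), ceiling(min_s / epoch_s))
  repeat {
    counts <- table(factor(hyp$state[seq_len(k)], levels = vigilance_states()))
    if (all(counts[names(min_state_epochs)] >= min_state_epochs) ||
        k >= nrow(hyp)) break
    k <- min(nrow(hyp), k + ceiling(600 / epoch_s))  # extend by 10 min
  }
  hypnogram(hyp$state[seq_len(k)], epoch_s = epoch_s)
}

#' @export
print.remloop_cohort <- function(x, ...) {
  cat(sprintf("<remloop_cohort> %d animals, %d/%d passed the validation gate\n",
              nrow(x$animals), sum(x$animals$gate_passed), nrow(x$animals)))
  cat("pooled per-state recall: ",
      paste(sprintf("%s %.1f%%", x$recall$state, 100 * x$recall$recall),
            collapse = ", "), "\n", sep = "")
  print(x$efficacy)
  invisible(x)
}
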