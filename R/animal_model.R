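#' Virtual-animal model for synthetic EEG/EMG generation
#'
#' An `animal_model` bundles everything the synthetic-data generator needs to
#' act as a "virtual mouse": per-state EEG spectral profiles, per-state EMG
#' amplitude, Markov state dynamics at the 2.5 s epoch scale, the probability
#' that active shaking terminates a REM bout, and the amplitude of the
#' movement artifact injected while the platform is in motion.
#'
#' Each per-state EEG profile is a sum of narrowband oscillators (tibble with
#' columns `freq_hz`, `bw_hz`, `amp_mv`; `amp_mv` is the RMS amplitude of the
#' component) over a background made of an AR(1) low-frequency process
#' (`ar1_mv`, RMS) and a white broadband floor (`white_mv`, RMS).
#'
#' @param state_profiles named list (`REM`, `Wake`, `NREM`) of lists with
#'   elements `tones` (data frame `freq_hz, bw_hz, amp_mv`), `ar1_mv`,
#'   `white_mv`.
#' @param emg_rms named numeric, per-state EMG RMS amplitude in mV.
#' @param transition_matrix 3x3 row-stochastic matrix of per-epoch (2.5 s)
#'   transition probabilities, rows/cols ordered REM, Wake, NREM.
#' @param arousal_prob probability per 100 ms control cycle that active
#'   stimulation terminates an ongoing REM bout (in `[0, 1]`).
#' @param artifact_hf_gain RMS amplitude (mV) of the band-limited 90-200 Hz
#'   motion artifact added to the EEG while the actuator is moving.
#' @param animal_id identifier carried into downstream logs and reports.
#' @return an object of class `remloop_model`.
#' @seealso [default_animal_model()], [generate_hypnogram()],
#'   [synthesize_signals()]
#' @export
animal_model <- function(state_profiles,
                         emg_rms,
                         transition_matrix,
                         arousal_prob = 0.4,
                         artifact_hf_gain = 0.1,
                         animal_id = "animal") {
  states <- vigilance_states()
  if (!setequal(names(state_profiles), states)) {
    rlang::abort("state_profiles must be a named list with elements REM, Wake, NREM")
  }
  state_profiles <- state_profiles[states]
  for (s in states) {
    p <- state_profiles[[s]]
    p$tones <- tibble::as_tibble(p$tones)
    if (!all(c("freq_hz", "bw_hz", "amp_mv") %in% names(p$tones))) {
      rlang::abort(paste0("profile for ", s, " lacks tone columns freq_hz, bw_hz, amp_mv"))
    }
    if (any(p$tones$amp_mv < 0) || p$ar1_mv < 0 || p$white_mv < 0) {
      rlang::abort(paste0("profile amplitudes for ", s, " must be >= 0"))
    }
    state_profiles[[s]] <- p
  }
  if (!setequal(names(emg_rms), states)) {
    rlang::abort("emg_rms must be named with REM, Wake, NREM")
  }
  if (any(emg_rms < 0)) rlang::abort("emg_rms must be >= 0")
  transition_matrix <- as.matrix(transition_matrix)
  check_stochastic(transition_matrix)
  dimnames(transition_matrix) <- list(states, states)
  if (!is.numeric(arousal_prob) || arousal_prob < 0 || arousal_prob > 1) {
    rlang::abort("arousal_prob must be in [0, 1]")
  }
  if (artifact_hf_gain < 0) rlang::abort("artifact_hf_gain must be >= 0")
  structure(
    list(
      animal_id = animal_id,
      state_profiles = state_profiles,
      emg_rms = emg_rms[states],
      transition_matrix = transition_matrix,
      arousal_prob = arousal_prob,
      artifact_hf_gain = artifact_hf_gain
    ),
    class = "remloop_model"
  )
}

check_stochastic <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || !all(dim(P) == c(3, 3))) {
    rlang::abort("transition_matrix must be 3x3 (REM, Wake, NREM)")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > tol)) {
    rlang::abort("transition_matrix rows must be non-negative and sum to 1 (+/- 1e-9)")
  }
  invisible(P)
}

#' Default virtual mouse
#'
#' The default model is tuned so that (i) the Markov chain's stationary
#' occupancy is exactly (REM 7 %, Wake 45 %, NREM 48 %) with a mean REM bout
#' of 75 s, and (ii) per-epoch features fall in physiologically plausible
#' ranges (REM theta/delta ratio of a few units against NREM a few tenths;
#' Wake high-frequency fraction well above both sleep states).
#'
#' @param animal_id identifier for the simulated animal.
#' @param arousal_prob,artifact_hf_gain override the defaults documented in
#'   [animal_model()].
#' @param seed optional; if supplied, tone amplitudes and EMG levels are
#'   jittered (+/- ~15 %, lognormal) so a cohort of animals differs, the way
#'   electrode impedance varies between real mice.
#' @return a `remloop_model`.
#' @examples
#' m <- default_animal_model()
#' stationary_distribution(m$transition_matrix)
#' @export
default_animal_model <- function(animal_id = "animal-01",
                                 arousal_prob = 0.4,
                                 artifact_hf_gain = 0.1,
                                 seed = NULL) {
  profiles <- list(
    REM = list(
      tones = tibble::tibble(freq_hz = 6, bw_hz = 1.5, amp_mv = 0.14),
      ar1_mv = 0.08, white_mv = 0.006
    ),
    Wake = list(
      tones = tibble::tibble(freq_hz = 7.5, bw_hz = 2, amp_mv = 0.05),
      ar1_mv = 0.04, white_mv = 0.09
    ),
    NREM = list(
      tones = tibble::tibble(
        freq_hz = c(2, 6), bw_hz = c(1.5, 1), amp_mv = c(0.16, 0.03)
      ),
      ar1_mv = 0.05, white_mv = 0.012
    )
  )
  emg <- c(REM = 0.01, Wake = 0.15, NREM = 0.03)
  if (!is.null(seed)) {
    old <- save_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    jit <- function(x) x * exp(stats::rnorm(length(x), 0, 0.15))
    for (s in names(profiles)) {
      profiles[[s]]$tones$amp_mv <- jit(profiles[[s]]$tones$amp_mv)
      profiles[[s]]$ar1_mv <- jit(profiles[[s]]$ar1_mv)
      profiles[[s]]$white_mv <- jit(profiles[[s]]$white_mv)
    }
    emg <- jit(emg)
    names(emg) <- c("REM", "Wake", "NREM")
  }
  animal_model(
    state_profiles = profiles,
    emg_rms = emg,
    transition_matrix = default_transition_matrix(),
    arousal_prob = arousal_prob,
    artifact_hf_gain = artifact_hf_gain,
    animal_id = animal_id
  )
}

#' Default per-epoch transition matrix
#'
#' Solved from target stationary occupancy (REM 0.07, Wake 0.45, NREM 0.48)
#' together with a mean REM bout of 75 s (30 epochs of 2.5 s), REM exiting
#' exclusively to Wake, REM entered exclusively from NREM, and an NREM-to-Wake
#' rate giving NREM bouts of roughly 2.5 min. Global balance then fixes the
#' remaining rates.
#'
#' @param epoch_s epoch duration in seconds (the rates are per epoch).
#' @return 3x3 row-stochastic matrix, rows/cols REM, Wake, NREM.
#' @export
default_transition_matrix <- function(epoch_s = 2.5) {
  pi_t <- c(REM = 0.07, Wake = 0.45, NREM = 0.48)
  p_rw <- epoch_s / 75            # REM -> Wake: mean REM bout 75 s
  p_nw <- 0.01                    # NREM -> Wake
  p_nr <- pi_t["REM"] * p_rw / pi_t["NREM"]                 # balance REM
  p_wn <- (pi_t["REM"] * p_rw + pi_t["NREM"] * p_nw) / pi_t["Wake"] # balance Wake
  P <- rbind(
    REM  = c(1 - p_rw, p_rw, 0),
    Wake = c(0, 1 - p_wn, p_wn),
    NREM = c(p_nr, p_nw, 1 - p_nr - p_nw)
  )
  colnames(P) <- vigilance_states()
  unname_attr(P)
}

unname_attr <- function(P) {
  dimnames(P) <- list(vigilance_states(), vigilance_states())
  P
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Computed from the left eigenvector of the transition matrix associated
#' with eigenvalue 1 (via `eigen()` of the transpose), normalized to sum to
#' one.
#'
#' @param P 3x3 row-stochastic matrix.
#' @return named numeric vector of stationary probabilities (REM, Wake, NREM).
#' @export
stationary_distribution <- function(P) {
  check_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, vigilance_states())
}

#' @export
print.remloop_model <- function(x, ...) {
  cat("<remloop_model> ", x$animal_id, "\n", sep = "")
  occ <- stationary_distribution(x$transition_matrix)
  cat("  stationary occupancy: ",
      paste(sprintf("%s %.1f%%", names(occ), 100 * occ), collapse = ", "), "\n", sep = "")
  cat("  arousal_prob per cycle: ", x$arousal_prob,
      "; artifact 90-200 Hz RMS: ", x$artifact_hf_gain, " mV\n", sep = "")
  invisible(x)
}

#' Read / write an animal model as YAML or JSON
#'
#' @param model a `remloop_model`.
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `read_animal_model()` returns a `remloop_model`;
#'   `write_animal_model()` returns `path` invisibly.
#' @export
write_animal_model <- function(model, path) {
  stopifnot(inherits(model, "remloop_model"))
  x <- list(
    animal_id = model$animal_id,
    state_profiles = lapply(model$state_profiles, function(p) {
      list(tones = as.list(as.data.frame(p$tones)), ar1_mv = p$ar1_mv, white_mv = p$white_mv)
    }),
    emg_rms = as.list(model$emg_rms),
    transition_matrix = apply(model$transition_matrix, 1, as.list, simplify = FALSE),
    arousal_prob = model$arousal_prob,
    artifact_hf_gain = model$artifact_hf_gain
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_animal_model
#' @export
read_animal_model <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  P <- t(vapply(vigilance_states(), function(s) unlist(x$transition_matrix[[s]]), numeric(3)))
  animal_model(
    state_profiles = lapply(x$state_profiles, function(p) {
      list(tones = tibble::as_tibble(lapply(p$tones, unlist)),
           ar1_mv = p$ar1_mv, white_mv = p$white_mv)
    }),
    emg_rms = unlist(x$emg_rms),
    transition_matrix = P,
    arousal_prob = x$arousal_prob,
    artifact_hf_gain = x$artifact_hf_gain,
    animal_id = x$animal_id %||% "animal"
  )
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
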