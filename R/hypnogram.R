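#' Hypnogram objects
#'
#' A hypnogram is a sequence of vigilance-state labels at a fixed epoch
#' duration, stored as a tibble with one row per epoch and columns
#' `epoch_index` (0-based), `start_s`, `state` (factor REM/Wake/NREM) and
#' `state_code` (1 = REM, 2 = Wake, 3 = NREM). Epoch `i` covers the half-open
#' interval `[start_time + i * epoch_s, start_time + (i + 1) * epoch_s)`.
#' Both ground-truth (generator) and classifier-output hypnograms use this
#' representation, so they can be compared row by row.
#'
#' @param states factor/character/integer vector of states.
#' @param epoch_s epoch duration in seconds (> 0).
#' @param start_time session start time in seconds.
#' @return a tibble of class `remloop_hypnogram`.
#' @export
hypnogram <- function(states, epoch_s = 2.5, start_time = 0) {
  if (!is.numeric(epoch_s) || epoch_s <= 0) rlang::abort("epoch_s must be > 0")
  st <- state_factor(states)
  if (anyNA(st)) rlang::abort("hypnogram labels must all be valid states")
  out <- tibble::tibble(
    epoch_index = seq_along(st) - 1L,
    start_s = start_time + (seq_along(st) - 1L) * epoch_s,
    state = st,
    state_code = state_code(st)
  )
  attr(out, "epoch_s") <- epoch_s
  attr(out, "start_time") <- start_time
  class(out) <- c("remloop_hypnogram", class(out))
  out
}

#' @rdname hypnogram
#' @param x object to query.
#' @export
epoch_duration <- function(x) {
  e <- attr(x, "epoch_s", exact = TRUE)
  if (is.null(e) && is.data.frame(x) && nrow(x) > 1) e <- diff(x$start_s[1:2])
  if (is.null(e)) rlang::abort("cannot determine epoch duration")
  e
}

#' Generate a ground-truth hypnogram from the animal's Markov chain
#'
#' Realizes the model's per-epoch Markov chain: the initial state is drawn
#' from the chain's stationary distribution and each subsequent epoch from
#' the transition row of its predecessor, via inverse-CDF sampling of a
#' pre-drawn uniform sequence. The same seed always reproduces the same
#' hypnogram, and [run_control_loop()] with `arousal_prob = 0` consumes an
#' identical uniform stream, so its plant trajectory matches this function
#' epoch for epoch.
#'
#' @param model a `remloop_model`.
#' @param duration_s total duration in seconds (>= `epoch_s`); truncated to
#'   whole epochs.
#' @param epoch_s epoch duration in seconds.
#' @param seed integer seed.
#' @param init optional initial state; by default the initial epoch is drawn
#'   from the chain's stationary distribution.
#' @return a `remloop_hypnogram` tibble.
#' @examples
#' h <- generate_hypnogram(default_animal_model(), duration_s = 600, seed = 1)
#' occupancy(h)
#' @export
generate_hypnogram <- function(model, duration_s, epoch_s = 2.5, seed = 1L,
                               init = NULL) {
  stopifnot(inherits(model, "remloop_model"))
  if (duration_s < epoch_s) rlang::abort("duration_s must be >= epoch_s")
  check_stochastic(model$transition_matrix)
  n <- floor(duration_s / epoch_s)
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  states <- markov_path(model$transition_matrix, u, init = init)
  hypnogram(states, epoch_s = epoch_s)
}

# Inverse-CDF Markov realization: u[1] draws the initial state from the
# stationary distribution, u[k] (k > 1) the k-th transition.
markov_path <- function(P, u, init = NULL) {
  cum <- t(apply(P, 1, cumsum))
  s <- integer(length(u))
  s[1] <- if (is.null(init)) draw_cdf(cumsum(stationary_distribution(P)), u[1])
          else state_code(init)
  if (length(u) > 1) {
    for (k in 2:length(u)) s[k] <- draw_cdf(cum[s[k - 1], ], u[k])
  }
  code_state(s)
}

draw_cdf <- function(cdf, u) {
  # strict < so u == 1 still lands in the last cell
  1L + sum(u > cdf[-length(cdf)])
}

#' Advance the virtual-mouse plant by one step
#'
#' Implements the plant's response rule: if the platform is shaking and the
#' animal is in REM, the bout is terminated (transition to Wake) with
#' probability `arousal_prob` at every 100 ms control cycle; otherwise the
#' state evolves by the epoch-scale Markov chain, but only at epoch
#' boundaries. Uses the current R RNG stream; seed upstream for
#' reproducibility.
#'
#' @param current_state a vigilance state (character, factor or code).
#' @param stimulating logical, is the actuator moving?
#' @param model a `remloop_model`.
#' @param at_epoch_boundary logical; draw a Markov transition this step?
#' @param arousal_prob override of `model$arousal_prob` (used by the control
#'   loop's REM-pressure schedule).
#' @return a length-1 factor, the next state.
#' @export
step_plant <- function(current_state, stimulating, model,
                       at_epoch_boundary = TRUE,
                       arousal_prob = model$arousal_prob) {
  s <- state_code(as.character(state_factor(current_state)))
  if (isTRUE(stimulating) && s == 1L && arousal_prob > 0 &&
      stats::runif(1) < arousal_prob) {
    return(code_state(2L)) # aroused to Wake
  }
  if (at_epoch_boundary) {
    s <- draw_cdf(cumsum(model$transition_matrix[s, ]), stats::runif(1))
  }
  code_state(s)
}
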