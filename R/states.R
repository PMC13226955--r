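#' Vigilance states and their integer codes
#'
#' The classifier's output alphabet is the three rodent vigilance states
#' REM, Wake and NREM. On disk they are stored as the integer codes used by
#' the AccuSleep scoring convention: 1 = REM, 2 = Wake, 3 = NREM. All factors
#' produced by remloop use the level order `REM, Wake, NREM` so that
#' confusion matrices, occupancy tables and transition matrices line up.
#'
#' @return `vigilance_states()` returns the character vector
#'   `c("REM", "Wake", "NREM")`.
#' @examples
#' vigilance_states()
#' state_code(c("NREM", "REM"))
#' code_state(c(3L, 1L))
#' @export
vigilance_states <- function() c("REM", "Wake", "NREM")

#' @rdname vigilance_states
#' @param x a character vector of state names (for `state_code()`), an
#'   integer vector of codes (for `code_state()`), or either (for
#'   `state_factor()`).
#' @return `state_code()` returns integer codes; `code_state()` returns a
#'   factor with levels `REM, Wake, NREM`.
#' @export
state_code <- function(x) {
  i <- match(as.character(x), vigilance_states())
  if (anyNA(i) && !anyNA(x)) {
    rlang::abort(paste0(
      "invalid vigilance state(s): ",
      paste(unique(setdiff(as.character(x), vigilance_states())), collapse = ", ")
    ))
  }
  i
}

#' @rdname vigilance_states
#' @export
code_state <- function(x) {
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% 1:3)
  if (any(bad)) {
    rlang::abort(paste0("invalid state code(s): ", paste(unique(x[bad]), collapse = ", "),
                        " (expected 1 = REM, 2 = Wake, 3 = NREM)"))
  }
  factor(vigilance_states()[x], levels = vigilance_states())
}

#' @rdname vigilance_states
#' @export
state_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) return(code_state(x))
  i <- state_code(x)
  factor(vigilance_states()[i], levels = vigilance_states())
}
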