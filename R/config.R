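#' Run configuration
#'
#' The full parameter set of the acquisition/analysis pipeline with the
#' system's design constants as defaults: 1 kHz sampling, 5 s window
#' (5000 samples), 100 ms step, 10,000-point FFT (0.1 Hz bins), 2.5 s
#' epochs (25 decisions per epoch), and the four analysis bands. Every
#' invariant is checked at load time and violations produce named errors.
#'
#' @param ... overrides of the default fields (see [default_config()]).
#' @return a validated list of class `remloop_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    sampling_rate = 1000,
    window_s = 5,
    step_ms = 100,
    n_fft = 10000,
    epoch_s = 2.5,
    bands = default_bands(),
    gate = c(REM = 0.8, Wake = 0.7, NREM = 0.8),
    arousal_decline_per_h = 0,
    max_rem_s = Inf,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  win_samples <- cfg$sampling_rate * cfg$window_s
  if (abs(win_samples - round(win_samples)) > 1e-9) {
    rlang::abort("invalid config: sampling_rate * window_s must be an integer number of samples")
  }
  if (cfg$n_fft < win_samples) {
    rlang::abort("invalid config: n_fft must be >= the window length in samples")
  }
  k <- cfg$epoch_s / (cfg$step_ms / 1000)
  if (abs(k - round(k)) > 1e-9) {
    rlang::abort("invalid config: epoch_s / step must be an integer number of decisions per epoch")
  }
  step_samples <- cfg$sampling_rate * cfg$step_ms / 1000
  if (abs(step_samples - round(step_samples)) > 1e-9) {
    rlang::abort("invalid config: step_ms must be an integer number of samples")
  }
  for (b in names(cfg$bands)) {
    v <- cfg$bands[[b]]
    if (length(v) != 2 || v[1] >= v[2] || v[1] < 0 || v[2] > cfg$sampling_rate / 2) {
      rlang::abort(paste0("invalid config: band '", b, "' must be (lo, hi) within [0, fs/2]"))
    }
  }
  if (!all(cfg$gate >= 0 & cfg$gate <= 1)) {
    rlang::abort("invalid config: gate recalls must be in [0, 1]")
  }
  structure(cfg, class = "remloop_config")
}

#' Load / save a run configuration (YAML or JSON)
#'
#' Missing fields take the design-constant defaults; an empty file yields
#' the full default configuration. The loaded configuration is validated
#' field by field.
#'
#' @param path `.yaml`/`.yml`/`.json` file.
#' @return a `remloop_config`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$bands)) raw$bands <- lapply(raw$bands, unlist)
  if (!is.null(raw$gate)) raw$gate <- unlist(raw$gate)
  if (!is.null(raw$max_rem_s) && is.character(raw$max_rem_s)) {
    raw$max_rem_s <- as.numeric(raw$max_rem_s)  # "Inf" round trip
  }
  do.call(default_config, raw)
}

#' @rdname load_config
#' @param cfg a `remloop_config`.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$bands <- lapply(x$bands, as.numeric)
  x$gate <- as.list(x$gate)
  if (is.infinite(x$max_rem_s)) x$max_rem_s <- "Inf"
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
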