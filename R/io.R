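#' Write / read signal traces as float32 binary + JSON sidecar
#'
#' Raw little-endian float32 samples, channels interleaved frame by frame,
#' with a JSON sidecar describing the layout
#' (`{fs, channels, n_samples, start_time, units}`). The binary round trip
#' is lossless at float32 precision; file-size mismatches against the
#' sidecar raise an explicit corruption error rather than a partial silent
#' read.
#'
#' @param traces named list of `remloop_trace` objects of equal length and
#'   sampling rate (e.g. `list(EEG = ..., EMG = ...)`).
#' @param path path without extension; `<path>.bin` and `<path>.json` are
#'   written.
#' @param start_time session start time stored in the sidecar.
#' @return `write_signals()` returns `path` invisibly; `read_signals()`
#'   returns a named list of `remloop_trace`.
#' @export
write_signals <- function(traces, path, start_time = 0) {
  stopifnot(length(traces) >= 1, all(vapply(traces, inherits, logical(1), "remloop_trace")))
  ns <- vapply(traces, length, integer(1))
  fss <- vapply(traces, trace_fs, numeric(1))
  if (length(unique(ns)) != 1 || length(unique(fss)) != 1) {
    rlang::abort("all traces must share length and sampling rate")
  }
  ch <- names(traces) %||% vapply(traces, function(x) attr(x, "channel"), character(1))
  m <- do.call(rbind, lapply(traces, as.numeric))  # channels x samples
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(m), con, size = 4, endian = "little")  # column-major = frames
  jsonlite::write_json(
    list(fs = fss[1], channels = ch, n_samples = ns[1],
         start_time = start_time, units = "mV",
         format = "float32-le-interleaved"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  bin <- paste0(path, ".bin")
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) rlang::abort(paste0("missing sidecar: ", sc))
  if (!file.exists(bin)) rlang::abort(paste0("missing binary: ", bin))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  n_ch <- length(meta$channels)
  expected <- 4 * n_ch * meta$n_samples
  if (file.size(bin) != expected) {
    rlang::abort(sprintf("corrupt or truncated signal file: %s is %d bytes, sidecar implies %d",
                         bin, file.size(bin), expected))
  }
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, numeric(), n = n_ch * meta$n_samples, size = 4,
               endian = "little")
  m <- matrix(x, nrow = n_ch)
  out <- lapply(seq_len(n_ch), function(i) {
    signal_trace(m[i, ], fs = meta$fs,
                 channel = if (grepl("EMG", meta$channels[i], ignore.case = TRUE)) "EMG" else "EEG")
  })
  stats::setNames(out, meta$channels)
}

#' Write / read hypnograms as CSV
#'
#' Schema `epoch_index,start_s,state_code` with a header row; identical for
#' ground truth and classifier output so files can be diffed directly.
#' State codes: 1 = REM, 2 = Wake, 3 = NREM.
#'
#' @param hyp a `remloop_hypnogram`.
#' @param path CSV path.
#' @return `read_hypnogram()` returns a `remloop_hypnogram`.
#' @export
write_hypnogram <- function(hyp, path) {
  readr::write_csv(tibble::as_tibble(hyp)[, c("epoch_index", "start_s", "state_code")],
                   path)
  invisible(path)
}

#' @rdname write_hypnogram
#' @param epoch_s epoch duration; inferred from `start_s` spacing when the
#'   file has more than one epoch.
#' @export
read_hypnogram <- function(path, epoch_s = NULL) {
  x <- readr::read_csv(path, col_types = readr::cols(
    epoch_index = readr::col_integer(), start_s = readr::col_double(),
    state_code = readr::col_integer()))
  if (is.null(epoch_s)) {
    if (nrow(x) < 2) rlang::abort("cannot infer epoch_s from a single epoch; supply epoch_s")
    epoch_s <- x$start_s[2] - x$start_s[1]
  }
  hypnogram(code_state(x$state_code), epoch_s = epoch_s,
            start_time = x$start_s[1])
}

#' Write / read a per-epoch feature stream as CSV
#'
#' Schema `end_time_s,r_theta_delta,r_hf` (an `epoch_index` column is
#' included when present).
#'
#' @param features feature tibble.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  keep <- intersect(c("epoch_index", "end_time_s", "r_theta_delta", "r_hf", "undefined"),
                    names(features))
  readr::write_csv(features[, keep], path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols())
}

#' Write / read calibrated thresholds as JSON
#'
#' `{animal_id, tau_theta_delta, tau_hf, stats, created_from}`.
#'
#' @param thresholds a `remloop_thresholds`.
#' @param path JSON path.
#' @param created_from free-text provenance stored in the file.
#' @export
write_thresholds <- function(thresholds, path, created_from = "baseline calibration") {
  stopifnot(inherits(thresholds, "remloop_thresholds"))
  st <- thresholds$source_stats
  st$state <- as.character(st$state)
  jsonlite::write_json(
    list(animal_id = thresholds$animal_id,
         tau_theta_delta = thresholds$tau_theta_delta,
         tau_hf = thresholds$tau_hf,
         stats = st, created_from = created_from),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- tibble::as_tibble(x$stats)
  st$state <- factor(st$state, levels = vigilance_states())
  class(st) <- c("remloop_state_stats", class(st))
  structure(
    list(animal_id = x$animal_id, tau_theta_delta = x$tau_theta_delta,
         tau_hf = x$tau_hf, source_stats = st),
    class = "remloop_thresholds"
  )
}

#' Write a closed-loop session to a directory
#'
#' `cycles.csv` (one row per 100 ms cycle), `epochs.csv` (predicted vs
#' plant-truth labels), `events.csv` (`time_s,event` TTL/motor transitions)
#' and `config.json` (the config snapshot, seed included).
#'
#' @param session a `remloop_session`.
#' @param dir output directory (created if needed).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "remloop_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cyc <- session$cycles
  cyc$decision <- state_code(cyc$decision)
  cyc$plant_state <- state_code(cyc$plant_state)
  readr::write_csv(cyc, file.path(dir, "cycles.csv"))
  ep <- session$epochs
  ep$predicted <- state_code(ep$predicted)
  ep$truth <- state_code(ep$truth)
  readr::write_csv(ep, file.path(dir, "epochs.csv"))
  readr::write_csv(session$events, file.path(dir, "events.csv"))
  jsonlite::write_json(
    c(session$config, list(termination = session$termination,
                           clipped = session$clipped)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
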