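# atomic file writes: write to a temp file in the same directory, then rename
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stopf("could not move %s into place", path)
  invisible(path)
}

# full-precision numeric formatting (round-trips doubles exactly)
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a recording session to disk
#'
#' Hierarchical on-disk layout mirroring the in-memory structure:
#' `session.json` carries the session attributes (sampling rate, protocol,
#' seed), per-trial attributes (driver, clamp mode, holding) and the cell
#' metadata table; `trials/trial_<k>.csv` holds one trace column per cell at
#' full double precision, so the round-trip through [read_session()] is
#' lossless.
#'
#' @param session a `recording_session`.
#' @param path directory to create.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(file.path(path, "trials"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    sampling_rate_Hz = session$sampling_rate_Hz,
    seed = session$seed,
    protocol = list(pulses = session$protocol$pulses,
                    trial_length_ms = session$protocol$trial_length_ms,
                    n_trials_electrical = session$protocol$n_trials_electrical,
                    n_trials_chemical = session$protocol$n_trials_chemical),
    cells = session$cells,
    trials = lapply(session$trials, function(tr)
      list(driver = tr$driver, clamp_mode = tr$clamp_mode,
           holding_mV = tr$holding_mV,
           spikes = lapply(tr$spikes, fmt_full))))
  atomic_write(file.path(path, "session.json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null"))
  for (k in seq_along(session$trials)) {
    tr <- session$trials[[k]]
    atomic_write(file.path(path, "trials", sprintf("trial_%04d.csv", k)),
                 function(tmp) {
      m <- apply(tr$traces, 2, fmt_full)
      write.table(m, tmp, sep = ",", row.names = FALSE, quote = FALSE,
                  col.names = colnames(tr$traces))
    })
  }
  invisible(path)
}

#' Read a recording session written by [write_session()]
#'
#' @param path session directory.
#' @return a `recording_session`.
#' @export
read_session <- function(path) {
  jpath <- file.path(path, "session.json")
  if (!file.exists(jpath)) stopf("format error: %s is missing", jpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = FALSE)
  for (f in c("sampling_rate_Hz", "protocol", "trials", "cells"))
    if (is.null(meta[[f]]))
      stopf("format error: %s lacks attribute '%s'", jpath, f)
  proto <- structure(list(
    pulses = as.data.frame(lapply(meta$protocol$pulses, unlist)),
    trial_length_ms = meta$protocol$trial_length_ms,
    n_trials_electrical = meta$protocol$n_trials_electrical,
    n_trials_chemical = meta$protocol$n_trials_chemical),
    class = "stim_protocol")
  num_or_na <- function(x) vapply(x, function(v)
    if (is.null(v)) NA_real_ else as.numeric(v), 0)
  trials <- vector("list", length(meta$trials))
  for (k in seq_along(meta$trials)) {
    f <- file.path(path, "trials", sprintf("trial_%04d.csv", k))
    if (!file.exists(f)) stopf("format error: %s is missing", f)
    m <- as.matrix(read.csv(f, colClasses = "numeric", check.names = FALSE))
    tk <- meta$trials[[k]]
    trials[[k]] <- list(driver = as.integer(tk$driver),
                        clamp_mode = vapply(tk$clamp_mode, as.character, ""),
                        holding_mV = num_or_na(tk$holding_mV),
                        traces = m,
                        spikes = lapply(tk$spikes, function(s)
                          as.numeric(unlist(s))))
  }
  cells <- as.data.frame(lapply(meta$cells, function(col)
    unlist(lapply(col, function(v) if (is.null(v)) NA else v))))
  structure(list(sampling_rate_Hz = meta$sampling_rate_Hz, protocol = proto,
                 cells = cells, trials = trials,
                 seed = meta$seed),
            class = "recording_session")
}

#' Pipeline configuration
#'
#' JSON-serializable configuration for the command-line surface. Unknown
#' keys are rejected.
#'
#' @param seed integer seed.
#' @param detection named overrides for [detection_criteria()].
#' @param classifier named overrides for [subtype_criteria()].
#' @param distance_bins,age_bins stratification bin edges.
#' @param simulator named simulator parameters (noise_sd_mV, noise_sd_pA,
#'   brief_amp_pA, long_depol_pA).
#' @param output_dir output directory.
#' @export
pipeline_config <- function(seed = 1, detection = list(), classifier = list(),
                            distance_bins = default_distance_bins,
                            age_bins = default_age_bins,
                            simulator = list(), output_dir = ".") {
  structure(list(seed = as.integer(seed), detection = detection,
                 classifier = classifier, distance_bins = distance_bins,
                 age_bins = age_bins, simulator = simulator,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stopf("unknown config keys in %s: %s", path, paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @export
write_config <- function(config, path) {
  atomic_write(path, function(tmp)
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
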