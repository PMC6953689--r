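# CSV and JSON I/O: experiment-record tables, waveform traces, run
# configuration and run manifests. All numeric round-trips are lossless to
# well beyond 9 significant digits (readr writes full double precision).

RECORD_COLUMNS <- c("record_id", "species", "peak_ka", "bulk_gcm3", "moisture",
                    "thickness_mm", "waveform", "polarity",
                    "action_integral_a2s", "energy_j", "ignited", "is_critical")

#' Read an experiment-record table
#'
#' @param path CSV file with the record header (see
#'   [generate_factorial_energies()] for the column set).
#' @return An experiment-record tibble.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(RECORD_COLUMNS, hdr)
  if (length(miss))
    stop("records file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  # parsing problems surface as our own located error below
  out <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      record_id = "c", species = "c", waveform = "c",
                      polarity = "c", ignited = "l", is_critical = "l",
                      .default = readr::col_double())))
  probs <- readr::problems(out)
  if (nrow(probs) > 0)
    stop("malformed value at row ", probs$row[1], ", column ", probs$col[1],
         " of ", path, call. = FALSE)
  out
}

#' Write an experiment-record table
#'
#' @param records Experiment-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(RECORD_COLUMNS, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  readr::write_csv(records, path)
  invisible(path)
}

#' Read/write a waveform trace
#'
#' Traces are 2--3 column CSVs (`time_us`, `current_ka`, optional
#' `voltage_kv`); the round-trip is lossless to full double precision.
#'
#' @param path CSV path.
#' @return `read_trace()`: a `waveform_trace` tibble.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  validate_trace(out)
  class(out) <- c("waveform_trace", class(out))
  out
}

#' @rdname read_trace
#' @param trace A `waveform_trace` tibble.
#' @return `write_trace()`: `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  readr::write_csv(trace, path)
  invisible(path)
}

RUN_CONFIG_KEYS <- c("thermo", "coefs", "noise", "protocol", "out_dir", "seed",
                     "verbosity")

#' Assemble a run configuration
#'
#' A serializable bag of every knob a pipeline run uses: thermophysical
#' overrides, model-coefficient overrides, noise and protocol parameters,
#' output directory, seed and verbosity. Unknown keys are rejected.
#'
#' @param ... Named values among `thermo`, `coefs`, `noise`, `protocol`,
#'   `out_dir`, `seed`, `verbosity`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == "")))
    stop("all configuration entries must be named", call. = FALSE)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a JSON run manifest
#'
#' Records the full configuration, the seed and the package/R versions next
#' to a pipeline output, so every result is reproducible from its manifest.
#'
#' @param config A [run_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- list(
    config = lapply(unclass(config), function(v) if (is.list(v)) unclass(v) else v),
    package = "impulsefire",
    package_version = as.character(utils::packageVersion("impulsefire")),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read model coefficients from a JSON config
#'
#' The file may override any subset of the printed coefficients; the rest
#' keep their defaults. Unknown keys are rejected.
#'
#' @param path JSON file of named coefficient overrides.
#' @return A [model_coefs()] object.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_coefs, as.list(vals))
}
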