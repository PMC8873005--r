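#' Write a sweep set to the on-disk trace format
#'
#' The interchange layout is one JSON metadata document plus one CSV
#' samples table per cell and protocol: the CSV holds a `time_s` column
#' followed by one column per sweep (`sweep_001`, ...); the JSON records
#' protocol, units, sampling rate and condition labels. The format is
#' plain text, inspectable and language-portable.
#'
#' @param ss A [sweep_set()].
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to `<cell_id>_<mode>`.
#' @return Invisibly, the path of the JSON metadata file.
#' @export
write_sweep_set <- function(ss, dir, stem = NULL) {
  stopifnot(inherits(ss, "ck_sweep_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% paste0(ss$cell_id, "_", ss$protocol$mode)
  fs <- ss$traces[[1]]$fs
  n <- length(ss$traces[[1]]$samples)
  sweep_names <- sprintf("sweep_%03d", seq_along(ss$traces))
  meta <- list(
    format = "clampkit-sweepset-v1",
    cell_id = ss$cell_id, genotype = ss$genotype, week = ss$week,
    kind = ss$traces[[1]]$kind, unit = ss$traces[[1]]$unit,
    fs_hz = fs, t0_s = ss$traces[[1]]$t0, n_samples = n,
    sweeps = sweep_names,
    protocol = list(mode = ss$protocol$mode, holding = ss$protocol$holding,
                    steps = ss$protocol$steps, t_on_s = ss$protocol$t_on,
                    t_off_s = ss$protocol$t_off,
                    duration_s = ss$protocol$duration)
  )
  json_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  tab <- c(list(time_s = trace_times(ss$traces[[1]])),
           stats::setNames(lapply(ss$traces, function(tr) tr$samples),
                           sweep_names))
  readr::write_csv(tibble::as_tibble(tab), file.path(dir, paste0(stem, ".csv")))
  invisible(json_path)
}

#' Read a sweep set written by [write_sweep_set()]
#'
#' Validates that every sweep named in the metadata is present in the
#' samples table, that units are consistent, and that the time column is
#' uniform to within 1 ppm of the sample period.
#'
#' @param json_path Path to the JSON metadata document.
#' @return A [sweep_set()].
#' @export
read_sweep_set <- function(json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (!identical(meta$format, "clampkit-sweepset-v1")) {
    stop("malformed metadata: unknown format field", call. = FALSE)
  }
  if (!meta$kind %in% c("voltage", "current") ||
      !identical(meta$unit, switch(meta$kind, voltage = "mV", current = "pA"))) {
    stop("unit mismatch: '", meta$unit, "' for kind '", meta$kind, "'",
         call. = FALSE)
  }
  csv_path <- sub("\\.json$", ".csv", json_path)
  tab <- readr::read_csv(csv_path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(meta$sweeps, names(tab))
  if (length(missing) > 0) {
    stop("samples table is missing sweep column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dt <- diff(tab$time_s)
  if (any(abs(dt - 1 / meta$fs_hz) > 1e-6 / meta$fs_hz)) {
    stop("non-uniform sampling in time column (tolerance 1 ppm)", call. = FALSE)
  }
  proto <- protocol_spec(meta$protocol$mode, holding = meta$protocol$holding,
                         steps = meta$protocol$steps %||% numeric(),
                         t_on = meta$protocol$t_on_s,
                         t_off = meta$protocol$t_off_s,
                         duration = meta$protocol$duration_s, fs = meta$fs_hz)
  traces <- lapply(meta$sweeps, function(sw) {
    trace(tab[[sw]], fs = meta$fs_hz, kind = meta$kind, t0 = meta$t0_s)
  })
  sweep_set(proto, traces, cell_id = meta$cell_id, genotype = meta$genotype,
            week = meta$week)
}

#' Write and read the per-cell feature table
#'
#' Tab-separated, one row per cell; list columns (per-event amplitudes,
#' QC flags) are serialized as JSON strings so the table stays plain
#' text and round-trips losslessly.
#'
#' @param features Feature tibble from [cohort_features()] or
#'   [extract_cell_features()].
#' @param path Output TSV path.
#' @return `write_features` invisibly returns `path`; `read_features`
#'   returns the tibble.
#' @export
write_features <- function(features, path) {
  out <- features
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(x) {
        as.character(jsonlite::toJSON(x, digits = NA))
      }, character(1))
    }
  }
  readr::write_tsv(out, path, quote = "none", escape = "none")
  invisible(path)
}

#' @rdname write_features
#' @param list_cols Columns to restore from JSON strings to lists.
#' @export
read_features <- function(path, list_cols = c("epsc_amplitudes", "qc")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(list_cols, names(tab))) {
    tab[[col]] <- lapply(tab[[col]], function(s) {
      jsonlite::fromJSON(s)
    })
  }
  tab
}
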