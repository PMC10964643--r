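#' Construct a raw SWP recording
#'
#' A raw recording is a surface-potential time series (mV) sampled at a fixed
#' rate, with the wounding time marked by an index into the series, and
#' labelled by leaf (8 = wounded/local, 13 = systemic) and light condition.
#'
#' @param sample_id Character scalar, unique within a dataset.
#' @param leaf Integer, 8 or 13.
#' @param condition One of `"Normal"`, `"SED"`, `"LED"`.
#' @param values Numeric vector of surface potential in mV (length >= 2,
#'   all finite).
#' @param wound_index 1-based index of the wounding time within `values`
#'   (must be `<= length(values) - 1` so at least one sample follows it).
#' @param sampling_rate_hz Sampling rate in Hz (default 100).
#' @return An object of class `swp_recording`.
#' @export
swp_recording <- function(sample_id, leaf, condition, values, wound_index,
                          sampling_rate_hz = 100) {
  rec <- structure(
    list(sample_id = as.character(sample_id),
         leaf = check_leaf(leaf),
         condition = check_condition(condition),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         values = as.numeric(values),
         wound_index = as.integer(wound_index)),
    class = "swp_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  if (length(rec$values) < 2L)
    swp_abort("recording must contain at least 2 samples", "swp_data_error")
  if (!all(is.finite(rec$values)))
    swp_abort(sprintf("recording '%s' contains non-finite potential values",
                      rec$sample_id), "swp_data_error")
  if (!is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0)
    swp_abort("sampling_rate_hz must be positive", "swp_data_error")
  if (is.na(rec$wound_index) || rec$wound_index < 1L ||
      rec$wound_index >= length(rec$values))
    swp_abort(sprintf(
      "wound_index must lie in [1, length(values) - 1], got %s for length %d",
      rec$wound_index, length(rec$values)), "swp_data_error")
  rec
}

#' @export
print.swp_recording <- function(x, ...) {
  cat(sprintf("<swp_recording> %s  leaf %d, %s\n", x$sample_id, x$leaf,
              x$condition))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), wound at index %d (%.1f s)\n",
              length(x$values), x$sampling_rate_hz,
              length(x$values) / x$sampling_rate_hz,
              x$wound_index, (x$wound_index - 1) / x$sampling_rate_hz))
  cat(sprintf("  potential range [%.3f, %.3f] mV\n",
              min(x$values), max(x$values)))
  invisible(x)
}

trace_meta_keys <- c("sample_id", "leaf", "condition", "wound_index",
                     "sampling_rate_hz")

#' Read a trace CSV file
#'
#' The on-disk format is a comma-separated file with `#key=value` metadata
#' lines (`sample_id`, `leaf`, `condition`, `wound_index`,
#' `sampling_rate_hz`) followed by a `time_s,potential_mV` header and one row
#' per sample. The time column is used only to validate uniform spacing at
#' `1/sampling_rate_hz`.
#'
#' @param path Path to a trace CSV written by [write_trace()].
#' @return An [swp_recording()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    swp_abort(sprintf("trace file does not exist: %s", path), "swp_io_error")
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
  }
  missing <- setdiff(trace_meta_keys, names(meta))
  if (length(missing))
    swp_abort(sprintf("trace file %s missing metadata: %s", path,
                      paste0("#", missing, collapse = ", ")),
              "swp_schema_error")
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || !identical(trimws(body[1]), "time_s,potential_mV"))
    swp_abort(sprintf("trace file %s: expected header 'time_s,potential_mV'",
                      path), "swp_format_error")
  dat <- utils::read.csv(text = body, header = TRUE)
  if (anyNA(dat$potential_mV))
    swp_abort(sprintf("trace file %s contains NaN/NA potential values", path),
              "swp_data_error")
  rate <- as.numeric(meta$sampling_rate_hz)
  if (nrow(dat) >= 2) {
    dt <- diff(dat$time_s)
    expected <- 1 / rate
    if (any(abs(dt - expected) > 1e-6 * max(expected, abs(dt))))
      swp_abort(sprintf(
        "trace file %s: time column is not a uniform grid at %g Hz",
        path, rate), "swp_format_error")
  }
  swp_recording(sample_id = meta$sample_id, leaf = meta$leaf,
                condition = meta$condition, values = dat$potential_mV,
                wound_index = as.integer(meta$wound_index),
                sampling_rate_hz = rate)
}

#' Write a trace CSV file
#'
#' @param rec An [swp_recording()].
#' @param path Output path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_trace <- function(rec, path) {
  validate_recording(rec)
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    swp_abort(sprintf("cannot open %s for writing: %s", path,
                                      conditionMessage(e)), "swp_io_error"))
  on.exit(close(con))
  writeLines(c(sprintf("#sample_id=%s", rec$sample_id),
               sprintf("#leaf=%d", rec$leaf),
               sprintf("#condition=%s", rec$condition),
               sprintf("#wound_index=%d", rec$wound_index),
               sprintf("#sampling_rate_hz=%g", rec$sampling_rate_hz),
               "time_s,potential_mV"), con)
  t <- (seq_along(rec$values) - 1) / rec$sampling_rate_hz
  writeLines(sprintf("%.6f,%.6f", t, rec$values), con)
  invisible(path)
}

#' Construct a dataset manifest
#'
#' @param records Data frame with columns `sample_id`, `leaf`, `condition`,
#'   `trace_file`.
#' @param provenance `"measured"`, `"synthetic"` or `"augmented"`.
#' @return An object of class `swp_manifest` (a data frame with a
#'   `provenance` attribute).
#' @export
swp_manifest <- function(records, provenance = c("measured", "synthetic",
                                                 "augmented")) {
  provenance <- match.arg(provenance)
  needed <- c("sample_id", "leaf", "condition", "trace_file")
  if (!all(needed %in% names(records)))
    swp_abort(sprintf("manifest needs columns %s",
                      paste(needed, collapse = ", ")), "swp_schema_error")
  if (anyDuplicated(records$sample_id))
    swp_abort("duplicate sample_id in manifest", "swp_schema_error")
  bad <- setdiff(unique(records$condition), swp_conditions())
  if (length(bad))
    swp_abort(sprintf("unknown condition(s) in manifest: %s",
                      paste(bad, collapse = ", ")), "swp_schema_error")
  structure(records[, needed, drop = FALSE], provenance = provenance,
            class = c("swp_manifest", "data.frame"))
}

#' Write a manifest CSV
#' @param manifest An [swp_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#provenance=%s", attr(manifest, "provenance")), con)
  utils::write.csv(as.data.frame(manifest), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load a dataset from a manifest CSV
#'
#' Reads a manifest (`sample_id,leaf,condition,trace_file` with an optional
#' `#provenance=` line) and every trace file it references, preserving row
#' order. Relative trace paths are resolved against the manifest's directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list with `recordings` (list of [swp_recording()]) and
#'   `manifest` (the [swp_manifest()]).
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    swp_abort(sprintf("manifest not found: %s", manifest_path),
              "swp_io_error")
  lines <- readLines(manifest_path, warn = FALSE)
  prov <- sub("^#provenance=", "", grep("^#provenance=", lines, value = TRUE))
  if (!length(prov)) prov <- "measured"
  body <- lines[!grepl("^#", lines)]
  records <- utils::read.csv(text = body, header = TRUE,
                             colClasses = "character")
  if (!nrow(records)) {
    return(list(recordings = list(),
                manifest = swp_manifest(
                  data.frame(sample_id = character(), leaf = integer(),
                             condition = character(),
                             trace_file = character()), prov)))
  }
  records$leaf <- as.integer(records$leaf)
  manifest <- swp_manifest(records, prov)
  base_dir <- dirname(manifest_path)
  failures <- character()
  recordings <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    p <- records$trace_file[i]
    if (!file.exists(p)) p <- file.path(base_dir, records$trace_file[i])
    rec <- tryCatch(read_trace(p), error = function(e) {
      failures <<- c(failures, sprintf("row %d (%s): %s", i,
                                       records$sample_id[i],
                                       conditionMessage(e)))
      NULL
    })
    recordings[[i]] <- rec
  }
  if (length(failures))
    swp_abort(paste0("failed to load ", length(failures), " trace file(s):\n",
                     paste(failures, collapse = "\n")), "swp_io_error")
  list(recordings = recordings, manifest = manifest)
}
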