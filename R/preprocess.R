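#' Extract the useful signal from a raw recording
#'
#' The useful window runs from wounding ("start") to the point where the
#' repolarization phase first recovers to half of the maximum depolarization
#' ("stop"): with baseline b = value at the wound index and minimum m = the
#' post-wound minimum, stop is the first post-minimum index whose value is at
#' or above `b - (b - m)/2`. If the recording ends before that level is
#' reached (or the minimum is its final sample), the full tail is returned
#' and `truncated` is set.
#'
#' @param rec An [swp_recording()].
#' @return A list of class `swp_extracted`: `values` (from wound to stop,
#'   inclusive), `sampling_rate_hz`, `truncated` flag, and the recording
#'   metadata.
#' @export
extract_signal <- function(rec) {
  validate_recording(rec)
  v <- rec$values
  start <- rec$wound_index
  baseline <- v[start]
  post <- v[start:length(v)]
  imin <- which.min(post)                # first index attaining the minimum
  m <- post[imin]
  half_level <- baseline - (baseline - m) / 2
  truncated <- FALSE
  if (imin == length(post)) {
    stop_rel <- length(post)
    truncated <- TRUE
  } else {
    after <- which(post[(imin + 1):length(post)] >= half_level)
    if (length(after)) {
      stop_rel <- imin + after[1]
    } else {
      stop_rel <- length(post)
      truncated <- TRUE
    }
  }
  degenerate <- m >= baseline            # no depolarization at all
  structure(list(values = post[1:stop_rel],
                 sampling_rate_hz = rec$sampling_rate_hz,
                 truncated = truncated, degenerate = degenerate,
                 sample_id = rec$sample_id, leaf = rec$leaf,
                 condition = rec$condition),
            class = "swp_extracted")
}

#' Local mean compression
#'
#' Block-mean downsampling: consecutive non-overlapping windows of `window`
#' samples are each replaced by their arithmetic mean; a final partial block
#' is replaced by the mean of its remaining samples. With the default window
#' of 100 at 100 Hz acquisition, one output value represents one second.
#'
#' @param sig An `swp_extracted` signal, or a bare numeric vector.
#' @param window Block width in samples (>= 1).
#' @return A list of class `swp_compressed` with `values` (length
#'   `ceiling(n/window)`), `real_length_s`, and carried-through metadata.
#' @export
local_mean_compress <- function(sig, window = 100) {
  if (window < 1) swp_abort("window must be >= 1", "swp_config_error")
  v <- if (is.numeric(sig)) sig else sig$values
  if (!length(v)) swp_abort("empty signal", "swp_data_error")
  blocks <- ceiling(length(v) / window)
  idx <- rep(seq_len(blocks), each = window, length.out = length(v))
  means <- as.numeric(tapply(v, idx, mean))
  meta <- if (is.numeric(sig)) list() else
    sig[c("sample_id", "leaf", "condition", "truncated", "degenerate")]
  structure(c(list(values = means, real_length_s = blocks), meta),
            class = "swp_compressed")
}

#' Pad a compressed trace to a fixed length
#'
#' Extends the trace to `target_length` values by repeating its last value,
#' so every sample has equal duration before normalization. Refuses traces
#' longer than `target_length` (raise the target instead of truncating; it
#' should equal the longest compressed trace in the dataset).
#'
#' @param ct An `swp_compressed` trace or numeric vector.
#' @param target_length Target length (default 411).
#' @return A list with `values` (length `target_length`), `real_length`, and
#'   carried metadata.
#' @export
pad_trace <- function(ct, target_length = 411) {
  v <- if (is.numeric(ct)) ct else ct$values
  n <- length(v)
  if (n > target_length)
    swp_abort(sprintf(
      "trace has %d values but target_length is %d; raise target_length to at least the longest compressed trace",
      n, target_length), "swp_length_error")
  padded <- c(v, rep(v[n], target_length - n))
  meta <- if (is.numeric(ct)) list() else
    ct[intersect(c("sample_id", "leaf", "condition", "truncated",
                   "degenerate"), names(ct))]
  c(list(values = padded, real_length = n), meta)
}

#' Normalize a padded trace and align its fill region to zero
#'
#' The real region (the first `real_length` values) is mapped to \[-1, 1\] by
#' `y = 2 * (x - min) / (max - min) - 1`, with min/max taken over the real
#' region; the fill region is then set to exactly 0 (`align = "zero_fill"`,
#' the default) or, alternatively, the whole normalized trace is shifted so
#' the fill value sits at 0 (`align = "shift"`).
#'
#' @param padded Output of [pad_trace()], or a numeric vector (then
#'   `real_length` must be given).
#' @param real_length Number of leading real values.
#' @param align `"zero_fill"` or `"shift"` (see Details in the vignette).
#' @return An object of class `swp_trace`: `values`, `real_length`, and any
#'   carried `sample_id`/`leaf`/`condition`.
#' @export
normalize_and_align <- function(padded, real_length = NULL,
                                align = c("zero_fill", "shift")) {
  align <- match.arg(align)
  if (is.numeric(padded)) {
    v <- padded
    if (is.null(real_length))
      swp_abort("real_length required for bare vectors", "swp_config_error")
    meta <- list()
  } else {
    v <- padded$values
    real_length <- padded$real_length
    meta <- padded[intersect(c("sample_id", "leaf", "condition"),
                             names(padded))]
  }
  real <- v[seq_len(real_length)]
  lo <- min(real); hi <- max(real)
  if (hi <= lo)
    swp_abort("degenerate signal: constant over its real region",
              "swp_degenerate_error")
  y <- 2 * (v - lo) / (hi - lo) - 1
  if (align == "zero_fill") {
    if (real_length < length(y)) y[(real_length + 1):length(y)] <- 0
  } else {
    fill <- y[real_length]
    y <- y - fill
  }
  structure(c(list(values = y, real_length = real_length), meta),
            class = "swp_trace")
}

#' @export
print.swp_trace <- function(x, ...) {
  cat(sprintf("<swp_trace> %s  leaf %s, %s: length %d (real %d), range [%.3f, %.3f]\n",
              x$sample_id %||% "?", x$leaf %||% "?", x$condition %||% "?",
              length(x$values), x$real_length, min(x$values), max(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full preprocessing pipeline for one recording
#'
#' Composes [extract_signal()], [local_mean_compress()], [pad_trace()] and
#' [normalize_and_align()].
#'
#' @param rec An [swp_recording()].
#' @param window Compression window, samples.
#' @param target_length Padded length.
#' @param align Alignment mode, see [normalize_and_align()].
#' @param verbose Log per-stage lengths to stderr.
#' @return An `swp_trace`.
#' @export
preprocess_recording <- function(rec, window = 100, target_length = 411,
                                 align = "zero_fill", verbose = FALSE) {
  sig <- extract_signal(rec)
  if (sig$degenerate)
    swp_abort(sprintf(
      "extract_signal: recording '%s' shows no depolarization (flat or rising)",
      rec$sample_id), "swp_degenerate_error")
  ct <- local_mean_compress(sig, window = window)
  pd <- pad_trace(ct, target_length = target_length)
  tr <- normalize_and_align(pd, align = align)
  if (verbose)
    message(sprintf("[preprocess] %s: extracted %d -> compressed %d -> padded %d",
                    rec$sample_id, length(sig$values), length(ct$values),
                    length(tr$values)))
  tr
}

#' Preprocess a list of recordings
#'
#' @param recordings List of [swp_recording()].
#' @inheritParams preprocess_recording
#' @return List of `swp_trace` objects, input order preserved.
#' @export
preprocess_dataset <- function(recordings, window = 100, target_length = 411,
                               align = "zero_fill", verbose = FALSE) {
  lapply(recordings, function(rec) {
    tryCatch(preprocess_recording(rec, window, target_length, align, verbose),
             error = function(e)
               swp_abort(sprintf("preprocessing failed for '%s': %s",
                                 rec$sample_id, conditionMessage(e)),
                         class(e)[1]))
  })
}

#' Stack normalized traces into a samples-by-time matrix
#'
#' @param traces List of `swp_trace`.
#' @return List with `matrix` (rows = samples), `labels` (condition per row),
#'   `sample_ids`, `leaf`, `real_lengths`.
#' @export
traces_to_matrix <- function(traces) {
  if (!length(traces))
    return(list(matrix = matrix(numeric(), 0, 0), labels = character(),
                sample_ids = character(), leaf = integer(),
                real_lengths = integer()))
  lens <- vapply(traces, function(t) length(t$values), integer(1))
  if (length(unique(lens)) != 1)
    swp_abort("traces have mixed lengths", "swp_shape_error")
  m <- do.call(rbind, lapply(traces, function(t) t$values))
  rownames(m) <- vapply(traces, function(t) t$sample_id %||% "", character(1))
  list(matrix = m,
       labels = vapply(traces, function(t) t$condition %||% NA_character_,
                       character(1)),
       sample_ids = rownames(m),
       leaf = vapply(traces, function(t) as.integer(t$leaf %||% NA),
                     integer(1)),
       real_lengths = vapply(traces, function(t) t$real_length, integer(1)))
}
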