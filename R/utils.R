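#' @keywords internal
"_PACKAGE"

# Condition classes used throughout: swp_schema_error, swp_format_error,
# swp_data_error, swp_shape_error, swp_config_error, swp_length_error,
# swp_io_error, swp_moment_error, swp_metric_error, swp_degenerate_error.

swp_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "swp_error"), call = call))
}

swp_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "swp_warning")))
}

#' Light-regime class labels
#'
#' The three experimental conditions: normal photoperiod, short extended
#' darkness and long extended darkness.
#' @return Character vector `c("Normal", "SED", "LED")`.
#' @export
swp_conditions <- function() c("Normal", "SED", "LED")

swp_leaves <- function() c(8L, 13L)

check_condition <- function(condition) {
  if (length(condition) != 1L || !condition %in% swp_conditions()) {
    swp_abort(
      sprintf("condition must be one of %s, got '%s'",
              paste(swp_conditions(), collapse = "/"),
              paste(condition, collapse = ",")),
      "swp_schema_error")
  }
  condition
}

check_leaf <- function(leaf) {
  leaf <- suppressWarnings(as.integer(leaf))
  if (length(leaf) != 1L || is.na(leaf) || !leaf %in% swp_leaves()) {
    swp_abort("leaf must be 8 or 13", "swp_schema_error")
  }
  leaf
}

# Deterministic sub-seed derivation: mixes a master seed with string tags so
# independent pipeline stages never share an RNG stream. Kept below 2^31.
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(tags)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
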