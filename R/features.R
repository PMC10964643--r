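#' Names of the twelve time-domain features
#' @return Character vector giving the column order used throughout.
#' @export
time_domain_feature_names <- function() {
  c("maximum", "minimum", "mean", "variance", "standard_deviation",
    "skewness", "kurtosis", "rms", "area", "decline_slope", "rising_slope",
    "amplitude")
}

#' Twelve time-domain features of a normalized trace
#'
#' Computes, over the full padded trace (zero tail included, `dt` = 1 s):
#' maximum, minimum, mean, population variance, standard deviation,
#' skewness `m3 / m2^(3/2)` and non-excess kurtosis `m4 / m2^2` (biased 1/n
#' moments, no small-sample correction), root mean square, area (sum of
#' absolute trapezoid segments), declining slope `(max - min) / (-dt_d)` with
#' `dt_d = t(min) - t(first maximum)`, rising slope `(max - min) / dt_r` with
#' `dt_r = t(first post-minimum maximum) - t(min)`, and amplitude
#' `max - min`. "First maximum" is the first index attaining the global
#' maximum; ties break to the earliest index. If the minimum falls on the
#' last sample, the rising slope uses that last index as the post-minimum
#' maximum and a warning of class `swp_warning` is signalled.
#'
#' @param trace An `swp_trace` or numeric vector (length >= 2).
#' @param dt Sampling interval of the trace in seconds (1 after local mean
#'   compression with window = acquisition rate).
#' @return Named numeric vector in [time_domain_feature_names()] order.
#' @export
time_domain_features <- function(trace, dt = 1) {
  x <- if (is.numeric(trace)) trace else trace$values
  n <- length(x)
  if (n < 2) swp_abort("trace must have length >= 2", "swp_data_error")
  mx <- max(x); mn <- min(x); mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 == 0)
    swp_abort("zero variance: skewness/kurtosis undefined for constant trace",
              "swp_moment_error")
  m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  i_max <- which(x == mx)[1]
  i_min <- which(x == mn)[1]
  area <- sum(abs((x[-n] + x[-1]) / 2 * dt))
  dt_d <- (i_min - i_max) * dt
  decline <- if (dt_d == 0) NA_real_ else (mx - mn) / (-dt_d)
  if (i_min == n) {
    swp_warn("minimum at final sample: rising slope uses the last index as the post-minimum maximum",
             "swp_slope_fallback")
    i_next_max <- n
  } else {
    post <- x[(i_min + 1):n]
    i_next_max <- i_min + which(post == max(post))[1]
  }
  dt_r <- (i_next_max - i_min) * dt
  rising <- if (dt_r == 0) NA_real_ else (mx - mn) / dt_r
  out <- c(maximum = mx, minimum = mn, mean = mu, variance = m2,
           standard_deviation = sqrt(m2), skewness = m3 / m2^1.5,
           kurtosis = m4 / m2^2, rms = sqrt(mean(x^2)), area = area,
           decline_slope = decline, rising_slope = rising,
           amplitude = mx - mn)
  out[time_domain_feature_names()]
}

#' First-order derivative of a trace
#'
#' Central average of forward and backward difference quotients at interior
#' points, one-sided differences at the two boundaries; output has the same
#' length as the input. Units 1/s for a dimensionless trace at `dt` seconds
#' per sample.
#'
#' @param trace `swp_trace` or numeric vector (length >= 2).
#' @param dt Sampling interval, seconds.
#' @return Numeric vector of the same length.
#' @export
first_derivative <- function(trace, dt = 1) {
  y <- if (is.numeric(trace)) trace else trace$values
  n <- length(y)
  if (n < 2) swp_abort("trace must have length >= 2", "swp_data_error")
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- ((y[i + 1] - y[i]) / dt + (y[i] - y[i - 1]) / dt) / 2
  }
  d
}

#' Cumulative trapezoid integral of a trace
#'
#' `I[1] = 0`, `I[i] = I[i-1] + (y[i] + y[i-1]) / 2 * dt` (signed, unlike the
#' absolute-value area scalar). Units: seconds for a dimensionless trace.
#'
#' @inheritParams first_derivative
#' @return Numeric vector of the same length, starting at 0.
#' @export
cumulative_integral <- function(trace, dt = 1) {
  y <- if (is.numeric(trace)) trace else trace$values
  n <- length(y)
  if (n < 2) swp_abort("trace must have length >= 2", "swp_data_error")
  c(0, cumsum((y[-1] + y[-n]) / 2 * dt))
}

#' Build a feature matrix for a set of traces
#'
#' @param traces List of `swp_trace` (all the same length).
#' @param kind `"time_domain"` (12 named scalars), `"deriv_1st"` or
#'   `"integral"` (one column per time point).
#' @param dt Sampling interval, seconds.
#' @return List with `matrix` (rows = samples, input order), `labels`
#'   (condition per row) and `sample_ids`.
#' @export
build_feature_matrix <- function(traces,
                                 kind = c("time_domain", "deriv_1st",
                                          "integral"),
                                 dt = 1) {
  kind <- match.arg(kind)
  if (!length(traces))
    return(list(matrix = matrix(numeric(), 0, 0), labels = character(),
                sample_ids = character()))
  lens <- vapply(traces, function(t)
    length(if (is.numeric(t)) t else t$values), integer(1))
  if (length(unique(lens)) != 1)
    swp_abort("traces have mixed lengths", "swp_shape_error")
  f <- switch(kind,
              time_domain = function(t) time_domain_features(t, dt),
              deriv_1st = function(t) first_derivative(t, dt),
              integral = function(t) cumulative_integral(t, dt))
  m <- do.call(rbind, lapply(traces, f))
  colnames(m) <- switch(kind,
                        time_domain = time_domain_feature_names(),
                        deriv_1st = sprintf("d_%03d", seq_len(ncol(m)) - 1),
                        integral = sprintf("i_%03d", seq_len(ncol(m)) - 1))
  ids <- vapply(traces, function(t)
    if (is.numeric(t)) "" else t$sample_id %||% "", character(1))
  rownames(m) <- ids
  labels <- vapply(traces, function(t)
    if (is.numeric(t)) NA_character_ else t$condition %||% NA_character_,
    character(1))
  list(matrix = m, labels = labels, sample_ids = ids)
}
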