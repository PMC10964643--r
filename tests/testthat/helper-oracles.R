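# Literal loop-based re-implementations of each documented formula, kept
# deliberately naive and independent of the package internals.
oracle_scalars <- function(x, dt = 1) {
  n <- length(x)
  mx <- x[1]; mn <- x[1]; s <- 0
  for (i in 1:n) {
    if (x[i] > mx) mx <- x[i]
    if (x[i] < mn) mn <- x[i]
    s <- s + x[i]
  }
  mu <- s / n
  m2 <- 0; m3 <- 0; m4 <- 0; sq <- 0
  for (i in 1:n) {
    d <- x[i] - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4; sq <- sq + x[i]^2
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  area <- 0
  for (i in 1:(n - 1)) area <- area + abs((x[i] + x[i + 1]) / 2 * dt)
  i_max <- 1; for (i in 1:n) if (x[i] == mx) { i_max <- i; break }
  i_min <- 1; for (i in 1:n) if (x[i] == mn) { i_min <- i; break }
  i_next <- i_min
  if (i_min < n) {
    pm <- x[i_min + 1]
    i_next <- i_min + 1
    for (i in (i_min + 1):n) if (x[i] > pm) { pm <- x[i]; i_next <- i }
  }
  c(maximum = mx, minimum = mn, mean = mu, variance = m2,
    standard_deviation = sqrt(m2), skewness = m3 / m2^(3 / 2),
    kurtosis = m4 / m2^2, rms = sqrt(sq / n), area = area,
    decline_slope = (mx - mn) / (-((i_min - i_max) * dt)),
    rising_slope = (mx - mn) / ((i_next - i_min) * dt),
    amplitude = mx - mn)
}

oracle_deriv <- function(y, dt = 1) {
  n <- length(y)
  d <- numeric(n)
  for (i in 2:(n - 1))
    d[i] <- 0.5 * ((y[i + 1] - y[i]) / dt + (y[i] - y[i - 1]) / dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}

oracle_integral <- function(y, dt = 1) {
  n <- length(y)
  s <- numeric(n)
  for (i in 2:n) s[i] <- s[i - 1] + (y[i] + y[i - 1]) * dt / 2
  s
}
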