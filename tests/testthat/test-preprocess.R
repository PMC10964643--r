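# Independent brute-force oracle for the extraction stop index: explicit
# scans, no vectorized shortcuts shared with the implementation.
oracle_extract <- function(values, wound) {
  baseline <- values[wound]
  imin <- wound
  for (i in wound:length(values)) if (values[i] < values[imin]) imin <- i
  level <- baseline - (baseline - values[imin]) / 2
  stop_i <- length(values)
  if (imin < length(values)) {
    for (i in (imin + 1):length(values)) {
      if (values[i] >= level) { stop_i <- i; break }
    }
  }
  values[wound:stop_i]
}

test_that("extraction stops at the first half-recovery sample", {
  # baseline 0, linear drop to -10 over 100 samples after wounding, then
  # rise at 0.05 per sample: half level -5 is first reached 100 samples
  # after the minimum, giving a 201-sample extraction.
  v <- c(rep(0, 100), seq(0, -10, length.out = 101)[-1],
         seq(-10, 10, by = 0.05)[-1])
  rec <- swp_recording("x", 8, "Normal", v, wound_index = 100)
  sig <- extract_signal(rec)
  expect_length(sig$values, 201)
  expect_equal(sig$values[1], 0)
  expect_equal(sig$values[201], -5)
  expect_false(sig$truncated)
})

test_that("flat and unrecovered recordings are flagged", {
  flat <- swp_recording("f", 8, "Normal", rep(1, 50), 10)
  sig <- extract_signal(flat)
  expect_true(sig$degenerate)
  expect_error(preprocess_recording(flat), class = "swp_degenerate_error")

  # never recovers to the half level: full tail returned, truncated flag set
  v <- c(rep(0, 10), seq(0, -10, length.out = 20), rep(-9, 30))
  rec <- swp_recording("t", 8, "Normal", v, 10)
  sig <- extract_signal(rec)
  expect_true(sig$truncated)
  expect_equal(length(sig$values), length(v) - 9)
})

test_that("extraction agrees with a brute-force scan on random traces", {
  set.seed(11)
  for (k in 1:200) {
    n <- sample(50:300, 1)
    wound <- sample(1:(n - 10), 1)
    v <- cumsum(rnorm(n)) - 3 * dnorm(seq(-3, 3, length.out = n)) * 10
    rec <- swp_recording(paste0("r", k), 8, "Normal", v, wound)
    expect_equal(extract_signal(rec)$values, oracle_extract(v, wound))
  }
})

test_that("local mean compression reproduces worked block means", {
  # 12,800 extracted points with window 100 -> 128 values
  expect_length(local_mean_compress(rnorm(12800), 100)$values, 128)
  expect_equal(local_mean_compress(rep(3.5, 250), 100)$values, rep(3.5, 3))
  expect_equal(local_mean_compress(as.numeric(1:250), 100)$values,
               c(50.5, 150.5, 225.5))
})

test_that("compression is mean-preserving per block", {
  set.seed(2)
  v <- rnorm(537)
  ct <- local_mean_compress(v, 100)
  recon <- rep(ct$values, each = 100)[seq_along(v)]
  for (b in seq_along(ct$values)) {
    idx <- ((b - 1) * 100 + 1):min(b * 100, length(v))
    expect_equal(mean(recon[idx]), mean(v[idx]))
  }
})

test_that("padding fills with the last value and refuses overlong traces", {
  p <- pad_trace(c(rnorm(127), 7.0), 411)
  expect_length(p$values, 411)
  expect_equal(p$real_length, 128)
  expect_true(all(p$values[129:411] == 7.0))

  same <- pad_trace(rnorm(411), 411)
  expect_equal(same$real_length, 411)

  expect_error(pad_trace(rnorm(412), 411), class = "swp_length_error")
})

test_that("normalization maps the real region to [-1,1] and zeroes the tail", {
  out <- normalize_and_align(c(0, 5, 10, 10, 10), real_length = 3)
  expect_equal(out$values, c(-1, 0, 1, 0, 0))

  # fixed point: real region already spanning [-1,1]
  v <- c(-1, 0.25, 1, 1, 1)
  out2 <- normalize_and_align(v, real_length = 3)
  expect_equal(out2$values[1:3], v[1:3])
  expect_equal(out2$values[4:5], c(0, 0))

  expect_error(normalize_and_align(rep(2, 5), real_length = 5),
               class = "swp_degenerate_error")
})

test_that("normalization is idempotent on its own real region", {
  set.seed(3)
  v <- rnorm(50)
  once <- normalize_and_align(pad_trace(v, 80))
  twice <- normalize_and_align(list(values = once$values, real_length = 50))
  expect_equal(twice$values, once$values)
})

test_that("the shift alignment places the fill value at zero", {
  out <- normalize_and_align(c(0, 5, 10, 10, 10), real_length = 3,
                             align = "shift")
  expect_equal(out$values, c(-2, -1, 0, 0, 0))
})

test_that("every preprocessed synthetic trace meets the output contract", {
  for (tr in tiny_traces(8)) {
    expect_length(tr$values, 411)
    expect_true(all(tr$values >= -1 & tr$values <= 1))
    expect_true(all(tr$values[(tr$real_length + 1):411] == 0))
    expect_equal(min(tr$values[1:tr$real_length]), -1)
    expect_equal(max(tr$values[1:tr$real_length]), 1)
  }
})
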