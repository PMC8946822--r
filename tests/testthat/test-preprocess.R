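test_that("interpolation fills gaps and leaves complete channels untouched", {
  x <- cbind(a = c(1, NA, 3, 4), b = c(5, 6, 7, 8))
  out <- interpolate_missing(x)
  expect_equal(unname(out[2, "a"]), 2) # linear midpoint between 1 and 3
  expect_identical(out[, "b"], x[, "b"])
  expect_identical(interpolate_missing(x[, 2, drop = FALSE]),
                   x[, 2, drop = FALSE])
})

test_that("leading/trailing gaps take the nearest valid value", {
  x <- matrix(c(NA, NA, 3, 4, NA), ncol = 1)
  out <- interpolate_missing(x)
  expect_equal(as.numeric(out), c(3, 3, 3, 4, 4))
})

test_that("a fully missing channel is unrecoverable", {
  x <- cbind(rep(NA_real_, 10), rnorm(10))
  expect_error(interpolate_missing(x), "unrecoverable channel")
})

test_that("a gap in a slow ramp reconstructs within the ramp step bound", {
  step <- 0.25
  x <- matrix(seq(0, by = step, length.out = 400) + sin((1:400) / 40) * 0.01, ncol = 1)
  truth <- x
  x[100:104, 1] <- NA
  out <- interpolate_missing(x)
  expect_lt(max(abs(out[100:104, 1] - truth[100:104, 1])), step * 5)
})

test_that("FIR passband/stopband behaviour matches the 4-45 Hz design", {
  spec <- filter_spec()
  n <- 10000
  t <- (0:(n - 1)) / 128
  mid <- 3000:7000 # steady state away from the edges
  amp <- function(sig) max(abs(fir_bandpass(sig, spec)[mid]))
  expect_gte(amp(sin(2 * pi * 10 * t)), 0.95)
  expect_lte(amp(sin(2 * pi * 10 * t)), 1.05)
  expect_lt(amp(rep(1, n)), 0.05) # DC outside 4-45 Hz
  expect_gte(-20 * log10(amp(sin(2 * pi * 2 * t))), 20) # >= 20 dB at 2 Hz
})

test_that("filtering is linear and zero-phase mode has no group delay", {
  spec <- filter_spec()
  set.seed(1)
  x <- rnorm(4000); y <- rnorm(4000)
  lhs <- fir_bandpass(2 * x - 3 * y, spec)
  rhs <- 2 * fir_bandpass(x, spec) - 3 * fir_bandpass(y, spec)
  expect_equal(lhs, rhs, tolerance = 1e-10)

  s <- sin(2 * pi * 10 * (0:3999) / 128)
  f <- fir_bandpass(s, spec)
  lags <- -5:5
  cc <- sapply(lags, function(l) {
    idx <- 1000:3000
    cor(s[idx], f[idx + l])
  })
  expect_equal(lags[which.max(cc)], 0)
})

test_that("single-pass mode compensates the group delay", {
  s <- sin(2 * pi * 10 * (0:3999) / 128)
  f <- fir_bandpass(s, filter_spec(mode = "single-pass"))
  idx <- 1000:3000
  cc <- sapply(-5:5, function(l) cor(s[idx], f[idx + l]))
  expect_equal((-5:5)[which.max(cc)], 0)
})

test_that("filter specification and length preconditions are enforced", {
  expect_error(filter_spec(low = 0), "0 < low")
  expect_error(filter_spec(low = 50, high = 45), "0 < low")
  expect_error(filter_spec(taps = 256), "odd")
  expect_error(fir_bandpass(rnorm(100), filter_spec()), "length error")
})

test_that("segmentation yields 200 segments of 14 x 1536 in trial order", {
  s <- default_session()
  segs <- segment_trials(s)
  expect_equal(dim(segs$x), c(1536, 14, 200))
  expect_identical(segs$labels, s$trials$label)
  # partition property: each segment reproduces its span exactly
  for (i in c(1, 57, 200)) {
    o <- s$trials$onset_sample[i]
    expect_equal(segs$x[, , i], s$signal[o:(o + 1535), ], ignore_attr = TRUE)
  }
})

test_that("segmentation edge cases error informatively", {
  s <- generate_session(small_config(seed = 2L))
  empty <- s
  empty$trials <- s$trials[0, ]
  expect_equal(dim(segment_trials(empty)$x)[3], 0)
  broken <- s
  broken$trials$onset_sample[3] <- nrow(s$signal) - 10L
  expect_error(segment_trials(broken), "segmentation error.*3")
})
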