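test_that("session composition holds across seeds under the default design", {
  for (seed in c(1L, 99L, 4321L)) {
    s <- generate_session(effect_config(seed = seed, baseline_s = 2))
    expect_equal(nrow(s$trials), 200)
    expect_equal(sum(s$trials$label == 0), 120)
    expect_equal(sum(s$trials$label == 1), 80)
    # 12-s trials at 128 Hz, non-overlapping increasing onsets
    expect_true(all(diff(s$trials$onset_sample) >= 1536))
    expect_lte(max(s$trials$onset_sample) + 1535, nrow(s$signal))
    expect_length(s$baseline_onsets, 6)
  }
})

test_that("generator is a pure function of (config, seed)", {
  cfg <- small_config(seed = 7L)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$trials, b$trials)
  c <- generate_session(small_config(seed = 8L))
  expect_false(identical(a$signal, c$signal))
})

test_that("invalid generator parameters raise configuration errors", {
  expect_error(effect_config(osc_amplitude = c(-1, 1, 1, 1)), "configuration error")
  expect_error(effect_config(noise_sd = NaN), "configuration error")
  expect_error(effect_config(multipliers = matrix(-1, 14, 4)), "configuration error")
  expect_error(effect_config(rt_sd = c(-5, 10)), "configuration error")
  bad <- effect_config(seed = 1)
  bad$rt_sd <- c(-5, 10) # corrupted after construction
  expect_error(generate_reaction_times(bad, c(0L, 1L)), "configuration error")
})

test_that("reaction times separate the classes with power", {
  cfg <- effect_config(rt_mean = c(900, 650), rt_sd = c(250, 250), seed = 1)
  labels <- rep(c(0L, 1L), c(120L, 80L))
  hits <- 0L
  set.seed(2024)
  for (r in 1:200) {
    rt <- generate_reaction_times(cfg, labels)
    p <- t.test(rt[labels == 0], rt[labels == 1])$p.value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 190) # >= 95% of replicates reject at alpha = 0.01
})

test_that("zero reaction-time SD returns the class means exactly", {
  cfg <- effect_config(rt_mean = c(900, 650), rt_sd = c(0, 0), seed = 1)
  labels <- c(0L, 1L, 0L, 1L)
  expect_equal(generate_reaction_times(cfg, labels), c(900, 650, 900, 650))
  expect_length(generate_reaction_times(cfg, rep(0L, 17)), 17)
})

test_that("inject_missing preserves shape, is seeded, rejects large fractions", {
  s <- generate_session(small_config(seed = 3L))
  expect_identical(inject_missing(s, 0), s)
  a <- inject_missing(s, 0.01, seed = 5L)
  b <- inject_missing(s, 0.01, seed = 5L)
  expect_identical(which(is.na(a$signal)), which(is.na(b$signal)))
  expect_equal(dim(a$signal), dim(s$signal))
  frac <- mean(is.na(a$signal))
  expect_gte(frac, 0.009)
  expect_lt(frac, 0.03)
  expect_error(inject_missing(s, 0.5), "fraction")
})

test_that("interpolated gaps deviate less than the local signal range", {
  s <- generate_session(small_config(seed = 11L))
  gapped <- inject_missing(s, 0.01, seed = 2L)
  rec <- interpolate_missing(gapped$signal)
  for (ch in c(1L, 7L, 14L)) {
    miss <- which(is.na(gapped$signal[, ch]))
    dev <- abs(rec[miss, ch] - s$signal[miss, ch])
    expect_lt(max(dev), diff(range(s$signal[, ch])))
  }
})

test_that("band power increases at a multiplied pair (Welch p < 0.01)", {
  # 3 pooled sessions give 600 trials; alpha at P8 carries the 1.5x multiplier
  fv <- do.call(rbind, lapply(1:3, function(i) {
    s <- generate_session(effect_config(seed = 300L + i, baseline_s = 2))
    extract_features(segment_trials(s))
  }))
  x0 <- fv$alpha_P8[fv$label == 0]
  x1 <- fv$alpha_P8[fv$label == 1]
  expect_gt(mean(x1), mean(x0))
  expect_lt(t.test(x0, x1)$p.value, 0.01)
})
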