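test_that("the rating-scale conversion folds gender direction into strength", {
  expect_equal(convert_rating_scale(c(1, 2, 3, 4, 5)), c(3L, 2L, 1L, 2L, 3L))
  expect_equal(convert_rating_scale(rep(3, 6)), rep(1L, 6))
  expect_error(convert_rating_scale(6), "1..5")
})

test_that("two-sample t-tests match the closed-form oracle", {
  set.seed(1)
  a <- rnorm(30, 1, 2); b <- rnorm(25, 0.2, 1.5)
  for (variant in c("pooled", "welch")) {
    r <- two_sample_ttest(a, b, variant)
    o <- ttest_from_summary(mean(a), var(a), 30, mean(b), var(b), 25, variant)
    expect_equal(r$t, o$t, tolerance = 1e-10)
    expect_equal(r$p, o$p, tolerance = 1e-10)
    expect_equal(r$df, o$df, tolerance = 1e-10)
  }
  ident <- two_sample_ttest(rep(2, 5), rep(2, 7))
  expect_equal(c(ident$t, ident$p), c(0, 1))
})

test_that("pooled and Welch agree for equal variances and sizes", {
  set.seed(2)
  a <- rnorm(20); b <- a + 1 # equal variance, equal n
  p <- two_sample_ttest(a, b, "pooled")
  w <- two_sample_ttest(a, b, "welch")
  expect_equal(p$t, w$t, tolerance = 1e-12)
})

test_that("the published reaction-time row is strongly significant", {
  # per-participant summaries: M0 922.8, V0 5.543e5 (n 120) vs
  # M1 394.825, V1 0.6054e5 (n 80)
  r <- ttest_from_summary(922.8, 5.543e5, 120, 394.825, 0.6054e5, 80, "welch")
  expect_equal(r$t, 7.2, tolerance = 0.01)
  expect_lt(r$p, 0.0001)
})

test_that("Type-1 accuracy counts correct referent choices", {
  tr <- data.frame(label = rep(c(1L, 0L), c(80L, 120L)),
                   response = c(rep("Z", 80), rep("M", 120)),
                   correct = c(rep("Z", 45), rep("M", 35), rep(NA, 120)))
  r <- type1_accuracy(tr)
  expect_equal(r$n_correct, 45)
  expect_equal(r$rate, 0.5625)
  all_ok <- tr
  all_ok$correct[1:80] <- "Z"
  expect_equal(type1_accuracy(all_ok)$rate, 1)
  none <- tr[tr$label == 0, ]
  expect_true(type1_accuracy(none)$undefined)
})

test_that("Type-0 proportions cover Z, M and missing responses", {
  tr <- data.frame(label = rep(0L, 120),
                   response = rep(c("Z", "M"), each = 60))
  expect_equal(type0_proportions(tr), c(Z = 0.5, M = 0.5, none = 0))
  tr$response <- "none"
  expect_equal(type0_proportions(tr), c(Z = 0, M = 0, none = 1))
  tr$response[1] <- "Q"
  expect_error(type0_proportions(tr), "unknown response")
  # rounded proportions stay within 5e-4 of 1 for arbitrary small designs
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:120, 1)
    t2 <- data.frame(label = rep(0L, n),
                     response = sample(c("Z", "M", "none"), n, replace = TRUE))
    p <- eegworkload:::round_half_up(type0_proportions(t2), 4)
    expect_lt(abs(sum(p) - 1), 5e-4)
  }
})

test_that("feature t-tests are zero for duplicated class sets", {
  fv <- default_features()[1:40, ]
  dup <- rbind(fv, fv)
  dup$label <- rep(c(0L, 1L), each = nrow(fv))
  tt <- feature_ttests(dup)
  expect_equal(nrow(tt), 42)
  expect_equal(tt$t, rep(0, 42), tolerance = 1e-10)
  expect_false(any(tt$significant))
  one_class <- fv
  one_class$label <- 0L
  expect_error(feature_ttests(one_class), "both classes")
})

test_that("feature t-tests follow the Class0-minus-Class1 sign convention", {
  fv <- default_features()
  tt <- feature_ttests(fv)
  # the multiplied alpha_P8 pair increases under Class 1 -> negative t
  expect_lt(tt$t[tt$feature == "alpha_P8"], 0)
})

test_that("habituation analysis is null-calibrated and detects drift", {
  # identical segments across conditions -> all t = 0
  flat <- replicate(8, matrix(1:3, 6, 3, byrow = TRUE,
                              dimnames = list(NULL, c("theta", "alpha", "bg"))),
                    simplify = FALSE)
  h0 <- habituation_analysis(flat)
  expect_equal(h0$t, rep(0, 15))
  expect_false(any(h0$significant))

  # stationary baselines: corrected rejections track the corrected alpha
  rejections <- 0L; total <- 0L
  for (r in 1:40) {
    summ <- lapply(1:15, function(s) {
      ec <- effect_config(seed = r * 100L + s, n_class0 = 6L, n_class1 = 4L,
                          baseline_s = 4)
      baseline_band_summary(generate_session(ec))
    })
    h <- habituation_analysis(summ)
    rejections <- rejections + sum(h$significant)
    total <- total + nrow(h)
  }
  expect_lt(rejections / total, 0.025) # corrected alpha is 0.01 per test

  # doubled condition-6 amplitude is detected after correction
  summ <- lapply(1:15, function(s) {
    ec <- effect_config(seed = 7000L + s, n_class0 = 6L, n_class1 = 4L,
                        baseline_s = 4)
    b <- baseline_band_summary(generate_session(ec))
    b[6, ] <- b[6, ] * 4 # amplitude doubled = power quadrupled
    b
  })
  h1 <- habituation_analysis(summ)
  expect_true(any(h1$significant))
  expect_error(habituation_analysis(list(matrix(0, 5, 3))), "6 baseline")
})
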