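counts_of <- function(tp, fn, tn, fp, positive = 0L) {
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, positive = positive),
            class = "confusion_counts")
}

test_that("metrics reproduce the published stratified-fusion row", {
  m <- workload_metrics(counts_of(25, 11, 12, 12), f1 = "macro")
  expect_rounded_equal(m$Pacc, 0.6167)
  expect_rounded_equal(m$Psen, 0.6944)
  expect_rounded_equal(m$Pspe, 0.5000)
  expect_rounded_equal(m$F1, 0.5978)
})

test_that("binary F1 reproduces the published hold-out row", {
  m <- workload_metrics(counts_of(33, 24, 0, 3), f1 = "binary")
  expect_rounded_equal(m$Pacc, 0.5500)
  expect_rounded_equal(m$Psen, 0.5789)
  expect_rounded_equal(m$Pspe, 0.0000)
  expect_rounded_equal(m$F1, 0.7097)
})

test_that("perfect predictions score 1 and zero denominators are flagged", {
  perf <- workload_metrics(confusion_counts(c(0, 1, 1), c(0, 1, 1)))
  expect_equal(c(perf$Pacc, perf$F1, perf$Psen, perf$Pspe), rep(1, 4))
  m <- workload_metrics(confusion_counts(c(0, 0), c(0, 0), positive = 1))
  expect_true("Psen" %in% m$undefined)
  expect_true(is.na(m$Psen))
  expect_false(is.nan(m$Pacc))
})

test_that("accuracy equals the prevalence-weighted mix of sen and spe", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2) next
    m <- workload_metrics(confusion_counts(truth, pred, positive = 1))
    pi1 <- mean(truth == 1)
    expect_equal(m$Pacc, m$Psen * pi1 + m$Pspe * (1 - pi1), tolerance = 1e-12)
  }
})

test_that("macro F1 is symmetric in the positive class, binary F1 is not", {
  truth <- c(rep(1, 30), rep(0, 20))
  set.seed(3)
  pred <- ifelse(runif(50) < 0.7, truth, 1 - truth)
  m1 <- workload_metrics(confusion_counts(truth, pred, positive = 1))
  m0 <- workload_metrics(confusion_counts(truth, pred, positive = 0))
  expect_equal(m1$f1_macro, m0$f1_macro, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m1$f1_binary, m0$f1_binary)))
})

test_that("stratified hold-out preserves the 120:80 design ratio", {
  labels <- rep(c(0L, 1L), c(120L, 80L))
  sp <- holdout_split(labels, 0.7, stratified = TRUE, seed = 9L)
  expect_length(sp$train, 140)
  expect_length(sp$test, 60)
  expect_equal(sum(labels[sp$test] == 0), 36)
  expect_equal(sum(labels[sp$test] == 1), 24)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_identical(sp, holdout_split(labels, 0.7, TRUE, seed = 9L))
  expect_error(holdout_split(labels, 1), "strictly between")
})

test_that("k-fold folds partition the trials and pool correctly", {
  labels <- rep(c(0L, 1L), c(120L, 80L))
  x <- matrix(rnorm(200 * 3), 200)
  always0 <- function(xtr, ytr, xte) rep(0L, nrow(xte))
  cv <- kfold_cv(x, labels, always0, k = 10, seed = 1, positive = 1)
  expect_equal(cv$pooled$Pacc, 0.6) # majority-class fraction 120/200
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(as.numeric(table(cv$folds)), rep(20, 10))
  oracle <- function(xtr, ytr, xte) {
    # an oracle that remembers the labels by row identity
    labels[match(asplit(xte, 1), asplit(x, 1))]
  }
  expect_equal(kfold_cv(x, labels, oracle, k = 10, seed = 1)$pooled$Pacc, 1)
  expect_error(kfold_cv(x, labels, always0, k = 1), "k must be")
})

test_that("cross-validation pipelines never see held-out rows", {
  labels <- rep(c(0L, 1L), each = 20)
  x <- matrix(rnorm(40 * 2), 40)
  seen <- list()
  spy <- function(xtr, ytr, xte) {
    seen[[length(seen) + 1]] <<- list(tr = xtr, te = xte)
    rep(0L, nrow(xte))
  }
  kfold_cv(x, labels, spy, k = 4, seed = 2)
  for (s in seen) {
    overlap <- intersect(asplit(s$tr, 1), asplit(s$te, 1))
    expect_length(overlap, 0)
  }
})

test_that("subject aggregation reproduces the published mean rows", {
  t9 <- reference_table("lenet5_holdout")
  # the published mean averages the exact per-subject accuracies (k/60);
  # reconstruct them from the printed 4-decimal values first
  acc_exact <- round(t9$Pacc * 60) / 60
  expect_equal(unname(aggregate_subjects(data.frame(Pacc = acc_exact))), 0.5544)
  agg9 <- aggregate_subjects(t9[, c("Pacc", "F1", "Psen", "Pspe")])
  expect_equal(unname(agg9["F1"]), 0.6872)
  t12 <- reference_table("fusion_leaveout")
  agg12 <- aggregate_subjects(t12[, c("Pacc", "F1", "Psen", "Pspe")])
  expect_equal(unname(agg12["Pacc"]), 0.5667)
  expect_equal(unname(agg12["Pspe"]), 0.3278)
  one <- aggregate_subjects(data.frame(Pacc = 0.61, F1 = 0.5))
  expect_equal(unname(one["Pacc"]), 0.61)
})

test_that("accuracy-vs-chance handles degenerate and closed-form cases", {
  d <- accuracy_vs_chance(rep(0.5, 15))
  expect_true(d$degenerate)
  expect_equal(d$t, 0)
  v <- c(rep(0.6, 8), rep(0.5, 7))
  r <- accuracy_vs_chance(v)
  expect_equal(r$t, (mean(v) - 0.5) / (sd(v) / sqrt(15)), tolerance = 1e-12)
  expect_equal(r$df, 14)
})

test_that("the consistency solver reconciles printed rows with counts", {
  s12 <- consistency_solver(0.6167, 0.6944, 0.5000, 60)
  expect_equal(nrow(s12), 1)
  expect_equal(s12$n_pos, 36)
  expect_equal(s12$n_neg, 24)
  expect_equal(unlist(s12[1, c("TP", "FN", "TN", "FP")], use.names = FALSE),
               c(25, 11, 12, 12))
  s9 <- consistency_solver(0.5500, 0.5789, 0.0000, 60)
  hit <- s9[s9$TP == 33 & s9$FN == 24 & s9$TN == 0 & s9$FP == 3, ]
  expect_equal(nrow(hit), 1)
  expect_rounded_equal(hit$f1_binary, 0.7097)
  perf <- consistency_solver(1, 1, 1, 60)
  expect_true(all(perf$FN == 0 & perf$FP == 0))
})
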