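#' Confusion counts of a binary prediction
#'
#' The positive class defaults to Class 1 (unambiguous pronoun resolution) as
#' in the study's metric definitions, but is an explicit parameter because
#' some published per-subject tables are only consistent with Class 0 as
#' positive.
#'
#' @param truth,pred Integer 0/1 vectors of equal length.
#' @param positive Positive-class label.
#' @return Object of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`
#'   and `positive`.
#' @export
confusion_counts <- function(truth, pred, positive = 1L) {
  stopifnot(length(truth) == length(pred))
  p <- truth == positive
  structure(list(TP = sum(p & pred == positive),
                 FP = sum(!p & pred == positive),
                 TN = sum(!p & pred != positive),
                 FN = sum(p & pred != positive),
                 positive = positive),
            class = "confusion_counts")
}

#' Workload classification metrics
#'
#' Accuracy `Pacc = (TP + TN) / (TP + TN + FP + FN)`, sensitivity
#' `Psen = TP / (TP + FN)`, specificity `Pspe = TN / (TN + FP)`, and the
#' F1 score, either binary (`2 TP / (2 TP + FP + FN)` for the declared
#' positive class) or macro (mean of the binary F1 computed once per class as
#' positive). Undefined ratios (zero denominators) are flagged rather than
#' propagated as NaN.
#'
#' @param counts A `confusion_counts` object.
#' @param f1 `"macro"` or `"binary"`.
#' @return Object of class `metric_set`: `Pacc`, `F1`, `Psen`, `Pspe`,
#'   `f1_variant`, `undefined` (character vector of flagged metrics) and the
#'   counts.
#' @export
workload_metrics <- function(counts, f1 = c("macro", "binary")) {
  f1 <- match.arg(f1)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop("workload_metrics: no evaluated trials")
  undef <- character(0)
  psen <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "Psen"); NA_real_ }
  pspe <- if (tn + fp > 0) tn / (tn + fp) else { undef <- c(undef, "Pspe"); NA_real_ }
  f1_bin <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  f1_neg <- if (2 * tn + fp + fn > 0) 2 * tn / (2 * tn + fp + fn) else NA_real_
  f1_macro <- mean(c(f1_bin, f1_neg))
  structure(list(Pacc = (tp + tn) / total,
                 F1 = if (f1 == "binary") f1_bin else f1_macro,
                 Psen = psen, Pspe = pspe,
                 f1_binary = f1_bin, f1_macro = f1_macro,
                 f1_variant = f1, undefined = undef, counts = counts),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> Pacc %.4f  F1(%s) %.4f  Psen %.4f  Pspe %.4f\n",
              x$Pacc, x$f1_variant, x$F1, x$Psen, x$Pspe))
  invisible(x)
}

#' Hold-out train/test split
#'
#' 70/30 split of a subject's trials. Stratified mode splits each class
#' separately, preserving the 120:80 design ratio (36 Class-0 + 24 Class-1
#' test trials for n = 200); non-stratified mode shuffles all trials.
#'
#' @param labels Integer 0/1 labels (one per trial).
#' @param train_fraction Training proportion, strictly between 0 and 1.
#' @param stratified Preserve class ratios (default `TRUE`).
#' @param seed Shuffle seed.
#' @return List with integer index vectors `train` and `test` (disjoint
#'   cover of the trials).
#' @export
holdout_split <- function(labels, train_fraction = 0.7, stratified = TRUE,
                          seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("holdout_split: train_fraction must be strictly between 0 and 1")
  }
  with_seed(seed, {
    if (stratified) {
      train <- integer(0)
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        if (length(idx) == 0) stop("holdout_split: empty class under stratification")
        n_tr <- round(train_fraction * length(idx))
        train <- c(train, sample(idx, n_tr))
      }
    } else {
      n_tr <- round(train_fraction * length(labels))
      train <- sample(seq_along(labels), n_tr)
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' k-fold cross-validation of a pipeline closure
#'
#' Seeded stratified partition into k folds; the entire pipeline (including
#' any standardisation/PCA refit) is re-run on each fold's training rows, so
#' no statistic ever sees held-out rows. Metrics are pooled over the
#' concatenated out-of-fold predictions.
#'
#' @param x Feature matrix (trials x d).
#' @param labels Integer 0/1 labels.
#' @param pipeline Closure `function(x_train, y_train, x_test)` returning
#'   predicted 0/1 labels for `x_test`.
#' @param k Number of folds (>= 2, <= class sizes).
#' @param seed Fold-assignment seed.
#' @param positive,f1 Passed to [workload_metrics()].
#' @return List with `fold_metrics` (list of `metric_set`), `pooled`
#'   (`metric_set` over all trials) and `folds` (fold id per trial).
#' @export
kfold_cv <- function(x, labels, pipeline, k = 10L, seed = 1L,
                     positive = 1L, f1 = "macro") {
  if (k < 2) stop("kfold_cv: k must be >= 2")
  if (any(table(labels) < k)) stop("kfold_cv: k exceeds a class size")
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  pred <- integer(n)
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(folds == f); tr <- which(folds != f)
    pred[te] <- pipeline(x[tr, , drop = FALSE], labels[tr], x[te, , drop = FALSE])
    fold_metrics[[f]] <- workload_metrics(
      confusion_counts(labels[te], pred[te], positive), f1)
  }
  pooled <- workload_metrics(confusion_counts(labels, pred, positive), f1)
  list(fold_metrics = fold_metrics, pooled = pooled, folds = folds)
}

#' Average per-subject metric rows
#'
#' Unweighted arithmetic mean of each metric across subjects, rounded
#' half-up to 4 decimals as in the printed report tables.
#'
#' @param metrics Data frame of per-subject metric rows (numeric columns) or
#'   a list of `metric_set`s.
#' @return Named numeric vector of rounded column means.
#' @export
aggregate_subjects <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics) &&
      inherits(metrics[[1]], "metric_set")) {
    metrics <- do.call(rbind, lapply(metrics, function(m) {
      data.frame(Pacc = m$Pacc, F1 = m$F1, Psen = m$Psen, Pspe = m$Pspe)
    }))
  }
  num <- vapply(metrics, is.numeric, TRUE)
  round_half_up(colMeans(metrics[, num, drop = FALSE]), 4)
}

#' One-sample t-test of per-subject accuracies against chance
#'
#' Two-sided one-sample t-test of the per-subject accuracy values against
#' 0.5, the chance level of the binary workload decision.
#'
#' @param accuracies Numeric vector (one accuracy per subject, n >= 2).
#' @param mu Chance level (default 0.5).
#' @return List with `t`, `df`, `p`, `mean`, `sd` and a `degenerate` flag for
#'   zero-variance input.
#' @export
accuracy_vs_chance <- function(accuracies, mu = 0.5) {
  n <- length(accuracies)
  if (n < 2) stop("accuracy_vs_chance: need at least 2 subjects")
  s <- stats::sd(accuracies)
  m <- mean(accuracies)
  if (s == 0) {
    return(list(t = if (m == mu) 0 else sign(m - mu) * Inf, df = n - 1,
                p = NA_real_, mean = m, sd = s, degenerate = TRUE))
  }
  tt <- stats::t.test(accuracies, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = m, sd = s, degenerate = FALSE)
}

#' Reconcile printed metrics with integer confusion counts
#'
#' Brute-force solver recovering every integer (TP, FN, TN, FP) tuple over
#' `n` evaluated trials whose accuracy, sensitivity and specificity round
#' (half-up, 4 decimals) to the printed values. Used to reverse-engineer the
#' class split and F1 convention behind published report tables.
#'
#' @param pacc,psen,pspe Printed metrics (4 decimals).
#' @param n Total evaluated trials (<= 1000).
#' @return Data frame with columns TP, FN, TN, FP, n_pos, n_neg,
#'   f1_binary, f1_macro (0 rows if no integer solution exists).
#' @export
consistency_solver <- function(pacc, psen, pspe, n) {
  stopifnot(n <= 1000)
  sols <- list()
  for (npos in 0:n) {
    nneg <- n - npos
    tps <- if (npos == 0) {
      if (is.na(psen)) 0L else integer(0) # sensitivity undefined with no positives
    } else (0:npos)[round_half_up((0:npos) / npos) == psen]
    tns <- if (nneg == 0) {
      if (is.na(pspe)) 0L else integer(0)
    } else (0:nneg)[round_half_up((0:nneg) / nneg) == pspe]
    if (length(tps) == 0 || length(tns) == 0) next
    grid <- expand.grid(TP = tps, TN = tns)
    acc <- round_half_up((grid$TP + grid$TN) / n)
    hit <- which(acc == pacc)
    if (length(hit)) {
      sols[[length(sols) + 1L]] <- data.frame(
        TP = grid$TP[hit], FN = npos - grid$TP[hit],
        TN = grid$TN[hit], FP = nneg - grid$TN[hit],
        n_pos = npos, n_neg = nneg
      )
    }
  }
  if (length(sols) == 0) {
    return(data.frame(TP = integer(0), FN = integer(0), TN = integer(0),
                      FP = integer(0), n_pos = integer(0), n_neg = integer(0),
                      f1_binary = numeric(0), f1_macro = numeric(0)))
  }
  out <- do.call(rbind, sols)
  out$f1_binary <- 2 * out$TP / (2 * out$TP + out$FP + out$FN)
  neg_f1 <- 2 * out$TN / (2 * out$TN + out$FP + out$FN)
  out$f1_macro <- (out$f1_binary + neg_f1) / 2
  out
}
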