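#' Shallow classifier specification
#'
#' The learners applied to fused feature vectors in place of the network's
#' last fully connected layer: Gaussian naive Bayes (`nb`), soft-margin
#' support-vector classifier (`csvm`), k-nearest-neighbour (`knn`), or the
#' fully connected softmax head (`fc`). Hyperparameter defaults are the
#' conventional ones (C = 1 with a radial-basis kernel; k = 5, odd, with
#' Euclidean distance) and are recorded in every report.
#'
#' @param learner One of `"csvm"`, `"nb"`, `"knn"`, `"fc"`.
#' @param C Soft-margin cost (> 0).
#' @param kernel SVM kernel name (e1071 convention).
#' @param k Neighbour count (>= 1; odd by default).
#' @param positive Positive-class label used for tie-breaking (default 1).
#' @param seed Seed for any stochastic fitting.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(learner = c("csvm", "nb", "knn", "fc"),
                            C = 1, kernel = "radial", k = 5L,
                            positive = 1L, seed = 1L) {
  learner <- match.arg(learner)
  if (C <= 0) stop("classifier_spec: C must be > 0")
  if (k < 1) stop("classifier_spec: k must be >= 1")
  structure(list(learner = learner, C = C, kernel = kernel, k = as.integer(k),
                 positive = as.integer(positive), seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit a shallow workload classifier
#'
#' @param spec A [classifier_spec()].
#' @param x Training matrix (rows = trials).
#' @param labels Integer 0/1 labels; both classes must be present.
#' @return Object of class `workload_model`.
#' @export
workload_fit <- function(spec, x, labels) {
  x <- as.matrix(x)
  if (length(unique(labels)) < 2) {
    stop("workload_fit: training set contains a single class")
  }
  fit <- switch(spec$learner,
    csvm = with_seed(spec$seed,
                     e1071::svm(x, factor(labels), cost = spec$C,
                                kernel = spec$kernel, scale = FALSE)),
    nb = nb_fit(x, labels),
    knn = list(x = x, labels = as.integer(labels)),
    fc = train_head(x, labels, seed = spec$seed)
  )
  structure(list(spec = spec, fit = fit, d = ncol(x)), class = "workload_model")
}

#' Predict workload classes
#'
#' @param object A `workload_model`.
#' @param newdata Matrix with the training dimensionality.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels (empty input gives empty output).
#' @export
predict.workload_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == 1 && object$d > 1) newdata <- t(newdata)
  if (ncol(newdata) != object$d) {
    stop(sprintf("predict: dimension mismatch (%d columns, model expects %d)",
                 ncol(newdata), object$d))
  }
  if (nrow(newdata) == 0) return(integer(0))
  spec <- object$spec
  switch(spec$learner,
    csvm = as.integer(as.character(stats::predict(object$fit, newdata))),
    nb = nb_predict(object$fit, newdata, spec$positive),
    knn = knn_predict(object$fit, newdata, spec$k, spec$positive),
    fc = stats::predict(object$fit, newdata)
  )
}

# Gaussian naive Bayes with per-class diagonal covariance. At an exact
# posterior tie the declared positive class wins.
nb_fit <- function(x, labels) {
  classes <- sort(unique(labels))
  stats <- lapply(classes, function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    list(mean = colMeans(xi),
         var = pmax(apply(xi, 2, stats::var), 1e-12),
         logprior = log(nrow(xi) / nrow(x)))
  })
  names(stats) <- classes
  list(classes = classes, stats = stats)
}

nb_predict <- function(model, x, positive) {
  scores <- vapply(model$classes, function(cl) {
    s <- model$stats[[as.character(cl)]]
    z <- sweep(x, 2, s$mean)
    -0.5 * rowSums(sweep(z^2, 2, s$var, "/")) -
      0.5 * sum(log(2 * pi * s$var)) + s$logprior
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow(x), length(model$classes))
  best <- apply(scores, 1, function(r) {
    top <- which(r >= max(r) - 1e-12)
    cls <- model$classes[top]
    if (positive %in% cls) positive else cls[1]
  })
  as.integer(best)
}

# KNN with Euclidean distance. Distance ties are broken by lowest training
# index; class vote ties go to the positive class.
knn_predict <- function(model, x, k, positive) {
  tr <- model$x
  k <- min(k, nrow(tr))
  tr_sq <- rowSums(tr^2)
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    d2 <- tr_sq - 2 * drop(tr %*% x[i, ]) + sum(x[i, ]^2)
    nn <- order(d2, seq_along(d2))[seq_len(k)]
    votes <- table(model$labels[nn])
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (as.character(positive) %in% top) positive else as.integer(top[1])
  }
  out
}
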