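#' Concatenate per-trial embeddings from several extractors
#'
#' Early fusion starts from the raw concatenation of the heterogeneous
#' embeddings in the fixed extractor order R1 (LeNet-5, 120), R2 (GoogLeNet,
#' 1024), R3 (EfficientNet-B0, 1280); e.g. R1 + R2 gives 1144 columns.
#'
#' @param embeddings Named list of embedding matrices (same row count, rows =
#'   trials), in extractor order.
#' @return Matrix (trials x sum of embedding lengths) with a `sources`
#'   attribute.
#' @export
concat_embeddings <- function(embeddings) {
  if (is.matrix(embeddings)) return(embeddings)
  n <- vapply(embeddings, nrow, 1L)
  if (length(unique(n)) != 1) {
    stop("concat_embeddings: extractor sets are inconsistent across trials (row counts differ)")
  }
  out <- do.call(cbind, embeddings)
  attr(out, "sources") <- names(embeddings)
  out
}

#' Fit the PCA early-fusion model
#'
#' Standardises every dimension of the concatenated training embeddings to
#' zero mean and unit variance (training statistics only -- the model never
#' sees test rows), then finds the orthonormal directions of maximal variance
#' of the standardised matrix via singular value decomposition. `m_c = "max"`
#' retains every component of positive variance, i.e. `min(n_train - 1, d)`
#' components (139 for a 140-row training set). For determinism each
#' component's largest-magnitude loading is made positive.
#'
#' @param x Training matrix (n x d) of concatenated embeddings.
#' @param m_c Number of components, or `"max"`.
#' @return Object of class `pca_model`: `mean`, `sd` (zero-variance
#'   dimensions clamped to 1 and recorded), `W` (d x m_c, orthonormal
#'   columns), `variances` (non-increasing), `m_c`, `n_train`.
#' @export
pca_fit <- function(x, m_c = "max") {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 2) stop("pca_fit: need at least 2 training vectors")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero_var <- sdv == 0
  sdv[zero_var] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  sv <- svd(z)
  kmax <- min(n - 1L, d)
  k <- if (identical(m_c, "max")) kmax else min(as.integer(m_c), kmax)
  W <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| positive
  for (j in seq_len(k)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  variances <- sv$d[seq_len(k)]^2 / (n - 1)
  structure(list(mean = mu, sd = sdv, zero_variance = which(zero_var),
                 W = W, variances = variances, m_c = k, n_train = n),
            class = "pca_model")
}

#' Project embeddings through a fitted PCA fusion model
#'
#' Standardises with the training statistics and projects by the transpose of
#' the loading matrix, yielding the fused low-dimensional coordinates.
#'
#' @param model A `pca_model`.
#' @param x Matrix (rows x d) with `d` matching the model.
#' @return Matrix (rows x m_c) of fused vectors.
#' @export
pca_transform <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean)) {
    stop(sprintf("pca_transform: dimension mismatch (%d columns, model expects %d)",
                 ncol(x), length(model$mean)))
  }
  z <- sweep(sweep(x, 2, model$mean), 2, model$sd, "/")
  out <- z %*% model$W
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  out
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d -> %d components (n_train = %d)\n",
              length(x$mean), x$m_c, x$n_train))
  if (length(x$zero_variance)) {
    cat("  zero-variance dimensions clamped:", length(x$zero_variance), "\n")
  }
  invisible(x)
}
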