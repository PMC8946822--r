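#' Convert five-point gender ratings to the three-point scale
#'
#' The noun-rating arithmetic of the stimulus design: on the five-point scale
#' 1 = definitely female ... 5 = definitely male; the three-point scale folds
#' gender direction away, keeping only strength (3 = definitely gendered,
#' 2 = weakly gendered, 1 = neutral). Mapping: 1 -> 3, 2 -> 2, 3 -> 1,
#' 4 -> 2, 5 -> 3.
#'
#' @param ratings Integer vector with values in 1..5.
#' @return Integer vector of three-point ratings.
#' @export
convert_rating_scale <- function(ratings) {
  if (any(!(ratings %in% 1:5))) {
    stop("convert_rating_scale: ratings must be integers in 1..5")
  }
  c(3L, 2L, 1L, 2L, 3L)[ratings]
}

#' Two-sample t-test (pooled or Welch)
#'
#' Thin wrapper around [stats::t.test()] returning the statistic, two-sided p
#' value and degrees of freedom. The degenerate case of two identical
#' constant samples returns t = 0, p = 1.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param variant `"pooled"` (classic equal-variance) or `"welch"`.
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("two_sample_ttest: each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = variant == "pooled")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Two-sample t-test from summary statistics
#'
#' Closed form for published tables that report only per-group mean,
#' variance and size (reaction-time reports).
#'
#' @param m0,v0,n0 Mean, variance, size of sample 0.
#' @param m1,v1,n1 Mean, variance, size of sample 1.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List with `t`, `p`, `df`.
#' @export
ttest_from_summary <- function(m0, v0, n0, m1, v1, n1,
                               variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (variant == "welch") {
    se2 <- v0 / n0 + v1 / n1
    t <- (m0 - m1) / sqrt(se2)
    df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  } else {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    t <- (m0 - m1) / sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- n0 + n1 - 2
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Type-1 response accuracy
#'
#' Number and rate of correct referent choices among the unambiguous
#' (Class 1) trials, whose correct response is stored with the synthetic
#' design (or supplied with imported data).
#'
#' @param trials A session trial table (columns `label`, `response`,
#'   `correct`).
#' @return List with `n_correct`, `n_trials`, `rate` (NA with an `undefined`
#'   flag when there are no Class-1 trials).
#' @export
type1_accuracy <- function(trials) {
  t1 <- trials[trials$label == 1L, ]
  if (nrow(t1) == 0) {
    return(list(n_correct = 0L, n_trials = 0L, rate = NA_real_, undefined = TRUE))
  }
  n_ok <- sum(t1$response == t1$correct, na.rm = TRUE)
  list(n_correct = n_ok, n_trials = nrow(t1), rate = n_ok / nrow(t1),
       undefined = FALSE)
}

#' Type-0 response proportions
#'
#' Proportions of left (`Z`), right (`M`) and missing (`none`) responses over
#' the ambiguous (Class 0) trials.
#'
#' @param trials A session trial table.
#' @return Named numeric vector `c(Z, M, none)` summing to 1.
#' @export
type0_proportions <- function(trials) {
  t0 <- trials[trials$label == 0L, ]
  bad <- setdiff(unique(t0$response), c("Z", "M", "none"))
  if (length(bad)) {
    stop("type0_proportions: unknown response code(s): ", paste(bad, collapse = ", "))
  }
  n <- nrow(t0)
  c(Z = sum(t0$response == "Z") / n,
    M = sum(t0$response == "M") / n,
    none = sum(t0$response == "none") / n)
}

#' Per-feature two-sample t-tests between workload classes
#'
#' Pooled-variance two-sample t-test of every band-power feature between
#' Class 0 and Class 1 over the pooled feature vectors of all subjects. The
#' sign convention is Class 0 minus Class 1, so a feature that increases from
#' Class 0 to Class 1 yields a negative t. No multiple-testing correction is
#' applied to the 42 tests.
#'
#' @param features A pooled `feature_set` (both classes present).
#' @param alpha Significance level for the flag column.
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return Data frame with 42 rows: `feature`, `p`, `t`, `significant`.
#' @export
feature_ttests <- function(features, alpha = 0.05, variant = "pooled") {
  labs <- features$label
  if (length(unique(labs)) < 2) stop("feature_ttests: both classes must be present")
  fm <- feature_matrix(features)
  res <- lapply(feature_names(), function(fn) {
    tt <- two_sample_ttest(fm[labs == 0L, fn], fm[labs == 1L, fn], variant)
    data.frame(feature = fn, p = tt$p, t = tt$t)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  out
}

#' Per-condition baseline band power of one session
#'
#' Channel-averaged band power (theta, alpha, mean of beta and gamma) for
#' each of the six baseline conditions bracketing the five trial blocks.
#'
#' @param session An `eeg_session`.
#' @return 6 x 3 matrix (condition x band).
#' @export
baseline_band_summary <- function(session) {
  bands <- workload_bands()
  segs <- baseline_segments(session)
  out <- matrix(0, 6, 3, dimnames = list(paste0("cond", 1:6),
                                         c("theta", "alpha", "bg")))
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    th <- mean(apply(seg, 2, band_power, band = bands$theta, fs = session$fs))
    al <- mean(apply(seg, 2, band_power, band = bands$alpha, fs = session$fs))
    be <- mean(apply(seg, 2, band_power, band = bands$beta, fs = session$fs))
    ga <- mean(apply(seg, 2, band_power, band = bands$gamma, fs = session$fs))
    out[i, ] <- c(th, al, (be + ga) / 2)
  }
  out
}

#' Baseline habituation analysis
#'
#' Tests whether resting band power drifts over the experiment: for each band
#' the last baseline condition is compared against each of the five previous
#' conditions with a two-tailed paired t-test across subjects, Bonferroni
#' corrected for the five comparisons (corrected alpha = 0.05 / 5).
#'
#' @param summaries List of per-subject 6 x 3 baseline summaries
#'   ([baseline_band_summary()]) or of `eeg_session`s.
#' @param alpha Family significance level.
#' @return Data frame with `band`, `comparison`, `t`, `p`, `p_bonferroni`,
#'   `significant`.
#' @export
habituation_analysis <- function(summaries, alpha = 0.05) {
  summaries <- lapply(summaries, function(s) {
    if (inherits(s, "eeg_session")) baseline_band_summary(s) else s
  })
  if (any(vapply(summaries, function(s) any(dim(s) != c(6, 3)), TRUE))) {
    stop("habituation_analysis: each subject needs all 6 baseline conditions")
  }
  bands <- colnames(summaries[[1]])
  res <- list()
  for (b in bands) {
    mat <- t(vapply(summaries, function(s) s[, b], numeric(6))) # subjects x 6
    for (k in 1:5) {
      d <- mat[, 6] - mat[, k]
      if (stats::sd(d) == 0) {
        t <- 0; p <- 1
      } else {
        tt <- stats::t.test(mat[, 6], mat[, k], paired = TRUE)
        t <- unname(tt$statistic); p <- tt$p.value
      }
      res[[length(res) + 1L]] <- data.frame(
        band = b, comparison = sprintf("cond6 - cond%d", k), t = t, p = p)
    }
  }
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * 5)
  out$significant <- out$p_bonferroni < alpha
  out
}
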