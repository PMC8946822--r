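#' Band power of a single-channel segment
#'
#' One-sided periodogram power aggregated over a frequency band. The
#' periodogram is the squared DFT magnitude normalised so that the total over
#' all one-sided bins equals the mean squared signal (Parseval); negative
#' frequencies are folded onto their positive counterparts. The band is the
#' half-open interval `[f_lo, f_hi)`. The feature value is the mean over band
#' bins (absolute power, no window, no detrend, no log transform); `agg =
#' "sum"` gives the band-summed power used by energy-conservation checks.
#'
#' @param x Numeric vector (one channel of a trial segment).
#' @param band Length-2 numeric `c(f_lo, f_hi)` in Hz, `f_hi <= fs/2`.
#' @param fs Sampling rate in Hz.
#' @param agg `"mean"` (default, the feature definition) or `"sum"`.
#' @return Band power in microvolt^2.
#' @export
band_power <- function(x, band, fs = 128, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  n <- length(x)
  p <- periodogram_onesided(x)
  f <- (seq_along(p) - 1) * fs / n
  sel <- f >= band[1] & f < band[2]
  if (!any(sel)) stop("band_power: empty band (no DFT bins in [f_lo, f_hi))")
  if (agg == "mean") mean(p[sel]) else sum(p[sel])
}

# One-sided periodogram: bins k = 0..floor(n/2), sum over bins equals
# mean(x^2).
periodogram_onesided <- function(x) {
  n <- length(x)
  p2 <- abs(stats::fft(x))^2 / n^2
  half <- n %/% 2
  p <- p2[1:(half + 1)]
  if (n %% 2 == 0) {
    if (half > 1) p[2:half] <- 2 * p[2:half]
  } else {
    p[2:(half + 1)] <- 2 * p[2:(half + 1)]
  }
  p
}

#' Names of the 42 band-power features
#'
#' Band-major ordering: theta for the 14 channels in montage order, then
#' alpha, then the mean of beta and gamma (prefix `bg_`).
#' @return Character vector of length 42.
#' @export
feature_names <- function() {
  ch <- standard_montage()$channels
  c(paste0("theta_", ch), paste0("alpha_", ch), paste0("bg_", ch))
}

#' Extract the 42-dimensional band-power feature vectors
#'
#' For every trial segment: theta (4-8 Hz) and alpha (8-13 Hz) power per
#' channel, plus the arithmetic mean of the beta-band (14-30 Hz) and
#' gamma-band (31-40 Hz) powers per channel -- 3 features x 14 channels = 42
#' power spectral density features per 12-s trial.
#'
#' @param segments A `trial_segments` object.
#' @param subject Subject identifier stored with each feature vector.
#' @param bg `"mean_of_bands"` (default: average of the two per-band mean
#'   powers) or `"single_band"` (one 14-40 Hz band).
#' @return A `feature_set`: data.frame with columns `subject`, `trial`,
#'   `label` and the 42 named features (see [feature_names()]).
#' @export
extract_features <- function(segments, subject = 1L,
                             bg = c("mean_of_bands", "single_band")) {
  bg <- match.arg(bg)
  x <- segments$x
  if (dim(x)[2] != 14) {
    stop(sprintf("extract_features: expected 14 channels, got %d", dim(x)[2]))
  }
  n_trials <- dim(x)[3]
  n <- dim(x)[1]
  if (n_trials == 0) {
    out <- cbind(data.frame(subject = subject, trial = integer(0), label = integer(0))[0, ],
                 as.data.frame(matrix(0, 0, 42, dimnames = list(NULL, feature_names()))))
    class(out) <- c("feature_set", "data.frame")
    return(out)
  }
  bands <- workload_bands()
  # one multivariate DFT over all (channel, trial) columns
  p2 <- abs(stats::mvfft(matrix(x, n, 14 * n_trials)))^2 / n^2
  half <- n %/% 2
  p <- p2[1:(half + 1), , drop = FALSE]
  fold <- if (n %% 2 == 0) 2:half else 2:(half + 1)
  p[fold, ] <- 2 * p[fold, , drop = FALSE]
  f <- (1:(half + 1) - 1) * 128 / n
  bp <- function(b) {
    m <- colMeans(p[f >= b[1] & f < b[2], , drop = FALSE])
    matrix(m, n_trials, 14, byrow = TRUE) # columns were channel-fastest
  }
  bgpow <- if (bg == "mean_of_bands") {
    (bp(bands$beta) + bp(bands$gamma)) / 2
  } else {
    bp(c(bands$beta[1], bands$gamma[2]))
  }
  feat <- cbind(bp(bands$theta), bp(bands$alpha), bgpow)
  colnames(feat) <- feature_names()
  out <- data.frame(subject = subject, trial = seq_len(n_trials),
                    label = segments$labels)
  out <- cbind(out, as.data.frame(feat))
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Feature matrix of a feature set
#' @param features A `feature_set`.
#' @return Numeric matrix (trials x 42).
#' @export
feature_matrix <- function(features) {
  as.matrix(features[, feature_names(), drop = FALSE])
}
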