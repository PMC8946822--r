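#' Interpolate missing samples
#'
#' Replaces `NA` runs in each channel by linear interpolation between the
#' nearest valid neighbours; leading/trailing gaps take the nearest valid
#' value. Intended for the short acquisition drop-outs (well under a second)
#' the recording hardware produces.
#'
#' @param signal Samples x channels numeric matrix with `NA` marking missing
#'   samples (an `eeg_session$signal`), or an `eeg_session`.
#' @return Gap-free object of the same type.
#' @export
interpolate_missing <- function(signal) {
  if (inherits(signal, "eeg_session")) {
    signal$signal <- interpolate_missing(signal$signal)
    return(signal)
  }
  n <- nrow(signal)
  for (ch in seq_len(ncol(signal))) {
    x <- signal[, ch]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) {
      stop(sprintf("unrecoverable channel: channel %d is entirely missing", ch))
    }
    ok <- which(!miss)
    signal[miss, ch] <- stats::approx(ok, x[ok], xout = which(miss),
                                      method = "linear", rule = 2)$y
  }
  signal
}

#' Design the FIR bandpass kernel
#'
#' Windowed linear-phase FIR design via [signal::fir1()].
#' @param spec A [filter_spec()].
#' @return Numeric vector of `spec$taps` symmetric coefficients.
#' @export
fir_kernel <- function(spec) {
  w <- c(spec$low, spec$high) / (spec$fs / 2)
  as.numeric(signal::fir1(spec$taps - 1L, w, type = "pass",
                          window = signal::hamming(spec$taps)))
}

#' Apply the FIR bandpass filter
#'
#' Filters each channel of a continuous recording with the designed kernel.
#' Zero-phase mode applies the kernel forward and backward over an
#' odd-reflection edge padding (no group delay, squared magnitude response);
#' single-pass mode applies one causal convolution and compensates the
#' (taps-1)/2-sample group delay. Output length equals input length. The
#' continuous record is filtered before trial segmentation.
#'
#' @param signal Samples x channels matrix (or an `eeg_session`, filtered in
#'   place).
#' @param spec A [filter_spec()].
#' @return Filtered object of the same type and dimensions.
#' @export
fir_bandpass <- function(signal, spec = filter_spec()) {
  if (inherits(signal, "eeg_session")) {
    signal$signal <- fir_bandpass(signal$signal, spec)
    return(signal)
  }
  vec <- is.null(dim(signal))
  if (vec) signal <- matrix(signal, ncol = 1)
  n <- nrow(signal)
  if (n < 3L * spec$taps) {
    stop(sprintf("length error: signal (%d samples) shorter than 3 x %d filter taps",
                 n, spec$taps))
  }
  h <- fir_kernel(spec)
  L <- spec$taps
  delay <- (spec$taps - 1L) %/% 2L
  # odd reflection about the end points stabilises the filter edges
  xp <- rbind(2 * rep(1, L) %o% signal[1, ] - signal[(L + 1):2, , drop = FALSE],
              signal,
              2 * rep(1, L) %o% signal[n, ] - signal[(n - 1):(n - L), , drop = FALSE])
  # frequency-domain application at a 2/3-smooth length (exact linear
  # convolution: padding >= taps on both sides absorbs the circular wrap)
  nfft <- stats::nextn(nrow(xp) + 2L * spec$taps, c(2, 3))
  H <- stats::fft(c(h, numeric(nfft - L)))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - nrow(xp), ncol(xp))))
  if (spec$mode == "zero-phase") {
    # forward-backward: response |H|^2, symmetric kernel, no net delay
    Y <- X * Mod(H)^2
    y <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
    out <- y[(L + 1):(L + n), , drop = FALSE]
  } else {
    Y <- X * H
    y <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
    out <- y[(L + delay + 1):(L + delay + n), , drop = FALSE]
  }
  colnames(out) <- colnames(signal)
  if (vec) out <- out[, 1]
  out
}

#' Cut a session into labelled 12-s trial segments
#'
#' @param session An `eeg_session` (after filtering).
#' @param signal Optional samples x channels matrix overriding
#'   `session$signal` (e.g. a filtered copy).
#' @return An object of class `trial_segments`: list with `x` (array
#'   samples x channels x trials, 1536 x 14 x n), `labels`, and the session
#'   trial table.
#' @export
segment_trials <- function(session, signal = NULL) {
  if (is.null(signal)) signal <- session$signal
  trials <- session$trials
  len <- 12L * session$fs
  n <- nrow(signal)
  if (nrow(trials) == 0) {
    return(structure(list(x = array(0, c(len, ncol(signal), 0)),
                          labels = integer(0), trials = trials),
                     class = "trial_segments"))
  }
  bad <- which(trials$onset_sample + len - 1L > n | trials$onset_sample < 1L)
  if (length(bad) > 0) {
    stop(sprintf("segmentation error: trial(s) %s extend beyond the recording",
                 paste(trials$trial[bad], collapse = ", ")))
  }
  x <- array(0, c(len, ncol(signal), nrow(trials)))
  for (i in seq_len(nrow(trials))) {
    o <- trials$onset_sample[i]
    x[, , i] <- signal[o:(o + len - 1L), ]
  }
  dimnames(x) <- list(NULL, colnames(signal), NULL)
  structure(list(x = x, labels = trials$label, trials = trials),
            class = "trial_segments")
}
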