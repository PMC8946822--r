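#' Effect configuration for the synthetic session generator
#'
#' Describes the generative model of a synthetic recording session: a 1/f
#' background process, one band-limited oscillator per frequency band and
#' channel, white sensor noise, and class-dependent amplitude multipliers.
#' Under the default configuration the multiplier exceeds 1 exactly at the
#' eight (channel, band) pairs where the workload study found significant
#' band-power increases from Class 0 (ambiguous) to Class 1 (unambiguous):
#' theta at F3, F8, FC5, FC6; alpha at P7, P8; and both beta and gamma at F8
#' and T8 (so the derived mean beta/gamma feature carries the effect).
#'
#' @param multipliers 14 x 4 numeric matrix (channels x theta/alpha/beta/gamma)
#'   of Class-1 amplitude multipliers, all >= 0. Default: 1 everywhere except
#'   `effect_multiplier` at the eight significant pairs.
#' @param effect_multiplier Scalar multiplier applied at the significant pairs
#'   when `multipliers` is not supplied. Default 1.5.
#' @param background_exponent Exponent of the 1/f background spectrum.
#' @param background_sd Standard deviation (microvolt) of the 1/f background.
#' @param osc_amplitude Named numeric, oscillator base amplitude (microvolt)
#'   per band for Class 0 and the baselines.
#' @param noise_sd White sensor-noise SD (microvolt).
#' @param rt_mean,rt_sd Length-2 numeric (Class 0, Class 1): reaction-time
#'   mean and SD in milliseconds of the truncated-at-zero normal draw.
#' @param response_accuracy Probability that a Class-1 response matches the
#'   stored correct answer.
#' @param type0_response Length-3 probabilities (Z, M, none) for Class-0
#'   responses.
#' @param n_class0,n_class1 Trials per class (study design: 120 and 80).
#' @param baseline_s Duration in seconds of each of the 6 baseline segments.
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   (config, seed).
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(multipliers = NULL,
                          effect_multiplier = 1.5,
                          background_exponent = 1,
                          background_sd = 8,
                          osc_amplitude = c(theta = 0.55, alpha = 0.55, beta = 0.36, gamma = 0.27),
                          noise_sd = 2,
                          rt_mean = c(900, 650),
                          rt_sd = c(500, 350),
                          response_accuracy = 0.95,
                          type0_response = c(Z = 0.38, M = 0.6, none = 0.02),
                          n_class0 = 120,
                          n_class1 = 80,
                          baseline_s = 30,
                          seed = 1L) {
  channels <- standard_montage()$channels
  bands <- names(workload_bands())
  if (is.null(multipliers)) {
    multipliers <- matrix(1, 14, 4, dimnames = list(channels, bands))
    multipliers[c("F3", "F8", "FC5", "FC6"), "theta"] <- effect_multiplier
    multipliers[c("P7", "P8"), "alpha"] <- effect_multiplier
    multipliers[c("F8", "T8"), c("beta", "gamma")] <- effect_multiplier
  }
  multipliers <- as.matrix(multipliers)
  if (!all(dim(multipliers) == c(14, 4))) {
    stop("configuration error: 'multipliers' must be a 14 x 4 matrix")
  }
  dimnames(multipliers) <- list(channels, bands)
  num_ok <- function(x) all(is.finite(x)) && all(x >= 0)
  if (!num_ok(multipliers)) stop("configuration error: multipliers must be finite and >= 0")
  if (!num_ok(osc_amplitude) || length(osc_amplitude) != 4) {
    stop("configuration error: 'osc_amplitude' must be 4 finite non-negative values")
  }
  if (!num_ok(background_sd) || !num_ok(noise_sd)) {
    stop("configuration error: noise parameters must be finite and >= 0")
  }
  if (!num_ok(rt_sd) || !num_ok(rt_mean)) {
    stop("configuration error: reaction-time parameters must be finite and >= 0")
  }
  names(osc_amplitude) <- bands
  structure(list(
    multipliers = multipliers,
    background_exponent = background_exponent,
    background_sd = background_sd,
    osc_amplitude = osc_amplitude,
    noise_sd = noise_sd,
    rt_mean = rt_mean,
    rt_sd = rt_sd,
    response_accuracy = response_accuracy,
    type0_response = type0_response,
    n_class0 = as.integer(n_class0),
    n_class1 = as.integer(n_class1),
    baseline_s = baseline_s,
    seed = as.integer(seed)
  ), class = "effect_config")
}

#' FIR bandpass filter specification
#'
#' Linear-phase FIR design for the 4-45 Hz passband applied before feature
#' extraction. The default is a 255-tap Hamming-window design applied
#' forward-backward (zero phase). Band edges are nominal -6 dB cutoffs, the
#' windowed-design convention.
#'
#' @param low,high Passband edges in Hz; `0 < low < high < fs/2`.
#' @param taps Number of filter coefficients; must be odd for a symmetric
#'   (type-I linear-phase) kernel.
#' @param window Design window name (passed to [signal::fir1()]).
#' @param mode `"zero-phase"` (forward-backward with edge padding) or
#'   `"single-pass"` (causal convolution with group-delay compensation).
#' @param fs Sampling rate, Hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low = 4, high = 45, taps = 255,
                        window = "hamming",
                        mode = c("zero-phase", "single-pass"),
                        fs = 128) {
  mode <- match.arg(mode)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("filter_spec: need 0 < low < high < fs/2")
  }
  if (taps %% 2 != 1) stop("filter_spec: tap count must be odd")
  structure(list(low = low, high = high, taps = as.integer(taps),
                 window = window, mode = mode, fs = fs),
            class = "filter_spec")
}

# Evaluate code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. Keeps generators pure functions of their seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
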