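#' Generate a synthetic subject session
#'
#' Simulates one subject's continuous 14-channel, 128 Hz recording of the
#' pronoun-resolution experiment: `n_class0 + n_class1` trials of 12 s each
#' (default 120 ambiguous / 80 unambiguous, shuffled), organised in 5 blocks
#' of 40 trials bracketed by 6 baseline segments (before the first block and
#' after each block). Each trial's signal is the sum of a 1/f background, one
#' band-limited sinusoidal oscillator per frequency band (random frequency
#' within the band and random phase per trial/channel) whose amplitude is
#' scaled by the class multiplier of [effect_config()], and white sensor
#' noise. Baseline segments use Class-0 parameters. Reaction times, responses
#' and (for Class-1 trials) the stored correct answer are drawn alongside.
#'
#' @param config An [effect_config()]; its `seed` drives all randomness.
#' @return An object of class `eeg_session`: list with `signal` (samples x 14
#'   matrix, microvolt), `fs` (128), `montage`, `trials` (data.frame with
#'   trial, label, onset_sample, rt_ms, response, correct), `baseline_onsets`
#'   (6 sample indices), `baseline_samples` (segment length) and `config`.
#' @seealso [baseline_segments()], [segment_trials()], [write_session()]
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "effect_config"))
  with_seed(config$seed, {
    montage <- standard_montage()
    fs <- 128L
    trial_len <- 12L * fs
    n_trials <- config$n_class0 + config$n_class1
    bl_len <- as.integer(round(config$baseline_s * fs))
    n_blocks <- 5L
    per_block <- n_trials / n_blocks
    if (per_block != floor(per_block)) per_block <- ceiling(per_block)

    labels <- sample(rep(c(0L, 1L), c(config$n_class0, config$n_class1)))

    # layout: B | block1 | B | block2 | ... | block5 | B  (6 baselines)
    onsets <- integer(n_trials)
    bl_onsets <- integer(n_blocks + 1L)
    pos <- 1L
    t_i <- 1L
    for (blk in seq_len(n_blocks)) {
      bl_onsets[blk] <- pos
      pos <- pos + bl_len
      k <- min(per_block, n_trials - t_i + 1L)
      for (j in seq_len(k)) {
        onsets[t_i] <- pos
        pos <- pos + trial_len
        t_i <- t_i + 1L
      }
    }
    bl_onsets[n_blocks + 1L] <- pos
    n_samples <- pos + bl_len - 1L

    bands <- workload_bands()
    sig <- matrix(0, n_samples, 14, dimnames = list(NULL, montage$channels))
    tt_trial <- (seq_len(trial_len) - 1) / fs
    tt_bl <- (seq_len(bl_len) - 1) / fs

    # background + sensor noise, all channels at once
    sig[, ] <- noise_floor_matrix(n_samples, 14L, config$background_exponent,
                                  config$background_sd, config$noise_sd)

    # band oscillators, vectorised over (trial, channel) columns
    K <- n_trials * 14L
    nrK <- trial_len
    osc_sum <- matrix(0, nrK, K) # columns: trial fastest, then channel
    for (b in seq_along(bands)) {
      amp0 <- config$osc_amplitude[b]
      if (amp0 == 0) next
      lohi <- bands[[b]]
      f <- stats::runif(K, lohi[1], lohi[2])
      ph <- stats::runif(K, 0, 2 * pi)
      amp <- amp0 * rep(config$multipliers[, b], each = n_trials)^rep(labels == 1L, 14)
      ang <- outer(tt_trial, 2 * pi * f)
      ang <- ang + rep(ph, each = nrK)
      osc_sum <- osc_sum + sin(ang) * rep(amp, each = nrK)
    }
    trial_idx <- rep(onsets, each = trial_len) + rep.int(0:(trial_len - 1L), n_trials)
    osc_arr <- array(osc_sum, c(trial_len, n_trials, 14))
    sig[trial_idx, ] <- sig[trial_idx, ] + matrix(osc_arr, trial_len * n_trials, 14)

    # baselines: Class-0 parameters
    for (b in seq_along(bands)) {
      amp0 <- config$osc_amplitude[b]
      if (amp0 == 0) next
      lohi <- bands[[b]]
      fb <- matrix(stats::runif(6 * 14, lohi[1], lohi[2]), 6, 14)
      phb <- matrix(stats::runif(6 * 14, 0, 2 * pi), 6, 14)
      for (i in 1:6) {
        idx <- bl_onsets[i]:(bl_onsets[i] + bl_len - 1L)
        sig[idx, ] <- sig[idx, ] +
          amp0 * sin(outer(tt_bl, 2 * pi * fb[i, ]) + rep(phb[i, ], each = bl_len))
      }
    }

    rt <- generate_reaction_times(config, labels)
    correct <- ifelse(labels == 1L, sample(c("Z", "M"), n_trials, replace = TRUE), NA)
    response <- character(n_trials)
    i1 <- labels == 1L
    ok <- stats::runif(sum(i1)) < config$response_accuracy
    response[i1] <- ifelse(ok, correct[i1],
                           ifelse(correct[i1] == "Z", "M", "Z"))
    response[!i1] <- sample(names(config$type0_response), sum(!i1),
                            replace = TRUE, prob = config$type0_response)
    rt[response == "none"] <- NA_real_

    trials <- data.frame(
      trial = seq_len(n_trials), label = labels, onset_sample = onsets,
      rt_ms = rt, response = response, correct = correct,
      stringsAsFactors = FALSE
    )
    structure(list(
      signal = sig, fs = fs, montage = montage, trials = trials,
      baseline_onsets = bl_onsets, baseline_samples = bl_len,
      config = config, seed = config$seed
    ), class = "eeg_session")
  })
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %d channels x %d samples at %d Hz, %d trials (%d/%d per class)\n",
              ncol(x$signal), nrow(x$signal), x$fs, nrow(x$trials),
              sum(x$trials$label == 0), sum(x$trials$label == 1)))
  invisible(x)
}

# Stationary Gaussian noise floor: 1/f^alpha background (variance bg_sd^2)
# plus white sensor noise (variance noise_sd^2), synthesised directly in the
# frequency domain. Each complex inverse transform yields two independent
# real channels (real and imaginary part), and the sum of the two
# independent Gaussian processes is drawn in one pass through the quadrature
# sum of their spectral shapes. Transforms run at a 2/3-smooth length.
noise_floor_matrix <- function(n, ncol, exponent = 1, bg_sd = 1, noise_sd = 0) {
  nfft <- stats::nextn(n, c(2, 3))
  f <- c(1, seq_len(nfft - 1))
  f <- pmax(1, pmin(f, nfft - f))
  s2 <- f^(-exponent)
  s2[1] <- 0 # the 1/f background carries no DC
  shape <- sqrt((bg_sd^2 * s2 / mean(s2) + noise_sd^2) * 2 * nfft)
  npair <- ceiling(ncol / 2)
  g <- matrix(complex(real = stats::rnorm(nfft * npair),
                      imaginary = stats::rnorm(nfft * npair)) / sqrt(2),
              nfft, npair)
  z <- stats::mvfft(g * shape, inverse = TRUE) / nfft
  out <- matrix(0, n, 2 * npair)
  idx <- seq_len(n)
  for (j in seq_len(npair)) {
    out[, 2 * j - 1] <- Re(z[idx, j])
    out[, 2 * j] <- Im(z[idx, j])
  }
  out[, seq_len(ncol), drop = FALSE]
}

pink_noise <- function(n, exponent = 1) {
  x <- noise_floor_matrix(n, 1L, exponent, 1, 0)[, 1]
  x / stats::sd(x)
}

#' Draw per-trial reaction times
#'
#' Truncated-at-zero normal draws with class-specific mean and SD (defaults on
#' the scale of the study's reported reaction-time summaries: slower responses
#' for ambiguous Class-0 trials). Zero SD returns the class means exactly.
#'
#' @param config An [effect_config()] (fields `rt_mean`, `rt_sd`).
#' @param labels Integer vector of 0/1 class labels.
#' @return Numeric vector of reaction times (ms), same length as `labels`.
#' @export
generate_reaction_times <- function(config, labels) {
  if (any(config$rt_sd < 0)) stop("configuration error: negative reaction-time SD")
  if (any(config$rt_mean <= 0)) stop("configuration error: reaction-time means must be positive")
  mu <- config$rt_mean[labels + 1L]
  sd <- config$rt_sd[labels + 1L]
  rt <- stats::rnorm(length(labels), mu, sd)
  bad <- which(rt <= 0)
  guard <- 0L
  while (length(bad) > 0 && guard < 100L) {
    rt[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
    bad <- bad[rt[bad] <= 0]
    guard <- guard + 1L
  }
  rt[rt <= 0] <- 1 # pathological SD >> mean; clamp the stragglers
  rt
}

#' Mark short runs of samples as missing
#'
#' Fixture generator for the missing-value interpolation step: marks randomly
#' placed short runs (up to 1/4 s) of samples as `NA` per channel until the
#' requested fraction of each channel's samples is missing. Shape is
#' preserved; missingness is encoded as `NA` in memory and in the text format.
#'
#' @param session An `eeg_session`.
#' @param fraction Proportion of samples to drop per channel, `0 <= f < 0.5`.
#' @param seed Integer seed for the missing mask.
#' @return The session with `NA` gaps in `signal`.
#' @export
inject_missing <- function(session, fraction, seed = 1L) {
  if (fraction < 0 || fraction >= 0.5) {
    stop("inject_missing: fraction must be in [0, 0.5)")
  }
  if (fraction == 0) return(session)
  with_seed(seed, {
    n <- nrow(session$signal)
    max_run <- max(1L, session$fs %/% 4L)
    for (ch in seq_len(ncol(session$signal))) {
      target <- fraction * n
      dropped <- 0L
      while (dropped < target) {
        len <- sample.int(max_run, 1L)
        start <- sample.int(n - len + 1L, 1L)
        idx <- start:(start + len - 1L)
        session$signal[idx, ch] <- NA_real_
        dropped <- dropped + len
      }
    }
    session
  })
}

#' Extract the six baseline segments of a session
#'
#' @param session An `eeg_session`.
#' @return List of 6 matrices (samples x channels), one per baseline
#'   condition: before the first block and after each of the five blocks.
#' @export
baseline_segments <- function(session) {
  lapply(session$baseline_onsets, function(o) {
    session$signal[o:(o + session$baseline_samples - 1L), , drop = FALSE]
  })
}
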