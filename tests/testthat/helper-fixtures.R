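# Shared fixtures. Small sessions keep unit tests fast; default-size
# sessions are reserved for the acceptance suite.

small_config <- function(seed = 1L, ...) {
  effect_config(n_class0 = 12L, n_class1 = 8L, baseline_s = 4, seed = seed, ...)
}

# One default-size session, built once per test file that needs it.
.fixture_env <- new.env()

default_session <- function(seed = 42L) {
  key <- paste0("sess", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_session(effect_config(seed = seed))
  }
  .fixture_env[[key]]
}

# Features of the default session (filtered), cached.
default_features <- function(seed = 42L) {
  key <- paste0("feat", seed)
  if (is.null(.fixture_env[[key]])) {
    s <- default_session(seed)
    filt <- fir_bandpass(s$signal, filter_spec())
    .fixture_env[[key]] <- extract_features(segment_trials(s, filt))
  }
  .fixture_env[[key]]
}

expect_rounded_equal <- function(x, printed, digits = 4) {
  expect_equal(as.numeric(eegworkload:::round_half_up(x, digits)),
               as.numeric(printed), tolerance = 1e-12)
}
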