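#' Write a session as a delimited-text file pair
#'
#' `<prefix>_signal.csv` holds the continuous recording (`time_s` plus the 14
#' channel columns in montage order, microvolt; missing samples as the `NA`
#' sentinel) and `<prefix>_trials.csv` the trial table (trial, label,
#' onset_sample, rt_ms, response, correct).
#'
#' @param session An `eeg_session`.
#' @param prefix Path prefix for the two files.
#' @return Invisibly, the two file paths.
#' @export
write_session <- function(session, prefix) {
  sig <- data.frame(time_s = (seq_len(nrow(session$signal)) - 1) / session$fs,
                    session$signal, check.names = FALSE)
  sig_path <- paste0(prefix, "_signal.csv")
  tr_path <- paste0(prefix, "_trials.csv")
  utils::write.csv(sig, sig_path, row.names = FALSE)
  utils::write.csv(session$trials, tr_path, row.names = FALSE)
  invisible(c(sig_path, tr_path))
}

#' Read a session from a delimited-text file pair
#'
#' Validates the channel set against the montage and the sampling rate
#' against 128 Hz; malformed trial rows raise an error naming the offending
#' row.
#'
#' @param prefix Path prefix used by [write_session()].
#' @param montage Expected montage.
#' @return An `eeg_session` (baseline bookkeeping is not part of the text
#'   format and is left empty).
#' @export
read_session <- function(prefix, montage = standard_montage()) {
  sig <- utils::read.csv(paste0(prefix, "_signal.csv"), check.names = FALSE)
  trials <- utils::read.csv(paste0(prefix, "_trials.csv"),
                            stringsAsFactors = FALSE)
  if (!identical(colnames(sig)[-1], montage$channels)) {
    stop("format error: signal channels do not match the montage (",
         paste(colnames(sig)[-1], collapse = ","), ")")
  }
  fs <- 1 / stats::median(diff(sig$time_s))
  if (abs(fs - 128) > 0.5) {
    stop(sprintf("format error: sampling rate %.2f Hz, expected 128", fs))
  }
  req <- c("trial", "label", "onset_sample")
  miss <- setdiff(req, colnames(trials))
  if (length(miss)) stop("format error: trial table lacks column(s) ",
                         paste(miss, collapse = ", "))
  bad <- which(!(trials$label %in% c(0, 1)) | is.na(trials$onset_sample) |
                 trials$onset_sample < 1)
  if (length(bad)) {
    stop(sprintf("format error: malformed trial row(s) %s",
                 paste(bad, collapse = ", ")))
  }
  structure(list(signal = as.matrix(sig[, -1]), fs = 128L, montage = montage,
                 trials = trials, baseline_onsets = integer(0),
                 baseline_samples = 0L, config = NULL, seed = NA_integer_),
            class = "eeg_session")
}

#' Resolved run configuration
#'
#' Assembles the full pipeline configuration with every defaulted field made
#' explicit, so the configuration logged with a report completely determines
#' the run.
#'
#' @param seed Master seed; per-subject generator seeds are derived from it.
#' @param n_subjects Number of simulated subjects.
#' @param effect Arguments for [effect_config()] (list; per-subject seeds are
#'   filled in by the pipeline).
#' @param filter Arguments for [filter_spec()].
#' @param topomap List: `resolution`, `input_side` (extractor input side).
#' @param backbones Character subset of `c("lenet5", "googlenet",
#'   "efficientnet_b0")`, in extractor order.
#' @param fusion List: `components` (`"max"` or integer).
#' @param classifier Arguments for [classifier_spec()].
#' @param protocol List: `type` (`"holdout"`, `"kfold"`, or
#'   `"leaveout-repetition"`), `train_fraction`, `stratified`, `k`,
#'   `positive`, `f1`.
#' @return Object of class `run_config` (a nested list).
#' @export
run_config <- function(seed = 1L,
                       n_subjects = 15L,
                       effect = list(),
                       filter = list(),
                       topomap = list(resolution = 67L, input_side = 32L),
                       backbones = "lenet5",
                       fusion = list(components = "max"),
                       classifier = list(learner = "csvm"),
                       protocol = list(type = "holdout", train_fraction = 0.7,
                                       stratified = TRUE, k = 10L,
                                       positive = 0L, f1 = "macro")) {
  base <- list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    effect = effect, filter = filter,
    topomap = utils::modifyList(list(resolution = 67L, input_side = 32L), topomap),
    backbones = backbones,
    fusion = utils::modifyList(list(components = "max"), fusion),
    classifier = utils::modifyList(list(learner = "csvm"), classifier),
    protocol = utils::modifyList(
      list(type = "holdout", train_fraction = 0.7, stratified = TRUE,
           k = 10L, positive = 0L, f1 = "macro"), protocol)
  )
  # resolve the effect/filter defaults explicitly for the log
  ec <- do.call(effect_config, c(base$effect, list(seed = base$seed)))
  base$effect_resolved <- ec[setdiff(names(ec), c("multipliers"))]
  base$filter_resolved <- unclass(do.call(filter_spec, base$filter))
  structure(base, class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[c("seed", "n_subjects", "effect", "filter",
                            "topomap", "backbones", "fusion", "classifier",
                            "protocol")])
}

#' Bundled reference report tables
#'
#' Published per-participant summaries of the pronoun-resolution workload
#' experiment, shipped as plain CSVs for consistency checks of the report
#' arithmetic (mean rows, confusion-count reconciliation) and as scale
#' references for the synthetic generator: per-participant hold-out and
#' fusion classification metrics, reaction-time summary statistics, Type-1
#' accuracy rates, Type-0 response proportions, and the pooled per-feature
#' t-tests.
#'
#' @param name One of `"lenet5_holdout"`, `"fusion_leaveout"`,
#'   `"fusion_tenfold"`, `"reaction_time"`, `"type1_accuracy"`,
#'   `"type0_proportions"`, `"feature_ttests"`.
#' @return Data frame.
#' @export
reference_table <- function(name = c("lenet5_holdout", "fusion_leaveout",
                                     "fusion_tenfold", "reaction_time",
                                     "type1_accuracy", "type0_proportions",
                                     "feature_ttests")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("ref_", name, ".csv"),
                      package = "eegworkload", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
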