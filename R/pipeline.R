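#' Run the full decoding pipeline for one subject
#'
#' Preprocess (missing-value interpolation + FIR bandpass of the continuous
#' record), segment into 12-s trials, extract the 42 band-power features,
#' render and resize the scalp topographies, embed with the configured
#' extractors, PCA-fuse the concatenated embeddings (fit on training rows
#' only), train the shallow classifier and evaluate under the configured
#' protocol.
#'
#' @param session An `eeg_session`.
#' @param config A [run_config()].
#' @param weights Named list of extractor weights (shared across subjects);
#'   created on the fly if `NULL`.
#' @param split_seed Seed for the train/test split (defaults to the session
#'   seed).
#' @return List with `metrics` (`metric_set`), `features` (the subject's
#'   `feature_set`), `split`, and `n_trials`.
#' @export
subject_pipeline <- function(session, config = run_config(), weights = NULL,
                             split_seed = NULL) {
  if (is.null(split_seed)) {
    split_seed <- if (is.na(session$seed)) config$seed else session$seed
  }
  session <- interpolate_missing(session)
  fspec <- do.call(filter_spec, config$filter)
  filt <- fir_bandpass(session$signal, fspec)
  segs <- segment_trials(session, filt)
  features <- extract_features(segs, subject = session$seed)

  if (is.null(weights)) weights <- pipeline_weights(config)
  emb <- embed_features(features, config, weights)

  proto <- config$protocol
  labels <- features$label
  if (proto$type == "kfold") {
    cls_spec <- do.call(classifier_spec, config$classifier)
    pipe <- function(xtr, ytr, xte) {
      pca <- pca_fit(xtr, config$fusion$components)
      model <- workload_fit(cls_spec, pca_transform(pca, xtr), ytr)
      predict(model, pca_transform(pca, xte))
    }
    cv <- kfold_cv(emb, labels, pipe, k = proto$k, seed = split_seed,
                   positive = proto$positive, f1 = proto$f1)
    return(list(metrics = cv$pooled, features = features, split = cv$folds,
                n_trials = length(labels)))
  }
  split <- holdout_split(labels, proto$train_fraction, proto$stratified,
                         seed = split_seed)
  pca <- pca_fit(emb[split$train, , drop = FALSE], config$fusion$components)
  cls_spec <- do.call(classifier_spec, config$classifier)
  model <- workload_fit(cls_spec,
                        pca_transform(pca, emb[split$train, , drop = FALSE]),
                        labels[split$train])
  pred <- predict(model, pca_transform(pca, emb[split$test, , drop = FALSE]))
  metrics <- workload_metrics(
    confusion_counts(labels[split$test], pred, proto$positive), proto$f1)
  list(metrics = metrics, features = features, split = split,
       n_trials = length(labels))
}

# Extractor weights shared by every subject of a run.
pipeline_weights <- function(config) {
  w <- list()
  if ("lenet5" %in% config$backbones) {
    w$lenet5 <- lenet5_init(config$seed, input_side = config$topomap$input_side)
  }
  if ("googlenet" %in% config$backbones) w$googlenet <- googlenet_init(config$seed)
  if ("efficientnet_b0" %in% config$backbones) {
    w$efficientnet_b0 <- efficientnet_b0_init(config$seed)
  }
  w
}

# Topomap rendering + configured embeddings, concatenated in R1/R2/R3 order.
embed_features <- function(features, config, weights) {
  imgs <- render_topomap_batch(features, resolution = config$topomap$resolution)
  parts <- list()
  if ("lenet5" %in% config$backbones) {
    side <- config$topomap$input_side
    im1 <- if (side == config$topomap$resolution) imgs else {
      lapply(imgs, resize_topomap, side = side)
    }
    parts$R1 <- lenet5_embed(im1, weights$lenet5)
  }
  if (any(c("googlenet", "efficientnet_b0") %in% config$backbones)) {
    im224 <- lapply(imgs, resize_topomap, side = 224L)
    if ("googlenet" %in% config$backbones) {
      parts$R2 <- googlenet_embed(im224, weights$googlenet)
    }
    if ("efficientnet_b0" %in% config$backbones) {
      parts$R3 <- efficientnet_b0_embed(im224, weights$efficientnet_b0)
    }
  }
  concat_embeddings(parts)
}

#' Run the multi-subject study pipeline
#'
#' Generates (or accepts) one session per subject, runs [subject_pipeline()]
#' on each, and aggregates: per-subject metric rows, their unweighted mean,
#' and the one-sample t-test of the per-subject accuracies against chance.
#'
#' @param config A [run_config()].
#' @param sessions Optional list of `eeg_session`s; generated from the config
#'   when `NULL` (subject s uses seed `config$seed * 1000 + s`).
#' @param report_dir Optional directory to write the report CSVs into.
#' @param keep_features Also return the pooled per-subject `feature_set`
#'   (for feature-level statistics on the same simulated cohort).
#' @return Object of class `workload_report`: list with `subjects` (data
#'   frame of per-subject rows), `mean` (rounded mean row), `chance_test`,
#'   `config`, and `features` when requested.
#' @export
run_pipeline <- function(config = run_config(), sessions = NULL,
                         report_dir = NULL, keep_features = FALSE) {
  weights <- pipeline_weights(config)
  n <- if (is.null(sessions)) config$n_subjects else length(sessions)
  rows <- vector("list", n)
  feats <- if (keep_features) vector("list", n) else NULL
  for (s in seq_len(n)) {
    sess <- if (is.null(sessions)) {
      ec <- do.call(effect_config,
                    c(config$effect, list(seed = config$seed * 1000L + s)))
      generate_session(ec)
    } else {
      sessions[[s]]
    }
    res <- subject_pipeline(sess, config, weights)
    m <- res$metrics
    rows[[s]] <- data.frame(subject = s, Pacc = m$Pacc, F1 = m$F1,
                            Psen = m$Psen, Pspe = m$Pspe)
    if (keep_features) {
      f <- res$features
      f$subject <- s
      feats[[s]] <- f
    }
  }
  subjects <- do.call(rbind, rows)
  mean_row <- aggregate_subjects(subjects[, -1])
  chance <- accuracy_vs_chance(subjects$Pacc)
  report <- structure(list(subjects = subjects, mean = mean_row,
                           chance_test = chance, config = config),
                      class = "workload_report")
  if (keep_features) {
    pooled <- do.call(rbind, feats)
    class(pooled) <- c("feature_set", "data.frame")
    report$features <- pooled
  }
  if (!is.null(report_dir)) {
    dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- subjects
    tab[, -1] <- lapply(tab[, -1], round_half_up, 4)
    tab <- rbind(tab, data.frame(subject = NA, t(mean_row)))
    utils::write.csv(tab, file.path(report_dir, "per_subject_metrics.csv"),
                     row.names = FALSE)
    write_run_config(config, file.path(report_dir, "run_config.yaml"))
  }
  report
}

#' Simulate a cohort and pool its band-power features
#'
#' Generates one session per subject, preprocesses (interpolation + FIR
#' bandpass), segments and extracts the 42 band-power features, returning the
#' pooled labelled feature set (15 subjects at the default design give 1800
#' Class-0 and 1200 Class-1 vectors). This is the input of the pooled
#' per-feature t-tests.
#'
#' @param n_subjects Number of subjects.
#' @param effect List of [effect_config()] overrides.
#' @param seed Cohort seed (subject s uses `seed * 1000 + s`).
#' @param filter List of [filter_spec()] overrides.
#' @return A pooled `feature_set`.
#' @export
simulate_feature_cohort <- function(n_subjects = 15L, effect = list(),
                                    seed = 1L, filter = list()) {
  fspec <- do.call(filter_spec, filter)
  feats <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ec <- do.call(effect_config, c(effect, list(seed = seed * 1000L + s)))
    sess <- interpolate_missing(generate_session(ec))
    filt <- fir_bandpass(sess$signal, fspec)
    feats[[s]] <- extract_features(segment_trials(sess, filt), subject = s)
  }
  pooled <- do.call(rbind, feats)
  class(pooled) <- c("feature_set", "data.frame")
  pooled
}

#' @export
print.workload_report <- function(x, ...) {
  cat(sprintf("<workload_report> %d subjects, mean Pacc %.4f (t(%d) = %.2f vs 0.5)\n",
              nrow(x$subjects), x$mean["Pacc"], x$chance_test$df, x$chance_test$t))
  invisible(x)
}
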