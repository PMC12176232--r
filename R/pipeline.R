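#' Preprocessing and split configuration
#'
#' Bundles the data-conditioning parameters used by [train_pipeline()].
#'
#' @param outlier_method `"none"` or `"iqr"` (per-feature Tukey fences with
#'   a row-fraction trigger; see [iqr_outlier_mask()]).
#' @param iqr_k Tukey fence multiplier (default 1.5).
#' @param outlier_row_fraction Row-drop trigger (default 0.10).
#' @param select_min_abs_r Relevance threshold for [select_features()]
#'   (default 0 = keep all).
#' @param redundancy_r Pairwise redundancy threshold (default 0.95).
#' @param augment_factor Total copies per row from [augment_dataset()]
#'   (default 1 = no augmentation).
#' @param jitter_eps Augmentation jitter amplitude (default 0.01).
#' @param test_fraction Held-out fraction for [stratified_split()]
#'   (default 0.25).
#' @param augment_before_split If `TRUE`, augmentation runs before the
#'   split, so near-copies of training rows can land in the test set. The
#'   default `FALSE` augments the training partition only — the leakage-free
#'   order.
#' @param seed Integer seed driving every stochastic stage.
#' @return A list of class `"protclass_preprocess"`.
#' @export
pipeline_config <- function(outlier_method = c("none", "iqr"), iqr_k = 1.5,
                            outlier_row_fraction = 0.10,
                            select_min_abs_r = 0, redundancy_r = 0.95,
                            augment_factor = 1L, jitter_eps = 0.01,
                            test_fraction = 0.25,
                            augment_before_split = FALSE, seed = 1L) {
  outlier_method <- match.arg(outlier_method)
  stopifnot(
    iqr_k > 0, outlier_row_fraction >= 0, outlier_row_fraction <= 1,
    select_min_abs_r >= 0, select_min_abs_r <= 1,
    redundancy_r >= 0, redundancy_r <= 1,
    augment_factor >= 1, jitter_eps >= 0,
    test_fraction > 0, test_fraction < 1
  )
  structure(
    list(
      outlier_method = outlier_method, iqr_k = iqr_k,
      outlier_row_fraction = outlier_row_fraction,
      select_min_abs_r = select_min_abs_r, redundancy_r = redundancy_r,
      augment_factor = as.integer(augment_factor), jitter_eps = jitter_eps,
      test_fraction = test_fraction,
      augment_before_split = isTRUE(augment_before_split),
      seed = as.integer(seed)
    ),
    class = "protclass_preprocess"
  )
}

#' Run the full training pipeline on a labeled feature matrix
#'
#' The end-to-end path from features to a held-out evaluation:
#' optional IQR outlier removal, correlation-based feature selection,
#' stratified train/test split, optional class-wise replica augmentation
#' (training partition only, unless `augment_before_split`), model
#' training, and evaluation on the held-out partition. Every stochastic
#' stage derives from `config$seed`, so the whole run is reproducible.
#'
#' @param fm Labeled feature tibble from [featurize_dataset()].
#' @param model_config A [default_config()] (or algo name, expanded against
#'   the matrix's scheme with the pipeline seed).
#' @param config A [pipeline_config()].
#' @return A list of class `"protclass_run"` with elements `model`
#'   (trained on the training partition), `metrics` (held-out
#'   [evaluate_model()] report), `split`, `selection` (feature-selection
#'   report), `model_config` and `config`.
#' @export
train_pipeline <- function(fm, model_config, config = pipeline_config()) {
  stopifnot(inherits(config, "protclass_preprocess"))
  if (is.character(model_config)) {
    model_config <- default_config(model_config, scheme = fm_scheme(fm), seed = config$seed)
  }
  if (config$outlier_method == "iqr") {
    fm <- remove_outliers(fm,
      k = config$iqr_k, row_fraction = config$outlier_row_fraction,
      quiet = TRUE
    )
  }
  fm <- select_features(fm,
    min_abs_r = config$select_min_abs_r,
    redundancy_r = config$redundancy_r
  )
  selection <- attr(fm, "selection")
  if (config$augment_before_split && config$augment_factor > 1L) {
    fm <- augment_dataset(fm,
      factor = config$augment_factor,
      eps = config$jitter_eps, seed = config$seed
    )
  }
  split <- stratified_split(fm, test_fraction = config$test_fraction, seed = config$seed)
  train_fm <- split$train
  if (!config$augment_before_split && config$augment_factor > 1L) {
    train_fm <- augment_dataset(train_fm,
      factor = config$augment_factor,
      eps = config$jitter_eps, seed = config$seed
    )
  }
  model <- train(train_fm, model_config)
  metrics <- evaluate_model(model, split$test)
  structure(
    list(
      model = model, metrics = metrics, split = split,
      selection = selection, model_config = model_config, config = config
    ),
    class = "protclass_run"
  )
}

#' @export
print.protclass_run <- function(x, ...) {
  cat("<protclass run> ", x$model$config$algo, " on ",
    x$model$provenance$scheme$name, "\n",
    sep = ""
  )
  m <- x$metrics
  cat(sprintf(
    "  held-out: accuracy %.1f%%, recall %.1f%%, specificity %.1f%%, F1 %.1f%%\n",
    m$accuracy, m$recall, m$specificity, m$f1
  ))
  cat("  train/test rows:", x$model$provenance$n_train, "/", sum(m$tn, m$fp, m$fn, m$tp), "\n")
  invisible(x)
}
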