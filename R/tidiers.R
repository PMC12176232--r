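#' Tidy a metrics report
#'
#' Broom-style accessor: one row per metric, in percent.
#'
#' @param x A `"protclass_metrics"` result.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value`.
#' @export
tidy.protclass_metrics <- function(x, ...) {
  tibble(
    metric = c("accuracy", "recall", "specificity", "precision", "f1"),
    value = c(x$accuracy, x$recall, x$specificity, x$precision, x$f1)
  )
}

#' @rdname tidy.protclass_metrics
#' @export
glance.protclass_metrics <- function(x, ...) {
  out <- x[, c("accuracy", "recall", "specificity", "precision", "f1")]
  out$n <- x$tn + x$fp + x$fn + x$tp
  as_tibble(out)
}

#' Tidy a trained model
#'
#' One row per provenance fact of the fitted classifier; `glance()` gives a
#' one-row summary.
#'
#' @param x A `"protclass_model"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.protclass_model <- function(x, ...) {
  hp <- x$config$hyperparameters
  tibble(
    term = c("algo", "scheme", "n_features", "n_train", "seed", names(hp)),
    value = c(
      x$config$algo, x$provenance$scheme$name,
      as.character(length(x$provenance$features)),
      as.character(x$provenance$n_train), as.character(x$provenance$seed),
      vapply(hp, function(v) paste(format(v), collapse = ","), character(1))
    )
  )
}

#' @rdname tidy.protclass_model
#' @export
glance.protclass_model <- function(x, ...) {
  tibble(
    algo = x$config$algo,
    scheme = x$provenance$scheme$name,
    n_features = length(x$provenance$features),
    n_train = x$provenance$n_train,
    seed = x$provenance$seed
  )
}

#' Tidy a pipeline run
#'
#' @param x A `"protclass_run"` from [train_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: the held-out metric table; `glance()`: a one-row
#'   summary with algorithm, scheme, partition sizes and held-out accuracy.
#' @export
tidy.protclass_run <- function(x, ...) {
  tidy(x$metrics)
}

#' @rdname tidy.protclass_run
#' @export
glance.protclass_run <- function(x, ...) {
  tibble(
    algo = x$model$config$algo,
    scheme = x$model$provenance$scheme$name,
    n_train = x$model$provenance$n_train,
    n_test = x$metrics$tn + x$metrics$fp + x$metrics$fn + x$metrics$tp,
    n_features = length(x$model$provenance$features),
    accuracy = x$metrics$accuracy,
    f1 = x$metrics$f1
  )
}
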