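#' Confusion matrix from true and predicted labels
#'
#' @param y_true,y_pred Equal-length binary (0/1) label vectors.
#' @return An object of class `"protclass_cm"`: a list with integer counts
#'   `tn`, `fp`, `fn`, `tp`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  if (length(y_true) == 0L) stop("Need at least one observation", call. = FALSE)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("Labels must be binary (0/1)", call. = FALSE)
  }
  confusion_matrix(
    tn = sum(y_true == 0L & y_pred == 0L),
    fp = sum(y_true == 0L & y_pred == 1L),
    fn = sum(y_true == 1L & y_pred == 0L),
    tp = sum(y_true == 1L & y_pred == 1L)
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tn,fp,fn,tp Nonnegative integer counts, totalling at least 1.
#' @return A `"protclass_cm"` object.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("Confusion counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("Confusion matrix must have a positive total", call. = FALSE)
  structure(as.list(as.integer(counts)) |> setNames(names(counts)), class = "protclass_cm")
}

#' @export
print.protclass_cm <- function(x, ...) {
  m <- matrix(
    c(x$tn, x$fp, x$fn, x$tp), 2L, 2L, byrow = TRUE,
    dimnames = list(c("true 0", "true 1"), c("pred 0", "pred 1"))
  )
  print(m)
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Computes the benchmark study's four headline metrics (plus precision),
#' as percentages:
#' accuracy = 100 (TN+TP)/total, recall (sensitivity) = 100 TP/(TP+FN),
#' specificity = 100 TN/(TN+FP), precision = 100 TP/(TP+FP),
#' F1 = 2 * precision * recall / (precision + recall).
#' Any metric with a zero denominator is 0 by convention — in particular
#' TP = 0 forces F1 = 0, which is how an all-negative classifier is
#' reported. Display rounding is half-to-even at `digits` decimals and
#' recorded in the result; the returned values are unrounded.
#'
#' @param cm A `"protclass_cm"` (or anything [confusion_matrix()] accepts as
#'   a 4-element tn/fp/fn/tp list).
#' @param digits Display rounding (default 1 decimal).
#' @return A one-row tibble of class `"protclass_metrics"` with columns
#'   `accuracy`, `recall`, `specificity`, `precision`, `f1`, the four
#'   counts, and a `rounding` column; the confusion matrix rides along in
#'   attribute `"cm"`.
#' @export
metrics_from_counts <- function(cm, digits = 1L) {
  if (!inherits(cm, "protclass_cm")) cm <- do.call(confusion_matrix, as.list(cm))
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  frac <- function(num, den) if (den == 0) 0 else 100 * num / den
  accuracy <- frac(cm$tn + cm$tp, total)
  recall <- frac(cm$tp, cm$tp + cm$fn)
  specificity <- frac(cm$tn, cm$tn + cm$fp)
  precision <- frac(cm$tp, cm$tp + cm$fp)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  out <- tibble(
    accuracy = accuracy, recall = recall, specificity = specificity,
    precision = precision, f1 = f1,
    tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp,
    rounding = as.integer(digits)
  )
  attr(out, "cm") <- cm
  class(out) <- unique(c("protclass_metrics", class(out)))
  out
}

#' Evaluate a trained model on a labeled feature matrix
#'
#' Predicts, tallies the confusion matrix, and reports metrics together
#' with the audit trail (algorithm, seed, data digest, n).
#'
#' @param model A `"protclass_model"`.
#' @param fm Labeled feature tibble matching the model's provenance.
#' @return A `"protclass_metrics"` tibble (see [metrics_from_counts()])
#'   with attributes `cm`, `predictions` and `audit`.
#' @export
evaluate_model <- function(model, fm) {
  stopifnot("label" %in% names(fm))
  pred <- predict(model, fm)
  cm <- confusion_counts(fm$label, pred$label)
  out <- metrics_from_counts(cm)
  attr(out, "predictions") <- pred
  attr(out, "audit") <- list(
    algo = model$config$algo,
    scheme = model$provenance$scheme$name,
    seed = model$provenance$seed,
    n = nrow(fm),
    data_digest = feature_digest(fm)
  )
  out
}

# order-sensitive digest of ids, labels and feature values
feature_digest <- function(fm) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, open = "wb")
  serialize(list(fm$id, fm$label, feature_values(fm)), con, version = 2L)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Serialize a metrics report to JSON
#'
#' @param metrics A `"protclass_metrics"` result.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (invisibly) or the JSON string.
#' @export
write_metrics_json <- function(metrics, path = NULL) {
  cm <- attr(metrics, "cm")
  payload <- list(
    cm = list(tn = cm$tn, fp = cm$fp, fn = cm$fn, tp = cm$tp),
    metrics = list(
      accuracy = metrics$accuracy, recall = metrics$recall,
      specificity = metrics$specificity, precision = metrics$precision,
      f1 = metrics$f1
    ),
    audit = attr(metrics, "audit")
  )
  payload$audit$scheme <- payload$audit$scheme %||% NULL
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) {
    return(json)
  }
  writeLines(json, path)
  invisible(path)
}

#' Check printed metric values against a confusion matrix
#'
#' Recomputes the four metrics from `cm` and flags each supplied printed
#' value (a point value or a `[lo, hi]` range) as consistent or not. A
#' printed value passes when the recomputed metric falls within the range
#' widened by half a unit in the value's last printed decimal place — i.e.
#' agreement up to display rounding. This is a documentation tool: it
#' reports inconsistencies in published tables, it never "fixes" them.
#'
#' @param cm A `"protclass_cm"`.
#' @param printed A tibble/data frame with columns `metric` (one of
#'   `accuracy`, `recall`, `specificity`, `precision`, `f1`), `lo`, `hi`
#'   (equal for point values) and optionally `digits` (printed decimal
#'   places; default inferred from `lo`/`hi`).
#' @return A tibble with columns `metric`, `recomputed`, `lo`, `hi`,
#'   `consistent`.
#' @export
table_check <- function(cm, printed) {
  printed <- as_tibble(printed)
  stopifnot(all(c("metric", "lo", "hi") %in% names(printed)))
  m <- metrics_from_counts(cm)
  recomputed <- vapply(printed$metric, function(name) {
    if (!name %in% c("accuracy", "recall", "specificity", "precision", "f1")) {
      stop("Unknown metric: ", name, call. = FALSE)
    }
    m[[name]]
  }, numeric(1))
  digits <- if ("digits" %in% names(printed)) {
    printed$digits
  } else {
    pmax(decimal_places(printed$lo), decimal_places(printed$hi))
  }
  tol <- 0.5 * 10^(-digits) + 1e-9
  tibble(
    metric = printed$metric,
    recomputed = unname(recomputed),
    lo = printed$lo,
    hi = printed$hi,
    consistent = recomputed >= printed$lo - tol & recomputed <= printed$hi + tol
  )
}

decimal_places <- function(x) {
  vapply(x, function(v) {
    s <- sub("0+$", "", sub(".*\\.", "", format(v, scientific = FALSE)))
    if (grepl("\\.", format(v, scientific = FALSE))) nchar(s) else 0L
  }, integer(1))
}
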