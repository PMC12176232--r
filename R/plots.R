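#' Plot a confusion matrix
#'
#' Tile plot of the four confusion counts.
#'
#' @param object A `"protclass_cm"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protclass_cm <- function(object, ...) {
  df <- tibble(
    truth = factor(c("negative", "negative", "positive", "positive"),
      levels = c("positive", "negative")
    ),
    prediction = factor(c("negative", "positive", "negative", "positive"),
      levels = c("negative", "positive")
    ),
    count = c(object$tn, object$fp, object$fn, object$tp)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot a metrics report
#'
#' Bar chart of the five evaluation metrics (percent).
#'
#' @param object A `"protclass_metrics"` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protclass_metrics <- function(object, ...) {
  df <- tidy(object)
  df$metric <- factor(df$metric, levels = df$metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$value)), vjust = -0.4) +
    ggplot2::ylim(0, 105) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' Plot feature-selection scores
#'
#' Dot plot of the absolute point-biserial correlation of each feature with
#' the class label, coloured by selection outcome. With more than
#' `max_features` features only the top-scoring ones are shown.
#'
#' @param run A `"protclass_run"` (or a selection report tibble from
#'   [select_features()]).
#' @param max_features Cap on displayed features (default 40).
#' @return A ggplot object.
#' @export
plot_feature_scores <- function(run, max_features = 40L) {
  report <- if (inherits(run, "protclass_run")) run$selection else as_tibble(run)
  stopifnot(all(c("feature", "abs_r", "kept") %in% names(report)))
  report <- dplyr::arrange(report, dplyr::desc(.data$abs_r))
  report <- head(report, max_features)
  report$feature <- factor(report$feature, levels = rev(report$feature))
  ggplot2::ggplot(report, ggplot2::aes(
    x = .data$abs_r, y = .data$feature,
    colour = .data$kept
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "|point-biserial r| with label", y = NULL, colour = "kept"
    ) +
    ggplot2::theme_minimal()
}
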