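#' Flag outlier rows by the per-feature Tukey IQR rule
#'
#' For every feature, values outside \[Q1 - k*IQR, Q3 + k*IQR\] are flagged;
#' a row is marked for removal when the fraction of its features that are
#' flagged exceeds `row_fraction`. The row-fraction trigger keeps
#' high-dimensional encodings (DPC's 400 mostly-sparse columns) from losing
#' every row to a handful of benign extremes.
#'
#' @param fm Feature tibble with at least 4 rows.
#' @param k Fence multiplier (default 1.5, the classical Tukey fence).
#' @param row_fraction Fraction of flagged features above which a row is
#'   dropped (default 0.10).
#' @return Logical vector, `TRUE` = keep the row.
#' @export
iqr_outlier_mask <- function(fm, k = 1.5, row_fraction = 0.10) {
  stopifnot(is.data.frame(fm))
  if (nrow(fm) < 4L) {
    stop("IQR outlier detection needs at least 4 rows", call. = FALSE)
  }
  vals <- feature_values(fm)
  flagged <- apply(vals, 2L, function(x) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2L] - q[1L]
    x < q[1L] - k * iqr | x > q[2L] + k * iqr
  })
  rowMeans(flagged) <= row_fraction
}

#' Remove outlier rows
#'
#' Convenience wrapper applying [iqr_outlier_mask()] and reporting counts.
#'
#' @inheritParams iqr_outlier_mask
#' @param quiet Suppress the count message.
#' @return The filtered feature tibble.
#' @export
remove_outliers <- function(fm, k = 1.5, row_fraction = 0.10, quiet = FALSE) {
  keep <- iqr_outlier_mask(fm, k = k, row_fraction = row_fraction)
  if (!quiet && any(!keep)) {
    message("Outlier removal: dropped ", sum(!keep), " of ", nrow(fm), " rows")
  }
  fm[keep, , drop = FALSE]
}

#' Point-biserial feature scores against the class label
#'
#' Absolute Pearson correlation between each feature and the 0/1 label
#' (equivalently the point-biserial correlation). Zero-variance features
#' score 0 by convention.
#'
#' @param fm Labeled feature tibble with both classes present and n >= 3.
#' @return A tibble with columns `feature`, `abs_r`, sorted in the original
#'   column order.
#' @export
pearson_feature_scores <- function(fm) {
  stopifnot(is.data.frame(fm), "label" %in% names(fm))
  y <- as.numeric(fm$label)
  if (length(unique(y)) < 2L) {
    stop("Both classes must be present to score features", call. = FALSE)
  }
  if (nrow(fm) < 3L) stop("Need at least 3 rows", call. = FALSE)
  vals <- feature_values(fm)
  r <- suppressWarnings(as.numeric(cor(vals, y)))
  r[!is.finite(r)] <- 0
  tibble(feature = colnames(vals), abs_r = abs(r))
}

#' Correlation-based feature selection
#'
#' Two stages, both driven by Pearson correlation:
#' 1. *relevance*: drop features whose absolute point-biserial correlation
#'    with the label is below `min_abs_r`;
#' 2. *redundancy*: scan the survivors in decreasing `abs_r` (ties broken by
#'    original column order) and drop any feature whose absolute pairwise
#'    Pearson correlation with an already-kept feature exceeds
#'    `redundancy_r`.
#'
#' @param fm Labeled feature tibble.
#' @param min_abs_r Relevance threshold in \[0, 1\] (default 0 = keep all).
#' @param redundancy_r Pairwise redundancy threshold (default 0.95;
#'   1.0 disables the redundancy stage for non-identical columns).
#' @return The reduced feature tibble, with a selection report in attribute
#'   `"selection"`: a tibble of all input features with their `abs_r`,
#'   whether they were kept, and the rule that dropped them.
#' @export
select_features <- function(fm, min_abs_r = 0, redundancy_r = 0.95) {
  scores <- pearson_feature_scores(fm)
  status <- rep("kept", nrow(scores))
  status[scores$abs_r < min_abs_r] <- "low_relevance"

  cand_idx <- which(status == "kept")
  ord <- cand_idx[order(-scores$abs_r[cand_idx], cand_idx, method = "radix")]
  vals <- feature_values(fm)
  keep <- integer(0)
  for (j in ord) {
    redundant <- FALSE
    xj <- vals[, j]
    for (i in keep) {
      r <- suppressWarnings(cor(xj, vals[, i]))
      if (is.finite(r) && abs(r) > redundancy_r) {
        redundant <- TRUE
        break
      }
    }
    if (redundant) {
      status[j] <- "redundant"
    } else {
      keep <- c(keep, j)
    }
  }
  if (length(keep) == 0L) {
    stop("Feature selection removed every feature; lower min_abs_r", call. = FALSE)
  }
  kept_cols <- scores$feature[sort(keep)]
  out <- fm[, c(intersect(c("id", "label"), names(fm)), kept_cols), drop = FALSE]
  attr(out, "scheme") <- fm_scheme(fm)
  class(out) <- class(fm)
  report <- tibble(
    feature = scores$feature,
    abs_r = scores$abs_r,
    kept = seq_len(nrow(scores)) %in% keep,
    dropped_by = ifelse(status == "kept", NA_character_, status)
  )
  attr(out, "selection") <- report
  out
}

#' Class-wise numerical-replica augmentation
#'
#' Expands a feature matrix by generating, per class, `factor - 1` jittered
#' replicas of every row: each feature of a replica is perturbed with
#' Gaussian noise of standard deviation `eps` times that feature's
#' class-wise standard deviation (so `eps = 0` gives exact duplicates and
#' zero-variance features are never perturbed). Replica ids carry an
#' `_aug<k>` suffix. Class proportions and feature count are preserved
#' exactly; the operation is a pure function of (input, factor, eps, seed).
#'
#' @param fm Labeled feature tibble.
#' @param factor Total copies of each row in the output (>= 1; 1 = no-op).
#' @param eps Relative jitter amplitude (default 0.01).
#' @param seed Integer seed.
#' @return The augmented feature tibble (originals first, then replicas in
#'   replica-index order).
#' @export
augment_dataset <- function(fm, factor = 2L, eps = 0.01, seed = 1L) {
  stopifnot(is.data.frame(fm), "label" %in% names(fm))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (eps < 0) stop("eps must be nonnegative", call. = FALSE)
  if (factor == 1L) {
    return(fm)
  }
  cols <- feature_names(fm)
  vals <- feature_values(fm, cols)
  # class-wise per-feature sd (sample sd; 0 when a class has a single row)
  sds <- matrix(0, nrow = nrow(fm), ncol = length(cols))
  for (lab in unique(fm$label)) {
    rows <- fm$label == lab
    s <- apply(vals[rows, , drop = FALSE], 2L, sd)
    s[!is.finite(s)] <- 0
    sds[rows, ] <- matrix(s, nrow = sum(rows), ncol = length(cols), byrow = TRUE)
  }
  replicas <- withr::with_seed(seed, {
    lapply(seq_len(factor - 1L), function(k) {
      noise <- matrix(rnorm(length(vals)), nrow = nrow(vals))
      rep_vals <- vals + eps * sds * noise
      rep_tbl <- fm
      rep_tbl[cols] <- as.data.frame(rep_vals)
      rep_tbl$id <- paste0(fm$id, "_aug", k)
      rep_tbl
    })
  })
  out <- dplyr::bind_rows(c(list(fm), replicas))
  attr(out, "scheme") <- fm_scheme(fm)
  class(out) <- class(fm)
  out
}

#' Stratified train/test split
#'
#' Random per-class partition: each class contributes
#' `floor(n_class * test_fraction)` rows to the test set (remainder to
#' train), so the split is disjoint, exhaustive, and keeps class balance.
#'
#' @param fm Labeled feature tibble; both classes need >= 2 rows.
#' @param test_fraction Fraction held out (default 0.25, the 75/25 split the
#'   benchmark study reports for its DPC experiments).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
stratified_split <- function(fm, test_fraction = 0.25, seed = 1L) {
  stopifnot(is.data.frame(fm), "label" %in% names(fm))
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  counts <- table(fm$label)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("Each class needs at least 2 rows to split", call. = FALSE)
  }
  test_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(fm)), fm$label), function(idx) {
      n_test <- floor(length(idx) * test_fraction)
      if (n_test == 0L) integer(0) else sample(idx, n_test)
    }), use.names = FALSE)
  })
  keep_attrs <- function(x) {
    attr(x, "scheme") <- fm_scheme(fm)
    class(x) <- class(fm)
    x
  }
  train_idx <- setdiff(seq_len(nrow(fm)), test_idx)
  list(
    train = keep_attrs(fm[train_idx, , drop = FALSE]),
    test = keep_attrs(fm[sort(test_idx), , drop = FALSE])
  )
}
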