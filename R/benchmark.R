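#' Reported benchmark results for CML protein-sequence classifiers
#'
#' The published benchmark study of chronic myeloid leukemia prediction from
#' protein sequences reports, for six classifiers on each of three encodings
#' (PseAAC, AAC, DPC), a confusion matrix and four metrics (accuracy, F1,
#' recall, specificity) — the metrics as ranges for PseAAC/DPC and as point
#' values for AAC. This function returns all 18 confusion matrices together
#' with the reported metric values, in tidy long form (one row per reported
#' metric cell, 72 rows). These tables are the arithmetic cross-checking
#' surface of the package: several reported cells are internally
#' inconsistent with their own confusion matrices, which
#' [check_benchmark_tables()] flags.
#'
#' @return A tibble with columns `scheme`, `algo`, `tn`, `fp`, `fn`, `tp`,
#'   `metric`, `lo`, `hi`, `digits` (printed decimal places).
#' @export
cml_benchmark_tables <- function() {
  cm_rows <- function(scheme, algo, tn, fp, fn, tp, acc, f1, rec, spec) {
    bounds <- rbind(acc, f1, rec, spec)
    tibble(
      scheme = scheme, algo = algo, tn = tn, fp = fp, fn = fn, tp = tp,
      metric = c("accuracy", "f1", "recall", "specificity"),
      lo = bounds[, 1L], hi = bounds[, 2L], digits = as.integer(bounds[, 3L])
    )
  }
  pt <- function(x, digits) c(x, x, digits)
  rg <- function(lo, hi) c(lo, hi, 0)
  dplyr::bind_rows(
    # -- PseAAC: metric ranges -------------------------------------------
    cm_rows("PseAAC", "svc", 424, 28, 14, 211,
      rg(92, 94), rg(91, 92), rg(91, 93), rg(92, 94)
    ),
    cm_rows("PseAAC", "xgb", 26159, 2271, 3435, 10890,
      rg(79, 85), rg(63, 70), rg(51, 55), rg(92, 94)
    ),
    cm_rows("PseAAC", "lr", 25817, 2849, 11010, 3445,
      rg(66, 69), rg(10, 20), rg(6, 10), rg(97, 98)
    ),
    cm_rows("PseAAC", "dt", 24388, 4278, 3803, 10652,
      rg(81, 84), rg(73, 76), rg(74, 76), rg(84, 86)
    ),
    cm_rows("PseAAC", "rf", 28014, 808, 2753, 11546,
      rg(87, 91), rg(85, 87), rg(80, 83), rg(96, 97)
    ),
    cm_rows("PseAAC", "knn", 419, 23, 95, 140,
      rg(82, 86), rg(72, 74), rg(61, 64), rg(93, 95)
    ),
    # -- AAC: point values ------------------------------------------------
    cm_rows("AAC", "svc", 271, 0, 121, 62,
      pt(54.95, 2), pt(14.3, 1), pt(0.7, 1), pt(100, 0)
    ),
    cm_rows("AAC", "xgb", 409, 23, 119, 103,
      pt(56.8, 1), pt(52.9, 1), pt(45.9, 1), pt(69, 0)
    ),
    cm_rows("AAC", "lr", 9028, 2022, 8519, 2025,
      pt(51.1, 1), pt(27.6, 1), pt(19.1, 1), pt(81.7, 1)
    ),
    cm_rows("AAC", "dt", 124, 98, 95, 107,
      pt(54.4, 1), pt(52.25, 2), pt(52.9, 1), pt(55.8, 1)
    ),
    cm_rows("AAC", "rf", 12612, 6817, 11832, 6510,
      pt(50.6, 1), pt(41.1, 1), pt(35.4, 1), pt(64.9, 1)
    ),
    cm_rows("AAC", "knn", 112, 105, 89, 118,
      pt(54.2, 1), pt(54.8, 1), pt(57, 0), pt(51, 0)
    ),
    # -- DPC: metric ranges ----------------------------------------------
    cm_rows("DPC", "svc", 416, 37, 17, 207,
      rg(92, 94), rg(87, 88), rg(91, 93), rg(90, 93)
    ),
    cm_rows("DPC", "xgb", 413, 25, 105, 134,
      rg(79, 84), rg(66, 68), rg(55, 57), rg(92, 94)
    ),
    cm_rows("DPC", "lr", 453, 0, 224, 0,
      rg(66, 69), rg(0, 0), rg(6, 10), rg(100, 100)
    ),
    cm_rows("DPC", "dt", 433, 16, 54, 134,
      rg(81, 84), rg(70, 73), rg(56, 59), rg(96, 97)
    ),
    cm_rows("DPC", "rf", 437, 23, 93, 124,
      rg(82, 84), rg(67, 68), rg(57, 58), rg(94, 95)
    ),
    cm_rows("DPC", "knn", 438, 15, 179, 45,
      rg(72, 73), rg(31, 32), rg(20, 21), rg(95, 97)
    )
  )
}

#' Cross-check the reported benchmark tables
#'
#' Runs [table_check()] over every reported confusion matrix from
#' [cml_benchmark_tables()]: each reported metric cell is recomputed from
#' its own confusion matrix and flagged as consistent (within display
#' rounding of the reported value/range) or inconsistent. Inconsistent
#' cells are findings about the published tables, not failures of the
#' recomputation.
#'
#' @return A tibble with columns `scheme`, `algo`, `metric`, `recomputed`,
#'   `lo`, `hi`, `consistent`.
#' @examples
#' checks <- check_benchmark_tables()
#' dplyr::count(checks, consistent)
#' @export
check_benchmark_tables <- function() {
  tab <- cml_benchmark_tables()
  groups <- split(tab, paste(tab$scheme, tab$algo), drop = TRUE)
  out <- lapply(groups, function(g) {
    cm <- confusion_matrix(tn = g$tn[1L], fp = g$fp[1L], fn = g$fn[1L], tp = g$tp[1L])
    chk <- table_check(cm, g[, c("metric", "lo", "hi", "digits")])
    dplyr::bind_cols(tibble(scheme = g$scheme, algo = g$algo), chk)
  })
  res <- dplyr::bind_rows(out)
  # restore table order (split() sorts by name)
  key <- paste(res$scheme, res$algo, res$metric)
  res[match(paste(tab$scheme, tab$algo, tab$metric), key), , drop = FALSE]
}
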