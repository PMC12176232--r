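#' Describe a feature-encoding scheme
#'
#' Constructs the descriptor that travels with every feature matrix and
#' trained model: which encoder to run and with which parameters. Three
#' encoders are supported:
#'
#' * `"AAC"` — amino-acid composition, 20 percentage frequencies;
#' * `"DPC"` — di-peptide composition, 400 ordered-pair frequencies;
#' * `"PseAAC"` — Chou's pseudo amino-acid composition, 20 residue
#'   fractions plus `lambda` sequence-order correlation factors.
#'
#' @param name `"AAC"`, `"DPC"` or `"PseAAC"` (case-insensitive).
#' @param lambda Number of sequence-order tiers (PseAAC only). Default 5,
#'   giving the 25-dimensional encoding used by the benchmark study.
#' @param w Weight of the sequence-order terms (PseAAC only); default 0.05,
#'   the conventional choice.
#' @param dpc_mode `"fraction"` (divide dipeptide counts by L-1, the
#'   standard definition; vector sums to 1) or `"per400"` (divide by the 400
#'   dipeptide types, as the benchmark study prints its formula; vector sums
#'   to (L-1)/400).
#' @param property_table Property tibble from [load_property_table()]
#'   (PseAAC only); `NULL` loads the shipped default.
#' @return An object of class `"protclass_scheme"` with fields `name`,
#'   `dimension`, `feature_names`, and the relevant parameters.
#' @export
feature_scheme <- function(name, lambda = 5L, w = 0.05,
                           dpc_mode = c("fraction", "per400"),
                           property_table = NULL) {
  name <- toupper(as.character(name))
  name <- c(AAC = "AAC", DPC = "DPC", PSEAAC = "PseAAC", PAAC = "PseAAC")[[name]]
  if (is.null(name) || is.na(name)) {
    stop("Unknown scheme; expected one of AAC, DPC, PseAAC", call. = FALSE)
  }
  dpc_mode <- match.arg(dpc_mode)
  sch <- switch(name,
    AAC = list(
      name = "AAC", dimension = 20L,
      feature_names = paste0("AAC_", AA_ALPHABET)
    ),
    DPC = list(
      name = "DPC", dimension = 400L, dpc_mode = dpc_mode,
      feature_names = paste0("DPC_", DIPEPTIDES)
    ),
    PseAAC = {
      lambda <- as.integer(lambda)
      if (lambda < 0L) stop("lambda must be >= 0", call. = FALSE)
      if (lambda > 0L && w <= 0) stop("w must be positive when lambda > 0", call. = FALSE)
      list(
        name = "PseAAC", dimension = 20L + lambda, lambda = lambda, w = w,
        property_table = property_table %||% load_property_table(),
        feature_names = paste0("PAAC_", seq_len(20L + lambda))
      )
    }
  )
  structure(sch, class = "protclass_scheme")
}

#' @export
print.protclass_scheme <- function(x, ...) {
  cat("<feature scheme> ", x$name, " (", x$dimension, " features)\n", sep = "")
  if (x$name == "PseAAC") cat("  lambda =", x$lambda, " w =", x$w, "\n")
  if (x$name == "DPC") cat("  mode =", x$dpc_mode, "\n")
  invisible(x)
}

residue_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(
      "Sequence contains noncanonical residue(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  table(factor(chars, levels = AA_ALPHABET))
}

#' Amino-acid composition (AAC)
#'
#' Percentage frequency of each of the 20 canonical residues:
#' 100 * n_i / L for residue i, so the vector always sums to 100.
#'
#' @param seq A protein sequence (string) or single-row record tibble.
#' @return Named numeric vector of length 20 (alphabetical residue order).
#' @examples
#' compute_aac("ACDE") # four residues at 25 percent each
#' @export
compute_aac <- function(seq) {
  seq <- as_sequence(seq)
  if (!nzchar(seq)) stop("Cannot featurize an empty sequence", call. = FALSE)
  counts <- residue_counts(seq)
  v <- 100 * as.numeric(counts) / sum(counts)
  setNames(v, paste0("AAC_", AA_ALPHABET))
}

#' Di-peptide composition (DPC)
#'
#' Frequencies of the 400 ordered residue pairs over the L-1 overlapping
#' length-2 windows of the sequence. With `mode = "fraction"` counts are
#' divided by L-1 (standard; sums to 1); with `mode = "per400"` they are
#' divided by the 400 dipeptide types, reproducing the benchmark study's
#' printed formula (sums to (L-1)/400, i.e. the vector scale grows with
#' sequence length).
#'
#' @param seq A protein sequence (string) or single-row record tibble of
#'   length at least 2.
#' @param mode `"fraction"` (default) or `"per400"`.
#' @return Named numeric vector of length 400 in row-major order
#'   (AA, AC, ..., YY).
#' @export
compute_dpc <- function(seq, mode = c("fraction", "per400")) {
  mode <- match.arg(mode)
  seq <- as_sequence(seq)
  L <- nchar(seq)
  if (L < 2L) stop("DPC requires a sequence of length >= 2", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(
      "Sequence contains noncanonical residue(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  pairs <- paste0(chars[-L], chars[-1L])
  counts <- table(factor(pairs, levels = DIPEPTIDES))
  denom <- if (mode == "fraction") L - 1L else 400L
  setNames(as.numeric(counts) / denom, paste0("DPC_", DIPEPTIDES))
}

#' Physicochemical dissimilarity between two residues
#'
#' The squared-difference correlation function of classical pseudo
#' amino-acid composition: the mean of the squared differences of the
#' standardized hydrophobicity, hydrophilicity and side-chain mass of the
#' two residues. Symmetric, nonnegative, and zero for identical residues.
#'
#' @param r1,r2 Single canonical residue letters.
#' @param props Property tibble from [load_property_table()].
#' @return A nonnegative scalar.
#' @export
theta <- function(r1, r2, props = load_property_table()) {
  i <- match(r1, props$residue)
  j <- match(r2, props$residue)
  if (is.na(i) || is.na(j)) {
    stop("Unknown residue: ", if (is.na(i)) r1 else r2, call. = FALSE)
  }
  cols <- c("hydrophobicity_norm", "hydrophilicity_norm", "side_chain_mass_norm")
  mean(vapply(cols, function(cl) (props[[cl]][j] - props[[cl]][i])^2, numeric(1)))
}

#' Sequence-order correlation factor
#'
#' Tier-k correlation factor of pseudo amino-acid composition: the average
#' [theta()] dissimilarity between residues k positions apart,
#' T_k = (1/(L-k)) * sum over i of Theta(R_i, R_(i+k)).
#'
#' @param seq A protein sequence (string) or single-row record tibble.
#' @param k Tier (1 <= k < L).
#' @param props Property tibble from [load_property_table()].
#' @return A nonnegative scalar.
#' @export
correlation_factor <- function(seq, k, props = load_property_table()) {
  seq <- as_sequence(seq)
  L <- nchar(seq)
  k <- as.integer(k)
  if (k < 1L || k >= L) {
    stop("Tier k must satisfy 1 <= k < sequence length (L = ", L, ")", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, props$residue)
  if (anyNA(idx)) {
    stop("Sequence contains noncanonical residue(s)", call. = FALSE)
  }
  cols <- c("hydrophobicity_norm", "hydrophilicity_norm", "side_chain_mass_norm")
  total <- 0
  for (cl in cols) {
    v <- props[[cl]][idx]
    total <- total + sum((v[(1L + k):L] - v[1L:(L - k)])^2)
  }
  total / (3 * (L - k))
}

#' Pseudo amino-acid composition (PseAAC)
#'
#' Chou's (20 + lambda)-dimensional encoding. With f_u the fraction of
#' residue u (so the fractions sum to 1) and T_k the tier-k
#' [correlation_factor()]:
#'
#' * components 1..20: f_u / (1 + w * sum(T_k)),
#' * components 21..20+lambda: w * T_(u-20) / (1 + w * sum(T_k)),
#'
#' so the full vector sums to 1. With `lambda = 0` the encoding reduces
#' exactly to the AAC fractions.
#'
#' @param seq A protein sequence (string) or single-row record tibble with
#'   length L > `lambda`.
#' @param lambda Number of sequence-order tiers (default 5 -> 25 features).
#' @param w Sequence-order weight (default 0.05).
#' @param props Property tibble from [load_property_table()].
#' @return Named numeric vector of length 20 + lambda.
#' @export
compute_pseaac <- function(seq, lambda = 5L, w = 0.05, props = load_property_table()) {
  seq <- as_sequence(seq)
  lambda <- as.integer(lambda)
  L <- nchar(seq)
  if (lambda < 0L) stop("lambda must be >= 0", call. = FALSE)
  if (L <= lambda) {
    stop(
      "Sequence length (", L, ") must exceed lambda (", lambda,
      "); use a smaller lambda or a longer sequence",
      call. = FALSE
    )
  }
  if (lambda > 0L && w <= 0) stop("w must be positive when lambda > 0", call. = FALSE)
  f <- as.numeric(residue_counts(seq)) / L
  tk <- if (lambda > 0L) {
    vapply(seq_len(lambda), function(k) correlation_factor(seq, k, props), numeric(1))
  } else {
    numeric(0)
  }
  denom <- 1 + w * sum(tk)
  v <- c(f / denom, w * tk / denom)
  setNames(v, paste0("PAAC_", seq_along(v)))
}

#' Encode a whole dataset as a feature matrix
#'
#' Applies the scheme's encoder to every record and returns a tidy feature
#' matrix: one row per record, columns `id`, `label` (when present in `ds`),
#' then the scheme's features in canonical order. The scheme descriptor is
#' attached as attribute `"scheme"` for provenance. Any record that fails
#' the encoder's length precondition aborts the run with its id — rows are
#' never silently dropped.
#'
#' @param ds A (labeled) record tibble.
#' @param scheme A [feature_scheme()] or a scheme name understood by it.
#' @return A tibble of class `"protclass_features"`.
#' @examples
#' ds <- attach_labels(
#'   tibble::tibble(id = "p1", description = "", sequence = "MKVLQAPK"),
#'   tibble::tibble(id = "n1", description = "", sequence = "GGSTNDEA")
#' )
#' featurize_dataset(ds, "AAC")
#' @export
featurize_dataset <- function(ds, scheme) {
  stopifnot(is.data.frame(ds), all(c("id", "sequence") %in% names(ds)))
  if (!inherits(scheme, "protclass_scheme")) scheme <- feature_scheme(scheme)
  encoder <- switch(scheme$name,
    AAC = function(s) compute_aac(s),
    DPC = function(s) compute_dpc(s, mode = scheme$dpc_mode),
    PseAAC = function(s) {
      compute_pseaac(s, lambda = scheme$lambda, w = scheme$w, props = scheme$property_table)
    }
  )
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    tryCatch(encoder(ds$sequence[i]), error = function(e) {
      stop(
        "Failed to featurize record '", ds$id[i], "': ", conditionMessage(e),
        call. = FALSE
      )
    })
  })
  mat <- do.call(rbind, rows)
  out <- as_tibble(as.data.frame(mat))
  names(out) <- scheme$feature_names
  meta <- tibble(id = ds$id)
  if ("label" %in% names(ds)) meta$label <- as.integer(ds$label)
  out <- dplyr::bind_cols(meta, out)
  new_feature_matrix(out, scheme)
}

new_feature_matrix <- function(tbl, scheme) {
  stopifnot(anyDuplicated(tbl$id) == 0L)
  vals <- as.matrix(tbl[, setdiff(names(tbl), c("id", "label")), drop = FALSE])
  if (!all(is.finite(vals))) {
    stop("Feature matrix contains non-finite values", call. = FALSE)
  }
  attr(tbl, "scheme") <- scheme
  class(tbl) <- unique(c("protclass_features", class(tbl)))
  tbl
}

#' Feature columns of a feature matrix
#'
#' @param fm A feature tibble from [featurize_dataset()].
#' @return Character vector of feature column names (everything except
#'   `id`/`label`).
#' @export
feature_names <- function(fm) {
  setdiff(names(fm), c("id", "label"))
}

# numeric matrix view of the feature columns
feature_values <- function(fm, cols = feature_names(fm)) {
  m <- as.matrix(fm[, cols, drop = FALSE])
  rownames(m) <- fm$id
  m
}

fm_scheme <- function(fm) attr(fm, "scheme")

#' Write / read a feature matrix as CSV
#'
#' The CSV carries `id` and (when present) `label` first, then the feature
#' columns in canonical order. The scheme is re-derived from the header on
#' read (PseAAC parameters from the column count; DPC mode is recorded in a
#' comment-free sidecar-less convention: pass it explicitly if non-default).
#'
#' @param fm Feature tibble.
#' @param path CSV path.
#' @return `write_feature_csv`: `path`, invisibly. `read_feature_csv`: a
#'   feature tibble.
#' @export
write_feature_csv <- function(fm, path) {
  write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @param dpc_mode DPC normalization of the file being read, if the scheme
#'   is DPC and was produced with a non-default mode.
#' @export
read_feature_csv <- function(path, dpc_mode = "fraction") {
  df <- as_tibble(read.csv(path, check.names = FALSE))
  feats <- setdiff(names(df), c("id", "label"))
  scheme <- if (all(startsWith(feats, "AAC_"))) {
    feature_scheme("AAC")
  } else if (all(startsWith(feats, "DPC_"))) {
    feature_scheme("DPC", dpc_mode = dpc_mode)
  } else if (all(startsWith(feats, "PAAC_"))) {
    feature_scheme("PseAAC", lambda = length(feats) - 20L)
  } else {
    stop("Cannot infer encoding scheme from CSV header", call. = FALSE)
  }
  df$id <- as.character(df$id)
  if (!setequal(feats, scheme$feature_names) && !all(feats %in% scheme$feature_names)) {
    stop("CSV feature columns do not match the inferred scheme", call. = FALSE)
  }
  # tolerate column-selected matrices: keep file order, validate names subset
  new_feature_matrix(df, scheme)
}
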