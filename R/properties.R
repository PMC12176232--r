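#' Load a per-residue physicochemical property table
#'
#' Reads a 4-column TSV (`residue`, `hydrophobicity`, `hydrophilicity`,
#' `side_chain_mass`) covering the 20 canonical residues and adds the
#' standardized variants that the pseudo amino-acid composition correlation
#' function uses. The default table ships with the package: hydrophobicity,
#' Hopp-Woods hydrophilicity, and side-chain mass — the three properties of
#' the classical pseudo amino-acid composition formulation.
#'
#' @param path Path to a property TSV; `NULL` (default) loads the shipped
#'   table.
#' @return A tibble with the raw columns plus `hydrophobicity_norm`,
#'   `hydrophilicity_norm`, `side_chain_mass_norm`, each standardized to
#'   mean 0 and population standard deviation 1 over the 20 residues.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "protclass")
  }
  raw <- as_tibble(read.delim(path, header = TRUE, sep = "\t"))
  needed <- c("residue", "hydrophobicity", "hydrophilicity", "side_chain_mass")
  if (!all(needed %in% names(raw))) {
    stop(
      "Property table must have columns: ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  if (!setequal(raw$residue, AA_ALPHABET) || nrow(raw) != 20L) {
    stop("Property table must cover exactly the 20 canonical residues", call. = FALSE)
  }
  raw <- raw[match(AA_ALPHABET, raw$residue), , drop = FALSE]
  for (col in needed[-1]) {
    raw[[paste0(col, "_norm")]] <- normalize_property(raw[[col]])
  }
  raw
}

#' Standardize a 20-value property vector
#'
#' Centers and scales per-residue property values to mean 0 and population
#' standard deviation 1 (divisor 20, not 19) — the conventional
#' pre-treatment before computing sequence-order correlation factors, which
#' puts hydrophobicity, hydrophilicity and side-chain mass on a common scale.
#'
#' @param raw Numeric vector of 20 finite values, not all equal.
#' @return The standardized vector.
#' @export
normalize_property <- function(raw) {
  if (length(raw) != 20L || !all(is.finite(raw))) {
    stop("Expected 20 finite property values", call. = FALSE)
  }
  mu <- mean(raw)
  sigma <- sqrt(mean((raw - mu)^2))
  if (sigma == 0) {
    stop("Property values are all equal; cannot standardize", call. = FALSE)
  }
  (raw - mu) / sigma
}
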