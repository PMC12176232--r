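#' Generate a synthetic labeled protein dataset
#'
#' Seeded stand-in for a curated positive/negative protein collection:
#' negative sequences are drawn i.i.d. from the uniform composition over the
#' 20 canonical residues; positive sequences from a composition in which the
#' probabilities of a designated residue subset are multiplied by
#' `(1 + delta)` and the vector renormalized. Lengths are uniform on
#' `length_range`. `delta = 0` makes the classes exchangeable (a null
#' dataset); larger `delta` plants a compositional signal that AAC/PseAAC
#' encoders measure directly, so pipeline recovery can be checked against an
#' analytic ground truth.
#'
#' @param n_pos,n_neg Class sizes (either may be 0, not both).
#' @param length_range Integer `c(min, max)` sequence length, default
#'   `c(80, 120)`.
#' @param delta Nonnegative composition boost for the positive class
#'   (default 2).
#' @param boosted Residues whose probability is boosted in positives
#'   (default `c("A", "L", "K")`).
#' @param seed Integer seed.
#' @return A labeled record tibble (`id`, `description`, `sequence`,
#'   `label`), positives first.
#' @export
generate_dataset <- function(n_pos, n_neg, length_range = c(80L, 120L),
                             delta = 2, boosted = c("A", "L", "K"),
                             seed = 1L) {
  n_pos <- as.integer(n_pos)
  n_neg <- as.integer(n_neg)
  if (n_pos < 0L || n_neg < 0L || n_pos + n_neg < 1L) {
    stop("Need nonnegative class sizes with at least one record", call. = FALSE)
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1L] < 1L ||
    length_range[1L] > length_range[2L]) {
    stop("length_range must be c(min, max) with 1 <= min <= max", call. = FALSE)
  }
  if (delta < 0) stop("delta must be nonnegative", call. = FALSE)
  if (!all(boosted %in% AA_ALPHABET)) {
    stop("boosted residues must be canonical amino acids", call. = FALSE)
  }
  p_neg <- setNames(rep(1 / 20, 20L), AA_ALPHABET)
  p_pos <- p_neg
  p_pos[boosted] <- p_pos[boosted] * (1 + delta)
  p_pos <- p_pos / sum(p_pos)

  draw <- function(n, prefix, probs) {
    if (n == 0L) {
      return(character(0))
    }
    vapply(seq_len(n), function(i) {
      L <- if (length_range[1L] == length_range[2L]) {
        length_range[1L]
      } else {
        sample(length_range[1L]:length_range[2L], 1L)
      }
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
  }
  withr::with_seed(seed, {
    pos_seqs <- draw(n_pos, "pos", p_pos)
    neg_seqs <- draw(n_neg, "neg", p_neg)
    pos <- tibble(
      id = sprintf("pos_%04d", seq_len(n_pos)),
      description = "synthetic positive",
      sequence = pos_seqs
    )
    neg <- tibble(
      id = sprintf("neg_%04d", seq_len(n_neg)),
      description = "synthetic negative",
      sequence = neg_seqs
    )
    if (n_pos == 0L) pos <- pos[0L, ]
    if (n_neg == 0L) neg <- neg[0L, ]
    attach_labels(pos, neg)
  })
}

#' Plant near-identical homologs of a sequence
#'
#' Generates `n` mutated copies of `base`, each with
#' `ceiling((1 - identity_target) * L)` randomly chosen positions
#' substituted by a different residue — so a copy's alignment identity to
#' the base is approximately `identity_target`. Used to exercise the
#' redundancy filter with a known cluster structure.
#'
#' @param base A protein sequence (string) or single-row record tibble of
#'   length >= 10.
#' @param n Number of copies.
#' @param identity_target Fraction in (0, 1]; 1 gives exact copies.
#' @param seed Integer seed.
#' @return A record tibble of `n` copies with ids `<hom1>`, `<hom2>`, ...
#' @export
plant_homologs <- function(base, n, identity_target = 0.9, seed = 1L) {
  base <- as_sequence(base)
  L <- nchar(base)
  if (L < 10L) stop("Base sequence must have length >= 10", call. = FALSE)
  if (!(identity_target > 0 && identity_target <= 1)) {
    stop("identity_target must be in (0, 1]", call. = FALSE)
  }
  n_mut <- ceiling((1 - identity_target) * L)
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      mutated <- chars
      if (n_mut > 0L) {
        pos <- sample(L, n_mut)
        for (p in pos) {
          mutated[p] <- sample(setdiff(AA_ALPHABET, mutated[p]), 1L)
        }
      }
      paste(mutated, collapse = "")
    }, character(1))
    tibble(
      id = sprintf("hom%d", seq_len(n)),
      description = sprintf("planted homolog (target identity %.2f)", identity_target),
      sequence = seqs
    )
  })
}
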