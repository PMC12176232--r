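#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) alignment identity between two protein
#' sequences, following the CD-HIT convention: the number of identical
#' aligned columns divided by the length of the shorter sequence. The
#' alignment is scored with match +1, mismatch 0 and a linear gap penalty of
#' -1, computed exactly (no k-mer prefilter), via
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a,b Protein sequences (character strings) or single-row record
#'   tibbles with a `sequence` column.
#' @return Identity fraction in \[0, 1\]; symmetric, and 1 for `a == b`.
#' @examples
#' pairwise_identity("MKVLQ", "MKVIQ") # 4 matching columns / 5 -> 0.8
#' @export
pairwise_identity <- function(a, b) {
  a <- as_sequence(a)
  b <- as_sequence(b)
  if (!nzchar(a) || !nzchar(b)) {
    stop("Cannot compute identity of an empty sequence", call. = FALSE)
  }
  if (a == b) {
    return(1)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global",
    substitutionMatrix = identity_substitution_matrix(),
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

as_sequence <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "sequence" %in% names(x))
    x <- x$sequence
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

identity_substitution_matrix <- function() {
  m <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(m) <- 1
  m
}

#' Greedy identity-threshold clustering
#'
#' CD-HIT-style greedy incremental clustering: records are sorted by
#' decreasing sequence length (ties broken by ascending id), the longest
#' becomes the first cluster representative, and each subsequent record
#' joins the first existing representative with [pairwise_identity()] at or
#' above `threshold`, otherwise founds a new cluster. Deterministic for a
#' given input.
#'
#' @param records A record tibble (columns `id`, `sequence`).
#' @param threshold Identity cutoff in (0, 1]; the benchmark study used 0.6.
#' @return A tibble with columns `id`, `representative` and `is_representative`,
#'   one row per input record, carrying the threshold in attribute
#'   `"threshold"`.
#' @export
greedy_cluster <- function(records, threshold = 0.6) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) {
    stop("No records to cluster", call. = FALSE)
  }
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  ord <- order(-nchar(records$sequence), records$id, method = "radix")
  ids <- records$id[ord]
  seqs <- records$sequence[ord]

  rep_idx <- integer(0) # indices (into ord-ed vectors) of representatives
  assigned <- character(length(ids))
  for (i in seq_along(ids)) {
    home <- NA_character_
    for (r in rep_idx) {
      if (pairwise_identity(seqs[i], seqs[r]) >= threshold) {
        home <- ids[r]
        break
      }
    }
    if (is.na(home)) {
      rep_idx <- c(rep_idx, i)
      home <- ids[i]
    }
    assigned[i] <- home
  }
  out <- tibble(
    id = ids,
    representative = assigned,
    is_representative = ids == assigned
  )
  # restore input order
  out <- out[match(records$id, out$id), , drop = FALSE]
  attr(out, "threshold") <- threshold
  out
}

#' Remove redundant sequences from a labeled dataset
#'
#' Applies [greedy_cluster()] within each class separately (so a positive can
#' never be absorbed by a negative representative) and keeps one
#' representative per cluster, preserving labels.
#'
#' @param ds A labeled record tibble from [attach_labels()].
#' @param threshold Identity cutoff in (0, 1] (default 0.6).
#' @param quiet Suppress the before/after count message.
#' @return The deduplicated labeled tibble, rows in original order.
#' @export
dedupe_dataset <- function(ds, threshold = 0.6, quiet = FALSE) {
  stopifnot(is.data.frame(ds), "label" %in% names(ds))
  keep_ids <- unlist(lapply(split(ds, ds$label), function(part) {
    cl <- greedy_cluster(part, threshold)
    cl$id[cl$is_representative]
  }), use.names = FALSE)
  out <- ds[ds$id %in% keep_ids, , drop = FALSE]
  if (!quiet) {
    message(
      "Redundancy filter (threshold ", threshold, "): ",
      nrow(ds), " -> ", nrow(out), " sequences (",
      sum(ds$label == 1L), "/", sum(ds$label == 0L), " -> ",
      sum(out$label == 1L), "/", sum(out$label == 0L), " pos/neg)"
    )
  }
  out
}
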