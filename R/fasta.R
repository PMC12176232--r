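#' Read protein sequences from a FASTA file
#'
#' Parses a plain-text FASTA file into a tibble with one row per record.
#' Header lines start with `">"`; the record id is the token after the first
#' `"|"` when the header carries `"|"`-delimited fields (the UniProt
#' convention, e.g. `>sp|P08238|HS90B_HUMAN`), otherwise the first
#' whitespace-delimited token. Multi-line sequences are concatenated and
#' uppercased.
#'
#' Residues outside the canonical 20-letter alphabet (`B`, `J`, `O`, `U`,
#' `X`, `Z`, `*`, gap characters, ...) are handled according to `policy`:
#'
#' * `"drop_residue"` (default): remove them, with a warning naming the
#'   affected records. UniProt keyword dumps routinely contain `X`/`U`/`B`,
#'   so this is the permissive default.
#' * `"reject"`: raise an error naming the first offending record and
#'   position; use for strict runs.
#' * `"map_to_exclusion"`: drop the whole record, with a warning.
#'
#' @param path Path to a FASTA file.
#' @param policy How to treat nonstandard residues; one of
#'   `"drop_residue"`, `"reject"`, `"map_to_exclusion"`.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P001|HSP90 heat shock", "MKV", "LQ"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, policy = c("drop_residue", "reject", "map_to_exclusion")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[[:space:]]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("Empty FASTA file: ", path, call. = FALSE)
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("Sequence data before any '>' header in ", path, call. = FALSE)
  }
  rec_idx <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  seqs <- unname(vapply(
    split(lines[!is_header], factor(rec_idx[!is_header], levels = seq_along(headers))),
    function(x) paste(x, collapse = ""),
    character(1)
  ))
  ids <- vapply(headers, parse_fasta_id, character(1), USE.NAMES = FALSE)
  desc <- vapply(headers, parse_fasta_description, character(1), USE.NAMES = FALSE)

  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(
      "Record(s) without sequence data: ",
      paste(ids[empty], collapse = ", "),
      call. = FALSE
    )
  }
  seqs <- toupper(seqs)

  clean <- sanitize_sequences(seqs, ids, policy)
  records <- tibble(id = ids, description = desc, sequence = clean$sequence)
  if (policy == "map_to_exclusion") {
    records <- records[!clean$excluded, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("No records left after applying policy '", policy, "'", call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop(
      "Duplicate record ids within one file: ",
      paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
      call. = FALSE
    )
  }
  records
}

parse_fasta_id <- function(header) {
  if (grepl("|", header, fixed = TRUE)) {
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    id <- if (length(parts) >= 2L) parts[2L] else parts[1L]
    id <- strsplit(id, "[[:space:]]+")[[1]][1L]
  } else {
    id <- strsplit(header, "[[:space:]]+")[[1]][1L]
  }
  if (is.na(id) || !nzchar(id)) {
    stop("Could not parse a record id from header: '>", header, "'", call. = FALSE)
  }
  id
}

parse_fasta_description <- function(header) {
  desc <- sub("^[^[:space:]]*[[:space:]]*", "", header)
  desc
}

# Applies the nonstandard-residue policy to uppercased sequences.
# Returns list(sequence = cleaned, excluded = logical).
sanitize_sequences <- function(seqs, ids, policy) {
  keep_re <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  bad <- grepl(keep_re, seqs)
  excluded <- rep(FALSE, length(seqs))
  if (any(bad)) {
    if (policy == "reject") {
      i <- which(bad)[1L]
      pos <- regexpr(keep_re, seqs[i])
      stop(
        "Nonstandard residue '", substr(seqs[i], pos, pos), "' at position ",
        as.integer(pos), " in record '", ids[i], "' (policy = reject)",
        call. = FALSE
      )
    } else if (policy == "drop_residue") {
      warning(
        "Dropped nonstandard residues from record(s): ",
        paste(ids[bad], collapse = ", "),
        call. = FALSE
      )
      seqs[bad] <- gsub(keep_re, "", seqs[bad])
      emptied <- !nzchar(seqs)
      if (any(emptied)) {
        stop(
          "Record(s) empty after removing nonstandard residues: ",
          paste(ids[emptied], collapse = ", "),
          call. = FALSE
        )
      }
    } else { # map_to_exclusion
      warning(
        "Excluded record(s) containing nonstandard residues: ",
        paste(ids[bad], collapse = ", "),
        call. = FALSE
      )
      excluded <- bad
    }
  }
  list(sequence = seqs, excluded = excluded)
}

#' Write protein records to a FASTA file
#'
#' Writes the inverse of [read_fasta()]: headers are `>id description` (the
#' description omitted when empty) and sequence lines are wrapped at 60
#' characters, so a write/read round trip reproduces ids and sequences
#' exactly.
#'
#' @param records A tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    stop("Refusing to write an empty record set", call. = FALSE)
  }
  desc <- if ("description" %in% names(records)) records$description else rep("", nrow(records))
  desc[is.na(desc)] <- ""
  headers <- ifelse(nzchar(desc), paste0(">", records$id, " ", desc), paste0(">", records$id))
  chunks <- lapply(seq_len(nrow(records)), function(i) {
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = 60L)
    c(headers[i], substring(s, starts, pmin(starts + 59L, nchar(s))))
  })
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(unlist(chunks), con)
  invisible(path)
}

#' Combine positive and negative records into one labeled dataset
#'
#' Binds a class label to each record: 1 for the positive set (e.g.
#' CML-associated proteins), 0 for the negative set. Records are returned
#' positives first, in input order.
#'
#' @param pos,neg Record tibbles as returned by [read_fasta()]. Either may be
#'   empty (zero rows), but ids must be unique across the two.
#' @return A tibble with columns `id`, `description`, `sequence`, `label`.
#' @export
attach_labels <- function(pos, neg) {
  both <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(pos), label = 1L),
    dplyr::mutate(as_tibble(neg), label = 0L)
  )
  if (nrow(both) == 0L) {
    stop("Both record sets are empty", call. = FALSE)
  }
  dup <- unique(both$id[duplicated(both$id)])
  if (length(dup) > 0L) {
    stop(
      "Record id(s) present in both classes: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  both
}

#' Attach labels from a two-column table
#'
#' Alternative to [attach_labels()] when all sequences live in one FASTA file
#' and the class assignment comes from a TSV with columns `id` and `label`
#' (0/1).
#'
#' @param records A record tibble from [read_fasta()].
#' @param path Path to a tab-separated file with columns `id`, `label`.
#' @return A labeled record tibble.
#' @export
attach_labels_tsv <- function(records, path) {
  lab <- read.delim(path, header = TRUE, sep = "\t", colClasses = c("character", "integer"))
  if (!all(c("id", "label") %in% names(lab))) {
    stop("Label table must have columns 'id' and 'label'", call. = FALSE)
  }
  if (!all(lab$label %in% c(0L, 1L))) {
    stop("Labels must be 0 or 1", call. = FALSE)
  }
  missing <- setdiff(records$id, lab$id)
  if (length(missing) > 0L) {
    stop("No label for record(s): ", paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  records$label <- lab$label[match(records$id, lab$id)]
  records
}
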