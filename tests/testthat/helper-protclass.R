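# Shared fixtures and independent oracles for the test suite.

toy_records <- function(ids, seqs, desc = "") {
  tibble::tibble(id = ids, description = desc, sequence = seqs)
}

random_sequences <- function(n, len_range = c(10L, 60L), seed = 1L) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      L <- if (len_range[1] == len_range[2]) {
        len_range[1]
      } else {
        sample(len_range[1]:len_range[2], 1)
      }
      paste(sample(protclass:::AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# ---- independent encoder oracles -------------------------------------------

# AAC by direct letter counting, no shared code with compute_aac()
oracle_aac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  counts <- vapply(alpha, function(a) sum(chars == a), numeric(1))
  unname(100 * counts / length(chars))
}

# normalized property tables recomputed from the shipped raw TSV by hand
oracle_props <- function() {
  path <- system.file("extdata", "aa_properties.tsv", package = "protclass")
  raw <- read.delim(path, sep = "\t")
  raw <- raw[order(raw$residue), ]
  norm <- function(x) (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
  list(
    residue = raw$residue,
    h1 = norm(raw$hydrophobicity),
    h2 = norm(raw$hydrophilicity),
    m = norm(raw$side_chain_mass)
  )
}

oracle_theta <- function(r1, r2, p = oracle_props()) {
  i <- match(r1, p$residue)
  j <- match(r2, p$residue)
  ((p$h1[j] - p$h1[i])^2 + (p$h2[j] - p$h2[i])^2 + (p$m[j] - p$m[i])^2) / 3
}

# brute-force pseudo amino-acid composition straight from the formula
oracle_pseaac <- function(seq, lambda, w) {
  p <- oracle_props()
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  f <- vapply(p$residue, function(a) sum(chars == a), numeric(1)) / L
  tk <- vapply(seq_len(lambda), function(k) {
    terms <- vapply(seq_len(L - k), function(i) {
      oracle_theta(chars[i], chars[i + k], p)
    }, numeric(1))
    mean(terms)
  }, numeric(1))
  denom <- sum(f) + w * sum(tk)
  unname(c(f / denom, w * tk / denom))
}

# ---- independent greedy clustering oracle ----------------------------------

# applies the greedy definition pair by pair, written separately from
# greedy_cluster(): sort by length desc then id asc, assign to the first
# representative at or above the threshold
oracle_greedy <- function(records, threshold) {
  ord <- order(-nchar(records$sequence), records$id, method = "radix")
  sorted <- records[ord, ]
  reps <- character(0)
  member_of <- character(nrow(sorted))
  names(member_of) <- sorted$id
  for (i in seq_len(nrow(sorted))) {
    placed <- FALSE
    for (r in reps) {
      rep_seq <- sorted$sequence[sorted$id == r]
      if (pairwise_identity(sorted$sequence[i], rep_seq) >= threshold) {
        member_of[sorted$id[i]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, sorted$id[i])
      member_of[sorted$id[i]] <- sorted$id[i]
    }
  }
  member_of
}

# a small strongly-separated feature set, linearly separable on one axis
toy_separable_fm <- function() {
  tbl <- tibble::tibble(
    id = paste0("r", 1:4),
    label = c(1L, 1L, 0L, 0L),
    AAC_A = c(1, 2, -1, -2),
    AAC_C = c(0.5, -0.5, 0.5, -0.5)
  )
  protclass:::new_feature_matrix(tbl, feature_scheme("AAC"))
}
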