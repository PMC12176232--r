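test_that("AAC matches the counting oracle and sums to 100", {
  expect_equal(unname(compute_aac("AAAAA")["AAC_A"]), 100)
  v <- compute_aac("ACDE")
  expect_equal(unname(v[c("AAC_A", "AAC_C", "AAC_D", "AAC_E")]), rep(25, 4))
  expect_equal(sum(v), 100)

  s <- random_sequences(1, c(200L, 200L), seed = 31)
  expect_equal(unname(compute_aac(s)), oracle_aac(s))
  expect_error(compute_aac(""), "empty")
})

test_that("DPC enumerates overlapping windows under both normalizations", {
  d <- compute_dpc("AAA")
  expect_equal(unname(d["DPC_AA"]), 1)
  expect_equal(sum(d), 1)

  d2 <- compute_dpc("ACAC")
  expect_equal(unname(d2["DPC_AC"]), 2 / 3)
  expect_equal(unname(d2["DPC_CA"]), 1 / 3)

  # per400 divides counts by the 400 dipeptide types: sum = (L-1)/400
  s <- random_sequences(1, c(11L, 11L), seed = 32)
  expect_equal(sum(compute_dpc(s, mode = "per400")), 10 / 400)

  expect_error(compute_dpc("A"), "length >= 2")
})

test_that("feature name order is canonical", {
  expect_equal(names(compute_aac("MKV"))[1:3], c("AAC_A", "AAC_C", "AAC_D"))
  d <- names(compute_dpc("MKV"))
  expect_equal(d[1:3], c("DPC_AA", "DPC_AC", "DPC_AD"))
  expect_equal(d[400], "DPC_YY")
})

test_that("property normalization yields mean 0, population sd 1, idempotently", {
  z <- normalize_property(1:20)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(normalize_property(z), z, tolerance = 1e-12)
  expect_error(normalize_property(rep(3, 20)), "equal")

  # shipped hydrophobicity column, residue A recomputed by hand
  props <- load_property_table()
  raw <- read.delim(
    system.file("extdata", "aa_properties.tsv", package = "protclass"),
    sep = "\t"
  )
  h <- raw$hydrophobicity
  expect_equal(
    props$hydrophobicity_norm[props$residue == "A"],
    (h[raw$residue == "A"] - mean(h)) / sqrt(mean((h - mean(h))^2))
  )
})

test_that("theta is symmetric, zero on the diagonal, and matches hand arithmetic", {
  props <- load_property_table()
  expect_equal(theta("A", "A", props), 0)
  expect_equal(theta("A", "C", props), oracle_theta("A", "C"))
  for (pair in list(c("M", "K"), c("W", "G"), c("R", "D"))) {
    expect_equal(
      theta(pair[1], pair[2], props),
      theta(pair[2], pair[1], props)
    )
  }
  expect_error(theta("A", "X", props), "Unknown")
})

test_that("correlation factors vanish on period-matched sequences and match brute force", {
  props <- load_property_table()
  expect_equal(correlation_factor("AAAAAA", 1, props), 0)
  expect_equal(correlation_factor("AAAAAA", 3, props), 0)
  # every residue two apart in ACACAC is identical
  expect_equal(correlation_factor("ACACAC", 2, props), 0)

  s <- "ACDEFG"
  brute <- mean(vapply(1:5, function(i) {
    oracle_theta(substr(s, i, i), substr(s, i + 1, i + 1))
  }, numeric(1)))
  expect_equal(correlation_factor(s, 1, props), brute)

  expect_error(correlation_factor("MKV", 3, props), "k must")
})

test_that("PseAAC has the documented dimension, sums to 1, and matches brute force", {
  s <- random_sequences(1, c(100L, 100L), seed = 33)
  v <- compute_pseaac(s, lambda = 5, w = 0.05)
  expect_length(v, 25)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_equal(unname(v), oracle_pseaac(s, lambda = 5, w = 0.05), tolerance = 1e-12)
})

test_that("PseAAC reduces to AAC fractions at lambda 0 and on homopolymers", {
  s <- random_sequences(1, c(50L, 50L), seed = 34)
  expect_equal(unname(compute_pseaac(s, lambda = 0)), unname(compute_aac(s)) / 100)

  h <- compute_pseaac(strrep("A", 30), lambda = 3)
  expect_equal(unname(h[21:23]), rep(0, 3))
  expect_equal(unname(h[1:20]), unname(compute_aac(strrep("A", 30))) / 100)

  expect_error(compute_pseaac("MKV", lambda = 5), "lambda")
})

test_that("composition sums hold on many random sequences", {
  seqs <- random_sequences(200, c(10L, 80L), seed = 35)
  for (s in seqs) {
    expect_equal(sum(compute_aac(s)), 100, tolerance = 1e-9)
    expect_equal(sum(compute_pseaac(s, lambda = 5)), 1, tolerance = 1e-9)
    expect_equal(sum(compute_dpc(s)), 1, tolerance = 1e-9)
  }
})

test_that("AAC is shuffle-invariant while DPC and PseAAC are order-sensitive", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  shuffled <- withr::with_seed(36, paste(sample(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(compute_aac(s), compute_aac(shuffled))
  expect_false(isTRUE(all.equal(compute_dpc(s), compute_dpc(shuffled))))
  expect_false(isTRUE(all.equal(
    compute_pseaac(s, lambda = 3),
    compute_pseaac(shuffled, lambda = 3)
  )))
})

test_that("featurize_dataset produces labeled matrices of the right shape", {
  ds <- attach_labels(
    toy_records(paste0("p", 1:3), random_sequences(3, c(30L, 40L), seed = 37)),
    toy_records(paste0("n", 1:2), random_sequences(2, c(30L, 40L), seed = 38))
  )
  aac <- featurize_dataset(ds, "AAC")
  expect_equal(dim(aac), c(5L, 22L)) # id + label + 20
  expect_equal(aac$label, ds$label)

  dpc <- featurize_dataset(ds, "DPC")
  expect_length(feature_names(dpc), 400L)

  paac <- featurize_dataset(ds, feature_scheme("PseAAC", lambda = 5))
  expect_length(feature_names(paac), 25L)
  expect_equal(attr(paac, "scheme")$name, "PseAAC")

  short <- attach_labels(
    toy_records("tiny", "MKV"),
    toy_records(paste0("n", 1:2), random_sequences(2, c(30L, 40L), seed = 39))
  )
  expect_error(featurize_dataset(short, feature_scheme("PseAAC", lambda = 5)), "tiny")
})

test_that("feature CSV round trip preserves values and scheme", {
  ds <- attach_labels(
    toy_records(paste0("p", 1:3), random_sequences(3, c(30L, 40L), seed = 40)),
    toy_records(paste0("n", 1:3), random_sequences(3, c(30L, 40L), seed = 41))
  )
  fm <- featurize_dataset(ds, feature_scheme("PseAAC", lambda = 5))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fm, csv)
  back <- read_feature_csv(csv)
  expect_equal(attr(back, "scheme")$lambda, 5L)
  expect_equal(as.data.frame(back), as.data.frame(fm), tolerance = 1e-12)
})
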