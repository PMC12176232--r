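make_fm <- function(values, labels = NULL, scheme = feature_scheme("AAC")) {
  tbl <- tibble::as_tibble(as.data.frame(values))
  names(tbl) <- paste0("F", seq_len(ncol(values)))
  tbl <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("r%03d", seq_len(nrow(values)))),
    if (!is.null(labels)) tibble::tibble(label = as.integer(labels)),
    tbl
  )
  protclass:::new_feature_matrix(tbl, scheme)
}

test_that("IQR outlier mask drops the planted outlier row and only it", {
  vals <- withr::with_seed(50, matrix(rnorm(20 * 10), nrow = 20))
  out_row <- rep(0, 10)
  out_row[1:5] <- 100 # extreme in 50% of features
  vals <- rbind(vals, out_row)
  fm <- make_fm(vals)
  keep <- iqr_outlier_mask(fm, k = 1.5, row_fraction = 0.10)
  expect_false(keep[21])
  expect_true(all(keep[1:20]))

  # constant matrix: IQR = 0, nothing flagged
  const <- make_fm(matrix(3, nrow = 6, ncol = 4))
  expect_true(all(iqr_outlier_mask(const)))

  # unreachable trigger never drops
  expect_true(all(iqr_outlier_mask(fm, row_fraction = 1.0)))

  expect_error(iqr_outlier_mask(make_fm(matrix(1:6, nrow = 3))), "4 rows")
})

test_that("outlier removal is idempotent at fixed thresholds", {
  vals <- withr::with_seed(51, matrix(rnorm(30 * 20), nrow = 30))
  vals[1, 1:10] <- 50
  fm <- make_fm(vals)
  once <- remove_outliers(fm, row_fraction = 0.2, quiet = TRUE)
  twice <- remove_outliers(once, row_fraction = 0.2, quiet = TRUE)
  expect_identical(as.data.frame(twice), as.data.frame(once))
})

test_that("point-biserial scores match the Pearson formula and conventions", {
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  noise <- withr::with_seed(52, rnorm(n, sd = 0.5))
  vals <- cbind(y, y + noise, rep(2, n))
  fm <- make_fm(vals, labels = y)
  sc <- pearson_feature_scores(fm)
  expect_equal(sc$abs_r[1], 1)
  # hand-computed Pearson correlation for the noisy feature
  x <- vals[, 2]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(sc$abs_r[2], abs(r_hand), tolerance = 1e-12)
  # zero-variance convention
  expect_equal(sc$abs_r[3], 0)

  expect_error(pearson_feature_scores(make_fm(vals, labels = rep(1, n))), "Both classes")
})

test_that("feature selection keeps informative features and drops duplicates", {
  n <- 100
  y <- rep(c(1, 0), each = n / 2)
  informative <- withr::with_seed(53, {
    sapply(1:10, function(i) y + rnorm(n, sd = 0.3))
  })
  noise <- withr::with_seed(54, matrix(rnorm(n * 40), nrow = n))
  vals <- cbind(informative, noise)
  fm <- make_fm(vals, labels = y)

  sc <- pearson_feature_scores(fm)
  cut <- min(sc$abs_r[1:10]) - 0.01
  sel <- select_features(fm, min_abs_r = cut, redundancy_r = 1.0)
  kept <- attr(sel, "selection")
  expect_true(all(kept$kept[1:10]))
  # report and matrix columns agree
  expect_setequal(feature_names(sel), kept$feature[kept$kept])
  # brute-force recomputation confirms every kept feature clears the bar
  expect_true(all(kept$abs_r[kept$kept] >= cut))
  expect_true(all(kept$abs_r[!kept$kept] < cut))

  # duplicated column: exactly one survives
  dup_vals <- cbind(vals[, 1], vals[, 1], vals[, 2])
  dup <- make_fm(dup_vals, labels = y)
  sel2 <- select_features(dup, min_abs_r = 0, redundancy_r = 0.95)
  rep2 <- attr(sel2, "selection")
  expect_equal(sum(rep2$kept[1:2]), 1L)
  expect_true(rep2$kept[1]) # tie broken toward the earlier column

  # no-op configuration leaves the matrix unchanged
  noop <- select_features(fm, min_abs_r = 0, redundancy_r = 1.0)
  expect_equal(feature_names(noop), feature_names(fm))

  expect_error(select_features(fm, min_abs_r = 0.999), "every feature")
})

test_that("augmentation replicates class-wise with exact bookkeeping", {
  vals <- withr::with_seed(55, matrix(rnorm(10 * 4), nrow = 10))
  fm <- make_fm(vals, labels = rep(c(1, 0), each = 5))

  expect_identical(augment_dataset(fm, factor = 1), fm)

  a3 <- augment_dataset(fm, factor = 3, eps = 0, seed = 1)
  expect_equal(nrow(a3), 30L)
  # each original row appears 3x verbatim under eps = 0
  first <- as.numeric(a3[a3$id == "r001", feature_names(a3)])
  aug1 <- as.numeric(a3[a3$id == "r001_aug1", feature_names(a3)])
  aug2 <- as.numeric(a3[a3$id == "r001_aug2", feature_names(a3)])
  expect_equal(first, aug1)
  expect_equal(first, aug2)
  # class ratio preserved exactly
  expect_equal(sum(a3$label == 1L), 15L)

  # determinism: same seed twice gives bit-identical output
  b1 <- augment_dataset(fm, factor = 2, eps = 0.01, seed = 7)
  b2 <- augment_dataset(fm, factor = 2, eps = 0.01, seed = 7)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  # and jitter actually perturbs
  expect_false(isTRUE(all.equal(
    as.numeric(b1[11, feature_names(b1)]),
    as.numeric(b1[1, feature_names(b1)])
  )))

  expect_error(augment_dataset(fm, factor = 0), "factor")
})

test_that("stratified split is exact, disjoint, exhaustive and seeded", {
  vals <- withr::with_seed(56, matrix(rnorm(100 * 3), nrow = 100))
  fm <- make_fm(vals, labels = rep(c(1, 0), each = 50))
  sp <- stratified_split(fm, test_fraction = 0.25, seed = 3)
  # floor(50 * 0.25) = 12 per class; the remainder goes to train
  expect_equal(nrow(sp$train), 76L)
  expect_equal(nrow(sp$test), 24L)
  expect_equal(sum(sp$test$label == 1L), 12L)
  expect_equal(sum(sp$test$label == 0L), 12L)

  sp2 <- stratified_split(fm, test_fraction = 0.25, seed = 3)
  expect_identical(sp2$test$id, sp$test$id)

  for (seed in 1:10) {
    s <- stratified_split(fm, test_fraction = 0.3, seed = seed)
    expect_setequal(c(s$train$id, s$test$id), fm$id)
    expect_length(intersect(s$train$id, s$test$id), 0)
  }

  one_class <- make_fm(vals[1:4, , drop = FALSE], labels = c(1, 1, 1, 0))
  expect_error(stratified_split(one_class), "at least 2")
})
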