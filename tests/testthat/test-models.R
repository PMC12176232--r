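test_that("the registry returns the documented default configurations", {
  svc <- default_config("svc", feature_scheme("PseAAC"))
  expect_equal(svc$hyperparameters$cost, 10000)
  expect_equal(svc$hyperparameters$gamma, 100000)
  expect_equal(svc$hyperparameters$kernel, "radial")
  expect_true(svc$hyperparameters$probability)

  expect_equal(default_config("rf", feature_scheme("DPC"))$hyperparameters$n_estimators, 150L)
  expect_equal(default_config("rf", feature_scheme("AAC"))$hyperparameters$n_estimators, 50L)
  expect_equal(default_config("rf")$hyperparameters$n_estimators, 50L)

  lr <- default_config("lr")
  expect_equal(lr$hyperparameters$C, 10)
  expect_equal(lr$hyperparameters$tol, 0.1)
  expect_equal(lr$hyperparameters$penalty, "L2")

  knn <- default_config("knn")
  expect_equal(knn$hyperparameters$k, 5L)
  expect_equal(knn$hyperparameters$metric, "euclidean")

  expect_error(default_config("mlp"), "svc, rf, knn")
})

test_that("separable toy data is fit perfectly by svc and 1-NN", {
  fm <- toy_separable_fm()
  svc_cfg <- default_config("svc", seed = 1)
  svc_cfg$hyperparameters$gamma <- "scale"
  m <- train(fm, svc_cfg)
  expect_equal(predict(m, fm)$label, fm$label)

  knn_cfg <- default_config("knn", seed = 1)
  knn_cfg$hyperparameters$k <- 1L
  m1 <- train(fm, knn_cfg)
  pred <- predict(m1, fm)
  expect_equal(pred$label, fm$label)
  expect_true(all(pred$probability %in% c(0, 1)))
})

test_that("training rejects degenerate input", {
  fm <- toy_separable_fm()
  single <- fm
  single$label <- 1L
  expect_error(train(single, "svc"), "both classes")

  m <- train(fm, "rf")
  bad <- fm
  names(bad)[names(bad) == "AAC_A"] <- "AAC_G"
  expect_error(predict(m, bad), "AAC_A")
})

test_that("every registry algorithm learns the planted signal and stays at chance on shuffled labels", {
  ds <- generate_dataset(200, 200, delta = 2, seed = 42)
  fm <- featurize_dataset(ds, "AAC")
  shuffled <- generate_dataset(200, 200, delta = 0, seed = 42)
  fm0 <- featurize_dataset(shuffled, "AAC")
  fm0$label <- withr::with_seed(42, sample(fm0$label))
  # chance behaviour is judged on 400 fresh null points, where the
  # [40, 60] band is a four-sigma bound
  eval0 <- featurize_dataset(generate_dataset(200, 200, delta = 0, seed = 43), "AAC")

  for (algo in c("svc", "rf", "knn", "nb", "xgb", "lr", "dt")) {
    cfg <- default_config(algo, "AAC", seed = 1)
    if (algo == "svc") cfg$hyperparameters$gamma <- "scale"
    run <- train_pipeline(fm, cfg, pipeline_config(seed = 1))
    expect_gt(run$metrics$accuracy, 80) # far above the 50% chance line

    run0 <- train_pipeline(fm0, cfg, pipeline_config(seed = 1))
    acc0 <- evaluate_model(run0$model, eval0)$accuracy
    expect_gte(acc0, 40)
    expect_lte(acc0, 60)
  }
})

test_that("training and prediction are deterministic given the seed", {
  ds <- generate_dataset(60, 60, delta = 1, seed = 11)
  fm <- featurize_dataset(ds, "AAC")
  sp <- stratified_split(fm, 0.25, seed = 2)
  for (algo in c("svc", "rf", "xgb", "knn")) {
    m1 <- train(sp$train, default_config(algo, "AAC", seed = 5))
    m2 <- train(sp$train, default_config(algo, "AAC", seed = 5))
    expect_identical(predict(m1, sp$test), predict(m2, sp$test))
  }
})

test_that("predict_fasta reproduces training-time predictions and isolates bad records", {
  ds <- generate_dataset(30, 30, delta = 2, seed = 13)
  scheme <- feature_scheme("PseAAC", lambda = 5)
  fm <- featurize_dataset(ds, scheme)
  cfg <- default_config("rf", scheme, seed = 3)
  m <- train(fm, cfg)

  direct <- predict(m, fm)
  via_fasta <- predict_fasta(m, ds)
  expect_equal(via_fasta$label, direct$label)
  expect_equal(via_fasta$probability, direct$probability)
  expect_true(all(is.na(via_fasta$error)))

  # a 4-residue query cannot support lambda = 5: error entry, run continues
  mixed <- dplyr::bind_rows(
    toy_records("shorty", "MKVL"),
    ds[1, c("id", "description", "sequence")]
  )
  out <- predict_fasta(m, mixed)
  expect_equal(nrow(out), 2L)
  expect_match(out$error[1], "lambda")
  expect_true(is.na(out$error[2]))

  empty <- predict_fasta(m, ds[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("model archives round-trip predictions and provenance", {
  fm <- toy_separable_fm()
  m <- train(fm, default_config("rf", "AAC", seed = 9))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict(back, fm), predict(m, fm))
  expect_identical(back$provenance, m$provenance)

  # truncated archive is refused
  raw <- readBin(path, "raw", n = file.size(path))
  trunc <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[1:20], trunc)
  expect_error(load_model(trunc), "archive")

  # wrong format version is refused
  bogus <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format_version = 99L), bogus)
  expect_error(load_model(bogus), "version 99")
})

test_that("tidy and glance summarize models and runs", {
  fm <- toy_separable_fm()
  m <- train(fm, default_config("rf", "AAC", seed = 1))
  td <- tidy(m)
  expect_true(all(c("algo", "scheme", "n_train") %in% td$term))
  gl <- glance(m)
  expect_equal(gl$algo, "rf")
  expect_equal(gl$n_train, 4L)
})
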