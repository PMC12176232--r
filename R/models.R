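MODEL_ALGOS <- c("svc", "rf", "knn", "nb", "xgb", "lr", "dt")

#' Default classifier configurations
#'
#' Returns the registry entry for one of the seven supported classifier
#' families, pre-filled with the hyperparameters the benchmark CML study
#' prints where it prints them, and with pinned library defaults elsewhere:
#'
#' * `svc` — RBF-kernel support vector classifier, `cost = 10000`,
#'   `gamma = 100000`, `degree = 8` (recorded but inert under the RBF
#'   kernel), probability estimates on. `gamma = "scale"` is also accepted
#'   and resolves to 1/d at training time — the conventional kernel width
#'   for features on their natural compositional scale.
#' * `rf` — random forest, 150 trees for DPC features, 50 otherwise.
#' * `knn` — k-nearest neighbours, `k = 5`, Euclidean distance.
#' * `nb` — Gaussian naive Bayes with equal class priors.
#' * `xgb` — gradient-boosted trees, pinned defaults
#'   (`nrounds = 100`, `eta = 0.3`, `max_depth = 6`).
#' * `lr` — L2-penalized logistic regression, `C = 10`, `tol = 0.1`.
#' * `dt` — CART decision tree, pinned `rpart` defaults.
#'
#' @param algo One of `"svc"`, `"rf"`, `"knn"`, `"nb"`, `"xgb"`, `"lr"`,
#'   `"dt"`.
#' @param scheme Optional [feature_scheme()] (or name); only consulted for
#'   the random-forest tree count.
#' @param seed Integer seed stored in the config.
#' @return A list of class `"protclass_config"` with fields `algo`,
#'   `hyperparameters`, `seed`.
#' @export
default_config <- function(algo, scheme = NULL, seed = 1L) {
  algo <- as.character(algo)
  if (!algo %in% MODEL_ALGOS) {
    stop(
      "Unknown algorithm '", algo, "'; expected one of: ",
      paste(MODEL_ALGOS, collapse = ", "),
      call. = FALSE
    )
  }
  scheme_name <- if (is.null(scheme)) {
    NA_character_
  } else if (inherits(scheme, "protclass_scheme")) {
    scheme$name
  } else {
    feature_scheme(scheme)$name
  }
  hp <- switch(algo,
    svc = list(
      kernel = "radial", cost = 10000, gamma = 100000, degree = 8,
      probability = TRUE
    ),
    rf = list(n_estimators = if (identical(scheme_name, "DPC")) 150L else 50L),
    knn = list(k = 5L, metric = "euclidean"),
    nb = list(distribution = "gaussian", equal_priors = TRUE),
    xgb = list(
      nrounds = 100L, eta = 0.3, max_depth = 6L,
      objective = "binary:logistic", nthread = 1L
    ),
    lr = list(C = 10, tol = 0.1, penalty = "L2"),
    dt = list(minsplit = 20L, cp = 0.01, maxdepth = 30L)
  )
  structure(
    list(algo = algo, hyperparameters = hp, seed = as.integer(seed)),
    class = "protclass_config"
  )
}

#' @export
print.protclass_config <- function(x, ...) {
  cat("<classifier config> ", x$algo, " (seed ", x$seed, ")\n", sep = "")
  hp <- x$hyperparameters
  cat(paste0("  ", names(hp), " = ", vapply(hp, format, character(1)), collapse = "\n"), "\n")
  invisible(x)
}

MODEL_FORMAT_VERSION <- 1L

#' Train a classifier on a labeled feature matrix
#'
#' Fits the configured classifier family (delegating to the standard
#' implementations: \pkg{e1071}, \pkg{randomForest}, \pkg{class},
#' \pkg{xgboost}, \pkg{glmnet}, \pkg{rpart}) and wraps the fit with the full
#' provenance needed to featurize and predict on new FASTA input: feature
#' scheme and parameters, selected feature names, seed and format version.
#' Training is deterministic given the config seed.
#'
#' @param fm Labeled feature tibble with both classes present.
#' @param cfg A [default_config()] result (or an algo name, which is
#'   expanded with defaults for the matrix's scheme).
#' @return An object of class `"protclass_model"`.
#' @export
train <- function(fm, cfg) {
  stopifnot(is.data.frame(fm), "label" %in% names(fm))
  if (is.character(cfg)) cfg <- default_config(cfg, scheme = fm_scheme(fm))
  stopifnot(inherits(cfg, "protclass_config"))
  y <- as.integer(fm$label)
  if (length(unique(y)) < 2L) {
    stop("Training data must contain both classes", call. = FALSE)
  }
  x <- feature_values(fm)
  if (!all(is.finite(x))) stop("Training matrix has non-finite values", call. = FALSE)
  hp <- cfg$hyperparameters
  fit <- withr::with_seed(cfg$seed, fit_algo(cfg$algo, x, y, hp))
  structure(
    list(
      config = cfg,
      fit = fit,
      provenance = list(
        scheme = fm_scheme(fm),
        features = colnames(x),
        n_train = nrow(x),
        seed = cfg$seed,
        format_version = MODEL_FORMAT_VERSION,
        package_version = as.character(utils::packageVersion("protclass"))
      )
    ),
    class = "protclass_model"
  )
}

fit_algo <- function(algo, x, y, hp) {
  yf <- factor(y, levels = c(0L, 1L))
  switch(algo,
    svc = {
      gamma <- hp$gamma
      if (identical(gamma, "scale")) {
        # kernel width adapted to the data scale: 1 / (d * Var(X)),
        # with Var taken over all matrix entries
        gamma <- 1 / (ncol(x) * stats::var(as.vector(x)))
      }
      e1071::svm(
        x, yf,
        kernel = hp$kernel, cost = hp$cost, gamma = gamma,
        degree = hp$degree, probability = isTRUE(hp$probability), scale = FALSE
      )
    },
    rf = randomForest::randomForest(x, yf, ntree = hp$n_estimators),
    knn = list(x = x, y = yf, k = hp$k), # lazy learner: memorize
    nb = e1071::naiveBayes(x, yf, laplace = 0),
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = hp$nthread)
      xgboost::xgb.train(
        params = list(
          objective = hp$objective, eta = hp$eta, max_depth = hp$max_depth,
          nthread = hp$nthread
        ),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      )
    },
    lr = {
      # glmnet ridge; sklearn-style C maps to lambda = 1 / (C * n)
      glmnet::glmnet(
        x, yf,
        family = "binomial", alpha = 0,
        lambda = 1 / (hp$C * nrow(x)), thresh = hp$tol * 1e-4,
        standardize = FALSE
      )
    },
    dt = {
      df <- data.frame(.y = yf, x, check.names = FALSE)
      rpart::rpart(
        .y ~ ., df,
        method = "class",
        control = rpart::rpart.control(
          minsplit = hp$minsplit, cp = hp$cp, maxdepth = hp$maxdepth
        )
      )
    }
  )
}

#' Predict labels and class-1 probabilities
#'
#' @param object A `"protclass_model"`.
#' @param fm Feature tibble whose columns match the model's provenance
#'   (extra columns are ignored; missing ones are an error).
#' @param ... Unused.
#' @return A tibble with columns `id`, `label` (0/1; 1 iff probability >=
#'   0.5, ties to 1) and `probability` (class 1).
#' @export
predict.protclass_model <- function(object, fm, ...) {
  stopifnot(is.data.frame(fm))
  want <- object$provenance$features
  missing <- setdiff(want, names(fm))
  if (length(missing) > 0L) {
    stop(
      "Feature matrix does not match model provenance; missing column(s): ",
      paste(head(missing, 5L), collapse = ", "),
      " (expected ", length(want), " features of scheme ",
      object$provenance$scheme$name, ")",
      call. = FALSE
    )
  }
  if (nrow(fm) == 0L) {
    return(tibble(id = character(0), label = integer(0), probability = numeric(0)))
  }
  x <- feature_values(fm, want)
  prob <- predict_prob(object, x)
  tibble(
    id = fm$id,
    label = as.integer(prob >= 0.5),
    probability = as.numeric(prob)
  )
}

predict_prob <- function(model, x) {
  fit <- model$fit
  switch(model$config$algo,
    svc = {
      pr <- predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rf = predict(fit, x, type = "prob")[, "1"],
    knn = {
      # class::knn breaks exact-distance ties randomly; pin the RNG so
      # prediction is a pure function of (model, input)
      pr <- withr::with_seed(
        model$provenance$seed,
        class::knn(fit$x, x, fit$y, k = fit$k, prob = TRUE)
      )
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    nb = predict(fit, x, type = "raw")[, "1"],
    xgb = predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L)),
    lr = as.numeric(predict(fit, x, type = "response")),
    dt = predict(fit, as.data.frame(x, check.names = FALSE), type = "prob")[, "1"]
  )
}

#' Predict directly from protein records
#'
#' Featurizes `records` with the model's archived scheme and parameters,
#' restricts to the archived selected features, and predicts. A record that
#' cannot be featurized (e.g. shorter than the archived PseAAC lambda) gets
#' an error entry instead of aborting the run.
#'
#' @param model A `"protclass_model"`.
#' @param records A record tibble (e.g. from [read_fasta()]); may be empty.
#' @return A tibble with columns `id`, `label`, `probability`, `error`
#'   (`NA` for clean rows).
#' @export
predict_fasta <- function(model, records) {
  stopifnot(inherits(model, "protclass_model"), is.data.frame(records))
  empty <- tibble(
    id = character(0), label = integer(0),
    probability = numeric(0), error = character(0)
  )
  if (nrow(records) == 0L) {
    return(empty)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    res <- tryCatch(
      {
        fm <- featurize_dataset(rec, model$provenance$scheme)
        pred <- predict(model, fm)
        tibble(
          id = pred$id, label = pred$label,
          probability = pred$probability, error = NA_character_
        )
      },
      error = function(e) {
        tibble(
          id = rec$id, label = NA_integer_,
          probability = NA_real_, error = conditionMessage(e)
        )
      }
    )
    res
  })
  dplyr::bind_rows(rows)
}

#' Save or load a trained model archive
#'
#' The archive is a single RDS container holding a format-version field,
#' the provenance metadata and the fitted payload. `load_model()` refuses
#' archives with a missing or mismatched format version rather than
#' guessing.
#'
#' @param model A `"protclass_model"`.
#' @param path Archive path.
#' @return `save_model`: `path`, invisibly. `load_model`: the restored
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "protclass_model"))
  archive <- list(
    format_version = MODEL_FORMAT_VERSION,
    metadata = model$provenance,
    config = model$config,
    payload = model$fit
  )
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  archive <- tryCatch(readRDS(path), error = function(e) {
    stop("Cannot read model archive '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(archive) || is.null(archive$format_version)) {
    stop("Not a protclass model archive: ", path, call. = FALSE)
  }
  if (!identical(as.integer(archive$format_version), MODEL_FORMAT_VERSION)) {
    stop(
      "Model archive format version ", archive$format_version,
      " is not supported (expected ", MODEL_FORMAT_VERSION, ")",
      call. = FALSE
    )
  }
  structure(
    list(config = archive$config, fit = archive$payload, metadata_checked = TRUE,
         provenance = archive$metadata),
    class = "protclass_model"
  )
}

#' @export
print.protclass_model <- function(x, ...) {
  p <- x$provenance
  cat(
    "<protclass model> ", x$config$algo, " on ", p$scheme$name,
    " (", length(p$features), " features, ", p$n_train, " training rows, seed ",
    p$seed, ")\n",
    sep = ""
  )
  invisible(x)
}
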