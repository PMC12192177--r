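# Train/test splitting, the six shallow classifier families, and the final
# radial-kernel SVM; plus a whole-pipeline convenience wrapper and model
# bundle persistence.

ALGORITHMS <- c("svm", "gbdt", "lr", "rf", "knn", "gnb")

#' Tuned hyperparameters of the final radial-kernel SVM
#'
#' The cost and kernel-width constants of the deployed model.
#'
#' @return Named list with `kernel`, `C`, `gamma`.
#' @export
final_svm_params <- function() {
  list(kernel = "rbf", C = 2.782559402207126, gamma = 0.005994842503189409)
}

#' Stratified train/test split
#'
#' Splits a labeled peptide set (or any data frame with a `label` column)
#' into disjoint, exhaustive train and test subsets. With stratification,
#' each class contributes `floor(n_class * (1 - train_fraction))` records
#' to the test set; the split is a deterministic function of the seed.
#'
#' @param data A labeled `peptide_set` (or data frame with `label`).
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.8, stratified = TRUE,
                          seed = 1L) {
  if (is.null(data$label)) stop("split_dataset needs a 'label' column")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (any(table(data$label) < 2L)) stop("each class needs at least 2 samples")
  n <- nrow(data)
  test_idx <- withr::with_seed(seed, {
    if (stratified) {
      unlist(lapply(split(seq_len(n), data$label), function(idx) {
        # guard the floor against binary representation of the fraction
        sample(idx, floor(length(idx) * (1 - train_fraction) + 1e-9))
      }), use.names = FALSE)
    } else {
      sample(seq_len(n), floor(n * (1 - train_fraction) + 1e-9))
    }
  })
  list(train = data[-sort(test_idx), , drop = FALSE],
       test = data[sort(test_idx), , drop = FALSE])
}

check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  bad <- which(apply(x, 2, function(col) any(!is.finite(col))))
  if (length(bad) > 0L) {
    stop("non-finite values in feature column(s): ",
         paste(colnames(x)[utils::head(bad, 5)], collapse = ", "))
  }
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("labels and feature rows differ in length")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  list(x = x, y = y)
}

#' Train a binary peptide classifier
#'
#' Fits one of the six supported algorithm families on an encoded feature
#' matrix. Algorithms: `"svm"` (radial-kernel support vector machine, the
#' final model family; defaults to [final_svm_params()]), `"gbdt"`
#' (gradient-boosted decision trees), `"lr"` (ridge-regularized logistic
#' regression), `"rf"` (random forest), `"knn"` (k-nearest neighbours,
#' k = 5), and `"gnb"` (Gaussian naive Bayes). Stochastic learners are
#' seeded, so refitting with the same data and seed reproduces the model.
#'
#' Features are used as encoded (all encoders emit bounded values);
#' `standardize = TRUE` optionally z-scores columns using training
#' statistics that are then reapplied at prediction time.
#'
#' @param x Numeric feature matrix with labeled columns.
#' @param y Binary 0/1 labels.
#' @param algorithm One of `r paste0('"', ALGORITHMS, '"', collapse = ", ")`.
#' @param hyperparameters Named list overriding the per-algorithm defaults
#'   (`C`/`gamma` for svm, `nrounds` for gbdt, `lambda` for lr, `ntree`
#'   for rf, `k` for knn).
#' @param seed Integer seed for stochastic learners.
#' @param standardize Z-score features with training statistics.
#' @return An object of class `aop_model`.
#' @export
train_classifier <- function(x, y, algorithm = "svm",
                             hyperparameters = list(), seed = 1L,
                             standardize = FALSE) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  xy <- check_xy(x, y)
  x <- xy$x; y <- xy$y
  scaling <- NULL
  if (standardize) {
    mu <- colMeans(x)
    sdev <- apply(x, 2, stats::sd)
    sdev[sdev == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdev, "/")
    scaling <- list(mean = mu, sd = sdev)
  }
  yf <- factor(y, levels = c(0L, 1L))
  hp <- hyperparameters
  fit <- withr::with_seed(as.integer(seed), switch(
    algorithm,
    svm = {
      hp <- utils::modifyList(final_svm_params(), hp)
      e1071::svm(x = x, y = yf, kernel = "radial", cost = hp$C,
                 gamma = if (is.null(hp$gamma)) 1 / ncol(x) else hp$gamma,
                 scale = FALSE)
    },
    gbdt = {
      nrounds <- if (is.null(hp$nrounds)) 100L else as.integer(hp$nrounds)
      params <- list(objective = "binary:logistic", nthread = 1L,
                     seed = as.integer(seed))
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(x, label = y),
                         nrounds = nrounds, verbose = 0)
    },
    lr = {
      lambda <- if (is.null(hp$lambda)) 0.01 else hp$lambda
      glmnet::glmnet(x, yf, family = "binomial", alpha = 0, lambda = lambda)
    },
    rf = {
      ntree <- if (is.null(hp$ntree)) 500L else as.integer(hp$ntree)
      randomForest::randomForest(x = x, y = yf, ntree = ntree)
    },
    knn = {
      k <- if (is.null(hp$k)) 5L else as.integer(hp$k)
      # lazy learner: the "fit" is the training data itself
      list(x = x, y = yf, k = k)
    },
    gnb = {
      # columns with zero variance within a class break the Gaussian
      # likelihood; they are excluded from this learner
      keep <- which(vapply(seq_len(ncol(x)), function(j) {
        all(tapply(x[, j], yf, stats::sd) > 0)
      }, logical(1)))
      if (length(keep) == 0L) stop("no feature has positive within-class variance")
      list(fit = e1071::naiveBayes(x = x[, keep, drop = FALSE], y = yf),
           keep = keep)
    }))
  structure(list(algorithm = algorithm, hyperparameters = hp, fit = fit,
                 feature_labels = colnames(x), scaling = scaling,
                 training_seed = as.integer(seed)),
            class = "aop_model")
}

#' @exportS3Method base::print
print.aop_model <- function(x, ...) {
  cat(sprintf("aop_model: %s on %d features (seed %d)\n", x$algorithm,
              length(x$feature_labels), x$training_seed))
  invisible(x)
}

#' Predict labels and confidence scores
#'
#' @param object A fitted `aop_model`.
#' @param newdata Feature matrix (or single `feature_block`) with the same
#'   feature layout the model was trained on.
#' @param ... Unused.
#' @return Data frame with columns `id`, `label` (0/1), `score` (real-valued
#'   confidence, monotone in the predicted probability of class 1; usable
#'   for ranking and AUC). `label` is 1 exactly when `score` exceeds the
#'   algorithm's decision threshold (0 for svm margins, 0.5 for
#'   probabilities).
#' @export
predict.aop_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1,
                                             dimnames = list(NULL, names(newdata)))
  if (ncol(newdata) != length(object$feature_labels)) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 length(object$feature_labels), ncol(newdata)))
  }
  if (!is.null(object$scaling)) {
    newdata <- sweep(sweep(newdata, 2, object$scaling$mean), 2,
                     object$scaling$sd, "/")
  }
  res <- switch(
    object$algorithm,
    svm = {
      pr <- stats::predict(object$fit, newdata, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients the margin toward the first factor level of the pair
      score <- if (colnames(dv)[1] == "1/0") dv[, 1] else -dv[, 1]
      list(label = as.integer(score > 0), score = as.numeric(score))
    },
    gbdt = {
      p <- stats::predict(object$fit, xgboost::xgb.DMatrix(newdata))
      list(label = as.integer(p > 0.5), score = as.numeric(p))
    },
    lr = {
      p <- as.numeric(stats::predict(object$fit, newdata, type = "response"))
      list(label = as.integer(p > 0.5), score = p)
    },
    rf = {
      p <- stats::predict(object$fit, newdata, type = "prob")[, "1"]
      list(label = as.integer(p > 0.5), score = as.numeric(p))
    },
    knn = {
      pr <- class::knn(object$fit$x, newdata, object$fit$y, k = object$fit$k,
                       prob = TRUE)
      win <- attr(pr, "prob")
      p <- ifelse(pr == "1", win, 1 - win)
      list(label = as.integer(p > 0.5), score = as.numeric(p))
    },
    gnb = {
      sub <- newdata[, object$fit$keep, drop = FALSE]
      p <- stats::predict(object$fit$fit, sub, type = "raw")[, "1"]
      list(label = as.integer(p > 0.5), score = as.numeric(p))
    })
  data.frame(id = rownames(newdata) %||% seq_len(nrow(newdata)),
             label = res$label, score = res$score,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the full encode/rank/select/classify pipeline
#'
#' Convenience wrapper producing a deployable model bundle from a labeled
#' peptide set: encodes the requested descriptor fusion, optionally ranks
#' features by gradient-boosted split counts and keeps the top k, then
#' trains the classifier.
#'
#' @param peptides Labeled `peptide_set`.
#' @param members Encoder fusion (default the ctd + blosum62 combination
#'   used by the final model).
#' @param algorithm,hyperparameters Classifier family and settings.
#' @param top_k Number of ranked features to keep; `NULL` disables
#'   selection and uses the full fusion.
#' @param resources Resource bundle from [load_resources()].
#' @param seed Integer seed (ranking and training).
#' @return An object of class `aop_pipeline` carrying the encoder spec,
#'   the feature ranking (if any) and the fitted model; its
#'   [predict.aop_pipeline()] method consumes raw peptide sets.
#' @export
aop_fit <- function(peptides, members = c("ctd", "blosum62"),
                    algorithm = "svm", hyperparameters = list(),
                    top_k = NULL, resources = load_resources(), seed = 1L) {
  members <- canonical_spec(members)
  x <- encode_peptides(peptides, members, resources)
  ranking <- NULL
  if (!is.null(top_k)) {
    ranking <- rank_features(x, peptides$label, seed = seed)
    x <- apply_selection(x, ranking, top_k)
  }
  model <- train_classifier(x, peptides$label, algorithm = algorithm,
                            hyperparameters = hyperparameters, seed = seed)
  structure(list(members = members, ranking = ranking, top_k = top_k,
                 model = model, seed = as.integer(seed),
                 resource_hashes = resource_hashes()),
            class = "aop_pipeline")
}

#' @rdname aop_fit
#' @param object A fitted `aop_pipeline`.
#' @param newdata A `peptide_set` (unlabeled is fine).
#' @param ... Unused.
#' @export
predict.aop_pipeline <- function(object, newdata, ...) {
  x <- encode_peptides(newdata, object$members)
  if (!is.null(object$top_k)) x <- apply_selection(x, object$ranking, object$top_k)
  predict(object$model, x)
}

#' Persist / restore a model bundle
#'
#' Writes the pipeline to a directory: human-readable `metadata.json`
#' (algorithm, hyperparameters, encoder set, selected feature labels,
#' seeds, resource checksums) plus the opaque fitted state.
#'
#' @param pipeline An `aop_pipeline` from [aop_fit()].
#' @param dir Target directory (created if missing).
#' @return `dir` (for `save_model`); the restored `aop_pipeline` (for
#'   `load_model`).
#' @export
save_model <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    package = "antioxpep",
    algorithm = pipeline$model$algorithm,
    hyperparameters = pipeline$model$hyperparameters,
    feature_spec = pipeline$members,
    top_k = pipeline$top_k,
    selected_features = if (is.null(pipeline$top_k)) NULL else
      utils::head(pipeline$ranking$labels, pipeline$top_k),
    seed = pipeline$seed,
    resource_hashes = as.list(pipeline$resource_hashes))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(pipeline, file.path(dir, "state.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  state <- file.path(dir, "state.rds")
  if (!file.exists(state)) stop("not a model bundle: ", dir)
  pipeline <- readRDS(state)
  current <- resource_hashes()
  stored <- pipeline$resource_hashes
  if (!identical(unname(current[names(stored)]), unname(unlist(stored)))) {
    stop("resource version mismatch: bundled lookup tables differ from ",
         "those the model was trained with")
  }
  pipeline
}
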