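# Split-count feature ranking with a gradient-boosted tree ensemble, and
# nested top-k subset sweeps for picking a compact feature set.

#' Rank features by gradient-boosted split counts
#'
#' Trains a gradient-boosted decision-tree ensemble on the encoded training
#' data and scores every feature by its split importance: the number of
#' internal tree nodes, summed over all trees, that split on that feature.
#' Features are returned in descending split-count order; ties are broken
#' by original feature index, so the ranking is a deterministic function of
#' the data and the seed. Features never used as a split variable (e.g.
#' constant columns) receive importance 0 and rank last.
#'
#' @param x Numeric feature matrix (rows = samples, labeled columns).
#' @param y Binary labels (0/1), one per row of `x`.
#' @param seed Integer seed controlling the ensemble's randomness.
#' @param ntrees Number of boosting rounds (trees). Default 100.
#' @param params Named list of additional booster parameters, merged over
#'   the defaults (binary logistic objective, single thread).
#' @return An object of class `feature_ranking`: list with `order`
#'   (permutation of column indices, most important first), `importance`
#'   (integer split counts in `order`), `labels` (column names in `order`),
#'   and `trainer_seed`.
#' @export
rank_features <- function(x, y, seed = 1L, ntrees = 100L, params = list()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("feature ranking needs both classes present")
  if (any(!is.finite(x))) stop("feature matrix must be finite")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- utils::modifyList(
    list(objective = "binary:logistic", nthread = 1L, seed = as.integer(seed)),
    params)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(params = p, data = dtrain,
                                nrounds = as.integer(ntrees), verbose = 0)
  tree_tab <- xgboost::xgb.model.dt.tree(model = booster)
  splits <- tree_tab$Feature[tree_tab$Feature != "Leaf"]
  counts <- integer(ncol(x))
  names(counts) <- colnames(x)
  tab <- table(splits)
  counts[names(tab)] <- as.integer(tab)
  ord <- order(-counts, seq_along(counts))
  structure(list(order = ord, importance = unname(counts[ord]),
                 labels = colnames(x)[ord], trainer_seed = as.integer(seed),
                 n_features = ncol(x)),
            class = "feature_ranking")
}

#' @exportS3Method base::print
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking over %d features (seed %d)\n", x$n_features,
              x$trainer_seed))
  cat("top:", paste(utils::head(x$labels, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Keep the top-k ranked features of a feature matrix or block
#'
#' @param block A `feature_block` vector or a feature matrix.
#' @param ranking A `feature_ranking` over the same feature layout.
#' @param k Number of features to keep (1 <= k <= total features).
#' @return The sub-vector/sub-matrix of the top-k features in ranking
#'   order, labels preserved. Top-k sets are nested: selecting k then
#'   k' < k equals selecting k' directly.
#' @export
apply_selection <- function(block, ranking, k) {
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  total <- if (is.matrix(block)) ncol(block) else length(block)
  if (k > total) stop("k exceeds the number of features (", total, ")")
  if (total != ranking$n_features) {
    stop("ranking covers ", ranking$n_features, " features but input has ", total)
  }
  idx <- ranking$order[seq_len(k)]
  if (is.matrix(block)) block[, idx, drop = FALSE] else {
    out <- block[idx]
    attr(out, "encoder") <- attr(block, "encoder")
    out
  }
}

#' Sweep nested top-k feature subsets
#'
#' For each k in the grid, trains the classifier on the top-k ranked
#' features and scores it; the selected `best_k` maximizes accuracy, with
#' the Matthews correlation coefficient as first tie-break and the smaller
#' k (parsimony) as final tie-break. Two scoring protocols are available:
#'
#' * `mode = "cv"` (default): stratified 5-fold cross-validation on the
#'   training set, so selection never sees the held-out test data.
#' * `mode = "holdout"`: each top-k model is trained on the full training
#'   set and scored on the supplied evaluation set (the protocol used when
#'   sweeping directly against an independent test set).
#'
#' @param x,y Training feature matrix and 0/1 labels.
#' @param ranking A `feature_ranking` over the columns of `x`.
#' @param grid Strictly increasing vector of candidate k values, each at
#'   most `ncol(x)`. The conventional grid is `seq(5, 300, by = 5)`.
#' @param mode Scoring protocol (see above).
#' @param x_eval,y_eval Evaluation set, required for `mode = "holdout"`.
#' @param algorithm,hyperparameters Classifier to fit at each k; defaults
#'   to the radial-kernel SVM with the package's tuned constants.
#' @param folds Cross-validation folds for `mode = "cv"`.
#' @param seed Seed for fold assignment and stochastic learners.
#' @return An object of class `sweep_result`: list with `grid`,
#'   `per_k` (data frame of metrics per k), `best_k`, `mode`, and
#'   `selection_rule`.
#' @export
sweep_topk <- function(x, y, ranking, grid = seq(5L, 300L, by = 5L),
                       mode = c("cv", "holdout"), x_eval = NULL, y_eval = NULL,
                       algorithm = "svm", hyperparameters = final_svm_params(),
                       folds = 5L, seed = 1L) {
  mode <- match.arg(mode)
  grid <- as.integer(grid)
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (max(grid) > ncol(x)) {
    stop("grid value ", max(grid), " exceeds the feature count ", ncol(x))
  }
  if (mode == "holdout" && (is.null(x_eval) || is.null(y_eval))) {
    stop("mode = 'holdout' needs x_eval and y_eval")
  }
  rows <- lapply(grid, function(k) {
    xk <- apply_selection(x, ranking, k)
    rep <- if (mode == "cv") {
      cross_validate(xk, y, algorithm = algorithm,
                     hyperparameters = hyperparameters,
                     folds = folds, seed = seed)$mean
    } else {
      model <- train_classifier(xk, y, algorithm = algorithm,
                                hyperparameters = hyperparameters, seed = seed)
      pred <- predict(model, apply_selection(x_eval, ranking, k))
      evaluate_predictions(pred$label, y_eval, pred$score)
    }
    c(k = k, unlist(rep))
  })
  per_k <- as.data.frame(do.call(rbind, rows))
  best <- order(-per_k$ACC, -per_k$MCC, per_k$k)[1]
  structure(list(grid = grid, per_k = per_k, best_k = per_k$k[best],
                 mode = mode,
                 selection_rule = "max ACC, tie-break max MCC, then smallest k"),
            class = "sweep_result")
}

#' @exportS3Method base::print
print.sweep_result <- function(x, ...) {
  cat(sprintf("top-k sweep over %d candidates (%s scoring): best k = %d\n",
              length(x$grid), x$mode, x$best_k))
  print(utils::head(x$per_k[order(-x$per_k$ACC), ], 5))
  invisible(x)
}

#' Write a feature ranking as a TSV table
#'
#' Columns: rank, feature label, split-count importance.
#'
#' @param ranking A `feature_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking$order), feature = ranking$labels,
                   importance = ranking$importance)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
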