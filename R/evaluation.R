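# Seven-metric evaluation, stratified cross-validation, the Friedman rank
# test for comparing model/feature groups, and 2-D feature-space embeddings.

#' Confusion counts of a binary prediction
#'
#' @param predicted,actual 0/1 vectors of equal length.
#' @return Named list of class `confusion_counts`: TP, TN, FP, FN.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  stopifnot(length(predicted) == length(actual),
            all(predicted %in% 0:1), all(actual %in% 0:1))
  structure(list(TP = sum(predicted == 1L & actual == 1L),
                 TN = sum(predicted == 0L & actual == 0L),
                 FP = sum(predicted == 1L & actual == 0L),
                 FN = sum(predicted == 0L & actual == 1L)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reporting 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Seven evaluation metrics from confusion counts
#'
#' Computes accuracy `ACC = (TP+TN)/(TP+TN+FP+FN)`, Matthews correlation
#' coefficient `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, precision
#' `Pre = TP/(TP+FP)`, the rank-based area under the ROC curve (when
#' per-record scores are supplied), and `F1 = 2*Pre*Sn/(Pre+Sn)`.
#'
#' Zero-denominator policy: Sn, Sp, Pre and F1 report 0 with a warning when
#' undefined; MCC reports 0 when any confusion-matrix marginal is 0. AUC is
#' `NA` when no scores are given; tied scores receive half credit, making
#' the value identical to counting concordant score pairs across the two
#' classes.
#'
#' @param counts A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @param scores Optional real-valued confidence per record (higher means
#'   more confidently positive), required for AUC.
#' @param labels Optional 0/1 truth per record, parallel to `scores`.
#' @return Named list of class `metrics_report`: ACC, MCC, Sn, Sp, Pre,
#'   AUC, F1.
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0) stop("empty confusion counts")
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  acc <- (TP + TN) / n
  sn <- safe_ratio(TP, TP + FN, "Sn")
  sp <- safe_ratio(TN, TN + FP, "Sp")
  pre <- safe_ratio(TP, TP + FP, "Pre")
  denom2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom2 == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom2)
  f1 <- if (pre + sn == 0) {
    warning("F1 undefined (Pre + Sn = 0); reporting 0", call. = FALSE)
    0
  } else 2 * pre * sn / (pre + sn)
  auc <- if (is.null(scores)) NA_real_ else auc_score(scores, labels)
  structure(list(ACC = acc, MCC = mcc, Sn = sn, Sp = sp, Pre = pre,
                 AUC = auc, F1 = f1),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  vals <- unlist(x)
  cat(paste(sprintf("%s=%.4f", names(vals), vals), collapse = "  "), "\n")
  invisible(x)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted half.
#'
#' @param scores Real-valued confidences.
#' @param labels 0/1 truth.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined with a single class; reporting NA", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metrics of a labeled prediction vector
#'
#' Thin wrapper tying [confusion_counts()] and [compute_metrics()]
#' together.
#'
#' @param predicted Predicted 0/1 labels.
#' @param actual True 0/1 labels.
#' @param scores Optional confidences for AUC.
#' @return A `metrics_report`.
#' @export
evaluate_predictions <- function(predicted, actual, scores = NULL) {
  compute_metrics(confusion_counts(predicted, actual), scores, actual)
}

#' Composite grid score
#'
#' Mean of the six independently evaluated metrics used to compare grid
#' cells: ACC, MCC, Sn, Sp, AUC and Pre.
#'
#' @param report A `metrics_report`.
#' @return Single number.
#' @export
mean_score <- function(report) {
  mean(unlist(report[c("ACC", "MCC", "Sn", "Sp", "AUC", "Pre")]))
}

#' Stratified k-fold cross-validation
#'
#' Assigns each class's records round-robin to `folds` folds after a seeded
#' shuffle, then trains on k-1 folds and evaluates on the held-out fold.
#'
#' @param x,y Feature matrix and 0/1 labels.
#' @param algorithm,hyperparameters,standardize Passed to
#'   [train_classifier()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and training.
#' @return List with `mean` (metrics averaged over folds), `per_fold`
#'   (list of `metrics_report`), and `fold` (the fold id of every record).
#' @export
cross_validate <- function(x, y, algorithm = "svm", hyperparameters = list(),
                           folds = 5L, seed = 1L, standardize = FALSE) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be at least 2")
  y <- as.integer(y)
  if (any(table(y) < folds)) stop("each class needs at least ", folds, " members")
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold != f
    model <- train_classifier(x[tr, , drop = FALSE], y[tr],
                              algorithm = algorithm,
                              hyperparameters = hyperparameters,
                              seed = seed, standardize = standardize)
    pred <- predict(model, x[!tr, , drop = FALSE])
    evaluate_predictions(pred$label, y[!tr], pred$score)
  })
  mean_rep <- as.list(colMeans(do.call(rbind, lapply(per_fold, unlist))))
  class(mean_rep) <- "metrics_report"
  list(mean = mean_rep, per_fold = per_fold, fold = fold)
}

#' Friedman rank test
#'
#' Nonparametric omnibus test for consistent differences among k treatments
#' (models, feature sets) measured on the same N blocks (metrics, datasets,
#' folds). Values are ranked within each block (average ranks on ties) and
#' the statistic `chi2 = 12/(N k (k+1)) * sum_j R_j^2 - 3 N (k+1)` is
#' referred to a chi-squared distribution with k-1 degrees of freedom. A
#' tie-corrected statistic (the uncorrected value divided by
#' `1 - sum(t^3 - t) / (N k (k^2 - 1))` over tie groups) is reported
#' alongside; with no ties the two coincide.
#'
#' @param scores N x k numeric matrix: blocks in rows, treatments in
#'   columns. Higher is taken as better; ranking direction does not affect
#'   the statistic.
#' @return Object of class `friedman_result`: list with `chi2`,
#'   `chi2_tie_corrected`, `p_value`, `p_value_tie_corrected`, `N`, `k`,
#'   `rank_sums`, `df`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  N <- nrow(scores); k <- ncol(scores)
  if (N < 2L || k < 2L) stop("need at least 2 blocks and 2 treatments")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ranks <- t(apply(scores, 1, rank))
  R <- colSums(ranks)
  chi2 <- 12 / (N * k * (k + 1)) * sum(R^2) - 3 * N * (k + 1)
  # tie correction over blocks
  tie_term <- sum(apply(scores, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  corr <- 1 - tie_term / (N * k * (k^2 - 1))
  chi2_c <- if (corr > 0) chi2 / corr else chi2
  df <- k - 1
  structure(list(chi2 = chi2, chi2_tie_corrected = chi2_c,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 p_value_tie_corrected =
                   stats::pchisq(chi2_c, df, lower.tail = FALSE),
                 N = N, k = k, rank_sums = R, df = df),
            class = "friedman_result")
}

#' @exportS3Method base::print
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test: chi2 = %.4f (df = %d), p = %.4g  [N = %d, k = %d]\n",
              x$chi2, x$df, x$p_value, x$N, x$k))
  invisible(x)
}

#' Two-dimensional feature-space embedding
#'
#' Projects an encoded feature matrix to 2-D for qualitative inspection of
#' class separation. Methods: `"pca"` (first two principal components,
#' centered) and `"mds"` (classical metric multidimensional scaling on
#' Euclidean distances). Both are deterministic; the seed is recorded for
#' provenance and to keep the interface stable if stochastic methods are
#' added.
#'
#' @param x Feature matrix with at least 10 rows.
#' @param labels Optional 0/1 labels, carried into the result for plotting.
#' @param method `"pca"` or `"mds"`.
#' @param seed Integer, recorded in the result.
#' @return Object of class `embedding_2d`: list with `coordinates` (n x 2
#'   matrix), `labels`, `method`, `seed`.
#' @export
embed_2d <- function(x, labels = NULL, method = c("pca", "mds"), seed = 0L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 10L) stop("embedding needs at least 10 records")
  coords <- switch(method,
    pca = {
      pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)
      sc <- pc$x
      if (ncol(sc) < 2L) sc <- cbind(sc, 0)
      sc[, 1:2, drop = FALSE]
    },
    mds = stats::cmdscale(stats::dist(x), k = 2))
  dimnames(coords) <- list(rownames(x), c("dim1", "dim2"))
  structure(list(coordinates = coords, labels = labels, method = method,
                 seed = as.integer(seed)),
            class = "embedding_2d")
}

#' Write a 2-D embedding as a TSV table
#'
#' Columns: id, x, y, and label when available.
#'
#' @param embedding An `embedding_2d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(id = rownames(embedding$coordinates) %||%
                     seq_len(nrow(embedding$coordinates)),
                   x = embedding$coordinates[, 1],
                   y = embedding$coordinates[, 2])
  if (!is.null(embedding$labels)) df$label <- embedding$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
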