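# The descriptor-combination x algorithm model grid and its Friedman
# comparison harness.

#' Evaluate the full feature-set x algorithm model grid
#'
#' Instantiates one model per (descriptor combination, algorithm) cell —
#' with the four standard encoders that is 15 x 6 = 90 cells — trains each
#' on the training split and scores it on the held-out split, reporting the
#' seven metrics plus the composite `mean_score` (mean of ACC, MCC, Sn, Sp,
#' AUC, Pre) per cell.
#'
#' @param peptides Labeled `peptide_set`.
#' @param feature_sets List of encoder-name vectors (default all 15
#'   non-empty subsets from [enumerate_feature_sets()]).
#' @param algorithms Character vector of algorithm names (default all six).
#' @param train_fraction,seed Split parameters (see [split_dataset()]).
#' @param hyperparameters Optional named list of per-algorithm
#'   hyperparameter lists.
#' @param resources Resource bundle from [load_resources()].
#' @return Data frame with one row per grid cell: `feature_set`,
#'   `algorithm`, the seven metrics, and `mean_score`.
#' @export
model_grid <- function(peptides, feature_sets = enumerate_feature_sets(),
                       algorithms = ALGORITHMS, train_fraction = 0.8,
                       seed = 1L, hyperparameters = list(),
                       resources = load_resources()) {
  split <- split_dataset(peptides, train_fraction = train_fraction, seed = seed)
  rows <- list()
  for (fs in feature_sets) {
    fs <- canonical_spec(fs)
    x_tr <- encode_peptides(split$train, fs, resources)
    x_te <- encode_peptides(split$test, fs, resources)
    for (alg in algorithms) {
      hp <- hyperparameters[[alg]] %||% list()
      model <- train_classifier(x_tr, split$train$label, algorithm = alg,
                                hyperparameters = hp, seed = seed)
      pred <- predict(model, x_te)
      rep <- evaluate_predictions(pred$label, split$test$label, pred$score)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = paste(fs, collapse = "+"), algorithm = alg,
        as.list(unlist(rep)), mean_score = mean_score(rep),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Friedman comparison over a model grid
#'
#' Builds a blocks x treatments score matrix from a [model_grid()] result
#' and runs [friedman_test()] on it. The default pairing treats the
#' evaluation metrics (ACC, MCC, Sn, Sp, AUC, Pre) as blocks and either
#' the feature sets (within one algorithm) or the algorithms (within one
#' feature set) as treatments; block construction is exposed because other
#' pairings (e.g. feature sets as blocks) are equally legitimate.
#'
#' @param grid Data frame from [model_grid()].
#' @param treatment `"feature_set"` or `"algorithm"` — the grid column
#'   whose values are compared.
#' @param within Optional filter: a single value of the *other* grouping
#'   column to restrict the grid to (e.g. compare feature sets within
#'   `algorithm = "svm"`). `NULL` uses all rows, averaging duplicates.
#' @param blocks Metric names used as blocks.
#' @return A `friedman_result`, with the score matrix attached as
#'   attribute `"scores"`.
#' @export
grid_friedman <- function(grid, treatment = c("feature_set", "algorithm"),
                          within = NULL,
                          blocks = c("ACC", "MCC", "Sn", "Sp", "AUC", "Pre")) {
  treatment <- match.arg(treatment)
  other <- setdiff(c("feature_set", "algorithm"), treatment)
  if (!is.null(within)) grid <- grid[grid[[other]] == within, , drop = FALSE]
  groups <- unique(grid[[treatment]])
  if (length(groups) < 2L) stop("need at least two treatments to compare")
  m <- vapply(groups, function(g) {
    colMeans(grid[grid[[treatment]] == g, blocks, drop = FALSE])
  }, numeric(length(blocks)))
  rownames(m) <- blocks
  res <- friedman_test(m)
  attr(res, "scores") <- m
  res
}
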