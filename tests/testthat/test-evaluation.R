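test_that("metrics match their defining formulas on worked confusion counts", {
  perfect <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("ACC", "MCC", "Sn", "Sp", "Pre", "F1")]),
               c(ACC = 1, MCC = 1, Sn = 1, Sp = 1, Pre = 1, F1 = 1))

  rep <- compute_metrics(list(TP = 40, FN = 10, TN = 45, FP = 5))
  expect_equal(rep$ACC, 0.85)
  expect_equal(rep$Sn, 0.80)
  expect_equal(rep$Sp, 0.90)
  expect_equal(rep$Pre, 40 / 45)
  expect_equal(rep$F1, 2 * (40 / 45) * 0.8 / (40 / 45 + 0.8))
  expect_equal(rep$MCC,
               (40 * 45 - 5 * 10) / sqrt(45 * 50 * 50 * 55))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("metrics agree with a brute-force oracle over 1000 random vectors", {
  withr::with_seed(123, {
    for (i in 1:1000) {
      n <- sample(10:60, 1)
      truth <- sample(0:1, n, replace = TRUE)
      if (length(unique(truth)) < 2) truth[1:2] <- 0:1
      pred <- sample(0:1, n, replace = TRUE)
      got <- suppressWarnings(
        evaluate_predictions(pred, truth))
      want <- metrics_oracle(pred, truth)
      expect_equal(unlist(got[names(want)]), want)
    }
  })
})

test_that("rank-based AUC equals pairwise concordance counting to 1e-12", {
  withr::with_seed(321, {
    for (i in 1:50) {
      n <- sample(20:80, 1)
      labels <- sample(0:1, n, replace = TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- 0:1
      scores <- round(stats::rnorm(n), sample(0:2, 1))  # induce ties
      expect_equal(auc_score(scores, labels), auc_oracle(scores, labels),
                   tolerance = 1e-12)
    }
  })
  # and against an independent reference implementation
  withr::with_seed(11, {
    labels <- sample(0:1, 200, replace = TRUE)
    scores <- stats::rnorm(200) + labels
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
})

test_that("uniformly random scores on balanced labels give AUC near one half", {
  withr::with_seed(77, {
    labels <- rep(0:1, each = 1000)
    scores <- stats::runif(2000)
  })
  expect_lt(abs(auc_score(scores, labels) - 0.5), 0.03)
})

test_that("undefined ratios fall back to zero with a warning", {
  rep <- NULL
  w <- capture_warnings(rep <- compute_metrics(list(TP = 0, TN = 90,
                                                    FP = 0, FN = 10)))
  expect_match(w, "Pre", all = FALSE)
  expect_match(w, "F1", all = FALSE)
  expect_equal(rep$Pre, 0)
  expect_equal(rep$MCC, 0)  # zero marginal
  expect_equal(rep$F1, 0)
})

test_that("F1 is the harmonic mean of precision and sensitivity", {
  withr::with_seed(5, {
    for (i in 1:100) {
      truth <- sample(0:1, 40, replace = TRUE)
      pred <- sample(0:1, 40, replace = TRUE)
      rep <- suppressWarnings(evaluate_predictions(pred, truth))
      if (rep$Pre > 0 && rep$Sn > 0) {
        expect_equal(rep$F1, 2 / (1 / rep$Pre + 1 / rep$Sn))
      }
    }
  })
})

test_that("cross-validation is stratified, deterministic, and exact on separable data", {
  toy <- toy_separable(n = 50)
  cv <- cross_validate(toy$x, toy$y, "svm", folds = 5, seed = 13)
  expect_equal(cv$mean$ACC, 1)
  expect_length(cv$per_fold, 5)
  # every fold holds both classes (stratification)
  for (f in 1:5) expect_setequal(unique(toy$y[cv$fold == f]), 0:1)
  cv2 <- cross_validate(toy$x, toy$y, "svm", folds = 5, seed = 13)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$mean, cv2$mean)
  expect_error(cross_validate(toy$x, toy$y, folds = 1), "at least 2")
})

test_that("Friedman statistic matches its closed forms", {
  # identical treatments in every block: zero statistic, p = 1
  same <- matrix(5, nrow = 4, ncol = 3)
  r0 <- friedman_test(same)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p_value, 1)
  # perfectly consistent ordering of k = 3 treatments: chi2 = 2N
  for (N in c(2, 6, 10)) {
    m <- matrix(rep(c(1, 2, 3), each = N), nrow = N)
    res <- friedman_test(m)
    expect_equal(res$chi2, 2 * N)
    expect_equal(sum(res$rank_sums), N * 3 * 4 / 2)
  }
  # block order is irrelevant (within-block ranks only)
  withr::with_seed(2, m <- matrix(stats::rnorm(24), 6, 4))
  expect_equal(friedman_test(m)$chi2, friedman_test(m[6:1, ])$chi2)
  expect_error(friedman_test(matrix(1, 1, 3)), "at least 2")
})

test_that("Friedman agrees with the reference implementation on tie-free data", {
  withr::with_seed(31, {
    for (i in 1:100) {
      N <- sample(3:10, 1); k <- sample(3:6, 1)
      m <- matrix(stats::rnorm(N * k), N, k)  # continuous: ties impossible
      ours <- friedman_test(m)
      ref <- stats::friedman.test(m)
      expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
      expect_equal(ours$chi2_tie_corrected, ours$chi2)  # no ties, no correction
    }
  })
})

test_that("tied scores receive average ranks and a tie-corrected statistic", {
  m <- rbind(c(1, 1, 2), c(1, 2, 2), c(3, 1, 2))
  res <- friedman_test(m)
  expect_equal(sum(res$rank_sums), 3 * 3 * 4 / 2)  # average ranks preserve the sum
  expect_gte(res$chi2_tie_corrected, res$chi2)
})

test_that("2-D embeddings have the shape contract and separate separable classes", {
  ds <- generate_dataset(synthesis_config(n_pos = 40, n_neg = 40, seed = 14))
  x <- encode_peptides(ds, "ctd", RES)
  for (method in c("pca", "mds")) {
    emb <- embed_2d(x, ds$label, method = method, seed = 14)
    expect_identical(dim(emb$coordinates), c(80L, 2L))
    expect_identical(emb$coordinates,
                     embed_2d(x, ds$label, method = method, seed = 14)$coordinates)
  }
  emb <- embed_2d(x, ds$label, method = "pca")
  # mean silhouette of the class labeling in the plane is positive
  d <- as.matrix(stats::dist(emb$coordinates))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- ds$label[i]
    a <- mean(d[i, ds$label == own & seq_len(nrow(d)) != i])
    b <- mean(d[i, ds$label != own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  expect_error(embed_2d(x[1:5, ]), "at least 10")
})

test_that("the composite grid score averages the six comparison metrics", {
  rep <- compute_metrics(list(TP = 40, FN = 10, TN = 45, FP = 5),
                         scores = c(0.9, 0.1), labels = c(1, 0))
  expect_equal(mean_score(rep),
               mean(unlist(rep[c("ACC", "MCC", "Sn", "Sp", "AUC", "Pre")])))
})
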