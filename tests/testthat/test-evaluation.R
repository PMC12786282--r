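test_that("ROC AUC matches analytic cases and the pairwise oracle", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(rocAuc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(12)
  for (r in 1:50) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties frequent
    expect_equal(rocAuc(scores, labels)$auc, aucPairwise(scores, labels))
  }
})

test_that("ROC AUC agrees with pROC and is monotone-transform invariant", {
  set.seed(3)
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  got <- rocAuc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref)
  expect_equal(rocAuc(qlogis(scores), labels)$auc, got)   # strictly monotone
  expect_equal(rocAuc(scores^3, labels)$auc, got)
})

test_that("precision-recall area behaves at its anchors", {
  expect_equal(prAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$pr_auc, 1)
  expect_equal(prAuc(c(0.9, 0.1, 0.2), c(1, 0, 0))$pr_auc, 1)
  expect_error(prAuc(c(0.1, 0.2), c(0, 0)), "positive")
  # random scores converge to prevalence
  set.seed(7)
  n <- 1e4; prev <- 0.3
  labels <- rbinom(n, 1, prev)
  expect_equal(prAuc(runif(n), labels)$pr_auc, prev, tolerance = 0.03)
})

test_that("confusion rates follow the threshold policy", {
  scores <- c(0.9, 0.8, 0.7, 0.1); labels <- c(1, 0, 1, 0)
  r <- confusionAndRates(scores, labels, threshold = 0.5)
  expect_equal(unname(r$confusion), c(2, 1, 1, 0))   # TP FP TN FN
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 0.5)
  expect_equal(r$accuracy, 0.75)
  # inverting scores at the complementary threshold complements the rates
  ri <- confusionAndRates(1 - scores, labels, threshold = 0.5 + 1e-12)
  expect_equal(ri$sensitivity, 1 - r$sensitivity)
  expect_equal(ri$specificity, 1 - r$specificity)
  # perfect scores: everything 1 at any interior threshold
  p <- confusionAndRates(c(0.99, 0.98, 0.01), c(1, 1, 0), threshold = 0.4)
  expect_equal(c(p$sensitivity, p$specificity, p$accuracy), c(1, 1, 1))
  expect_error(confusionAndRates(scores, labels, threshold = "youden"),
               "validation")
  ry <- confusionAndRates(scores, labels, threshold = "youden",
                          val_scores = scores, val_labels = labels)
  expect_true(is.numeric(ry$threshold))
})

test_that("marker fusion preserves ranks and tolerates a dead marker", {
  set.seed(21)
  n <- 200
  lab <- rep(c(0, 1), each = n / 2)
  good <- plogis(rnorm(n, mean = 2.5 * lab - 1.25))
  a <- data.frame(subject_id = sprintf("s%03d", 1:n), score = good, label = lab)
  # identical marker scores: fused score is rank-preserving
  fu <- fuseMarkers(a, a, method = "kan", seed = 4)
  expect_gt(cor(rank(fu$scores$score), rank(a$score)), 0.9999)
  # mean fallback
  b <- a; b$score <- 1 - a$score
  fm <- fuseMarkers(a, b, method = "mean")
  expect_true(all(abs(fm$scores$score - 0.5) < 1e-12))
  expect_null(fm$model)
  # one marker pure noise: fusion at most 0.02 below the informative marker
  noise <- a; noise$score <- runif(n)
  fn <- fuseMarkers(a, noise, method = "kan", seed = 4)
  expect_gte(rocAuc(fn$scores$score, lab)$auc, rocAuc(good, lab)$auc - 0.02)
  expect_error(fuseMarkers(a, a[1:50, ], method = "mean"), "same subjects")
})

test_that("permutation importance attributes signal to the informative marker", {
  set.seed(31)
  n <- 300
  lab <- rep(c(0, 1), each = n / 2)
  sig <- plogis(rnorm(n, mean = 3 * lab - 1.5))
  a <- data.frame(subject_id = sprintf("s%03d", 1:n), score = sig, label = lab)
  # two i.i.d. copies of the same kind of signal: symmetric importance
  b <- a; b$score <- plogis(rnorm(n, mean = 3 * lab - 1.5))
  fu <- fuseMarkers(a, b, method = "kan", seed = 9)
  imp <- relativeImportance(fu, a, b, n_permutations = 40, seed = 2)
  expect_equal(sum(imp$importance), 1)
  expect_lt(abs(imp$importance[1] - 0.5), 0.1)
  # one marker pure noise: its importance collapses
  nz <- a; nz$score <- runif(n)
  fu2 <- fuseMarkers(a, nz, method = "kan", seed = 9)
  imp2 <- relativeImportance(fu2, a, nz, n_permutations = 40, seed = 2)
  expect_lt(imp2$importance[2], 0.1)
  expect_error(relativeImportance(fuseMarkers(a, b, method = "mean"), a, b),
               "trained")
})

test_that("attention heatmaps are exported with annotated axes", {
  m <- buildFullSpectrumModel(64, patch_length = 8, d_model = 16, layers = 2,
                              heads = 2, head_hidden = 4, seed = 2)
  set.seed(5)
  X3 <- array(rnorm(3 * 8 * 16), c(3, 8, 16))
  dir <- file.path(tempdir(), "attmaps")
  maps <- exportAttentionHeatmaps(m, X3, grid = seq(500, 531.5, by = 0.5), dir)
  files <- list.files(dir, pattern = "^attention_layer\\d_head\\d\\.csv$")
  expect_length(files, 4)
  M <- as.matrix(read.csv(file.path(dir, files[1]), row.names = 1,
                          check.names = FALSE))
  expect_equal(dim(M), c(8, 8))
  expect_lt(max(abs(rowSums(M) - 1)), 1e-6)
  expect_match(rownames(M)[1], "nm")
  ov <- attentionModeOverlap(maps, seq(500, 531.5, by = 0.5), 8,
                             windows = list(W = c(500, 516)), n_top = 2)
  expect_equal(nrow(ov), 4)
  expect_true(all(ov$n_top_in_windows >= 0 & ov$n_top_in_windows <= 2))
})
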