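test_that("vectorized KAN layer equals the brute-force edge evaluation", {
  spec <- splineSpec()
  set.seed(11)
  for (r in 1:20) {
    p_in <- sample(1:4, 1); p_out <- sample(1:4, 1); n <- sample(1:6, 1)
    lay <- kanLayerInit(p_in, p_out, spec, seed = r)
    lay$coef <- matrix(rnorm(length(lay$coef)), nrow(lay$coef))
    lay$w <- matrix(rnorm(length(lay$w)), nrow(lay$w))
    X <- matrix(rnorm(n * p_in, sd = 2), n, p_in)   # exercises clamping too
    expect_lt(max(abs(kanLayerForward(X, lay, spec) -
                        kanLayerForwardNaive(X, lay, spec))), 1e-10)
  }
})

test_that("KAN layer edge cases behave analytically", {
  spec <- splineSpec()
  lay <- kanLayerInit(3, 2, spec, seed = 1)
  lay$coef[] <- 0; lay$w[] <- 0
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(kanLayerForward(X, lay, spec), matrix(0, 4, 2))
  # one edge interpolating the identity, all else silent
  lay$coef[seq_len(spec$m), 1] <- splineInterpolate(identity, spec)
  xs <- matrix(c(seq(-2.5, 2.5, length.out = 7), rep(0, 14)), 7, 3)
  out <- kanLayerForward(xs, lay, spec)
  expect_equal(out[, 1], xs[, 1], tolerance = 1e-8)
  expect_equal(out[, 2], rep(0, 7))
  expect_error(kanLayerForward(matrix(1, 2, 5), lay, spec), "width")
  expect_error(kanLayerForward(matrix(c(1, NA), 1, 2),
                               kanLayerInit(2, 1, spec), spec), "finite")
})

test_that("layer gradients match finite differences", {
  spec <- splineSpec()
  m <- buildFeatureModel(3, hidden = 4, seed = 2)
  set.seed(4)
  X <- matrix(rnorm(15), 5, 3); y <- c(1, 0, 1, 1, 0)
  fw <- plasmoKAN:::featureForward(m, X, cache = TRUE)
  dlogit <- (pmin(pmax(fw$p, 1e-7), 1 - 1e-7) - y) / 5
  gr <- plasmoKAN:::featureBackward(m, fw, dlogit)
  lossAt <- function(params) { m@params <- params
    bceLoss(y, plasmoKAN:::featureForward(m, X)) }
  for (nm in names(m@params)) {
    idx <- sample(length(m@params[[nm]]), 3)
    for (i in idx) {
      p2 <- m@params; p2[[nm]][i] <- p2[[nm]][i] + 1e-5
      expect_equal((lossAt(p2) - lossAt(m@params)) / 1e-5, gr[[nm]][i],
                   tolerance = 1e-3)
    }
  }
})

test_that("binary cross-entropy matches its analytic values", {
  expect_equal(bceLoss(c(1, 0, 1), rep(0.5, 3)), log(2))
  expect_lt(bceLoss(c(1, 0), c(1, 0)), 1.1e-7)
  expect_equal(bceLoss(1, 0.25), -log(0.25), tolerance = 1e-12)
  expect_error(bceLoss(c(1, 2), c(0.5, 0.5)), "labels")
  expect_gte(bceLoss(c(0, 1), c(0.9, 0.1)), 0)
})

test_that("positional encoding interleaves bounded sinusoids", {
  enc <- positionalEncoding(32, 8)
  expect_equal(dim(enc), c(32, 8))
  expect_true(all(enc >= -1 & enc <= 1))
  expect_equal(enc[1, ], rep(c(0, 1), 4))          # pos = 0: sin 0, cos 1
  expect_equal(enc[2, 1], sin(1))                   # pos = 1, i = 0: angle 1
  expect_equal(enc[2, 2], cos(1))
  pos <- 0:31
  expect_equal(enc[, 3], sin(pos / 10000^(2 / 8)))  # second frequency pair
  expect_error(positionalEncoding(4, 7), "even")
})

test_that("model construction is deterministic and parameter-frugal", {
  m1 <- buildFeatureModel(8, seed = 5)
  m2 <- buildFeatureModel(8, seed = 5)
  expect_identical(m1@params, m2@params)
  mlp <- buildMLPModel(8, seed = 5)
  expect_lt(parameterCount(m1), parameterCount(mlp))
  expect_gt(parameterCount(m1), 0)
  full <- buildFullSpectrumModel(601, seed = 5)
  expect_identical(full@params, buildFullSpectrumModel(601, seed = 5)@params)
  expect_error(buildFullSpectrumModel(601, layers = 1), "at least 2")
  expect_error(buildFullSpectrumModel(601, d_model = 63), "divisible")
})

test_that("training separates separable classes and not shuffled labels", {
  set.seed(9)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(2 * n), n, 2) + cbind(3 * y, -3 * y)
  tr <- sample(n, 300); va <- setdiff(seq_len(n), tr)
  m <- buildFeatureModel(2, hidden = 4, seed = 1)
  cfg <- trainConfig(epochs = 50, batch_size = 32, patience = 50, seed = 3)
  fit <- trainClassifier(m, X[tr, ], y[tr], X[va, ], y[va], cfg)
  h <- trainingHistory(fit)
  expect_gte(h$val_auc[h$best_epoch], 0.99)
  expect_true(all(is.finite(h$train_loss)))
  # same seed: identical learning curves
  fit2 <- trainClassifier(m, X[tr, ], y[tr], X[va, ], y[va], cfg)
  expect_identical(trainingHistory(fit)$train_loss,
                   trainingHistory(fit2)$train_loss)
  # label shuffling: chance-level validation AUC
  ys <- plasmoKAN:::withSeed(5, sample(y))
  fit0 <- trainClassifier(m, X[tr, ], ys[tr], X[va, ], ys[va],
                          trainConfig(epochs = 20, batch_size = 32,
                                      patience = 20, seed = 3))
  h0 <- trainingHistory(fit0)
  expect_gt(h0$val_auc[h0$best_epoch], 0.35)
  expect_lt(median(h0$val_auc), 0.65)
})

test_that("full-spectrum model exposes normalized attention and valid probabilities", {
  m <- buildFullSpectrumModel(64, patch_length = 8, d_model = 16, layers = 2,
                              heads = 2, head_hidden = 4, seed = 2)
  set.seed(6)
  X3 <- array(rnorm(4 * m@config$n_patches * 16), c(4, m@config$n_patches, 16))
  p <- plasmoKAN:::fullForward(m, X3)
  expect_true(all(p > 0 & p < 1))
  maps <- attentionMaps(m, X3)
  expect_length(maps, 2)
  expect_length(maps[[1]], 2)
  for (l in 1:2) for (h in 1:2) {
    M <- maps[[l]][[h]]
    expect_equal(dim(M), rep(m@config$n_patches, 2))
    expect_lt(max(abs(rowSums(M) - 1)), 1e-6)
  }
  # identical inputs give identical probabilities
  Xs <- X3[rep(1, 4), , , drop = FALSE]
  expect_equal(diff(range(plasmoKAN:::fullForward(m, Xs))), 0)
  # attention maps are refused for feature models
  expect_error(attentionMaps(buildFeatureModel(4), matrix(0, 2, 4)),
               "full-spectrum")
})

test_that("full-spectrum gradients match finite differences", {
  m <- buildFullSpectrumModel(40, patch_length = 8, d_model = 8, layers = 2,
                              heads = 2, head_hidden = 3, seed = 3)
  set.seed(8)
  X3 <- array(rnorm(3 * m@config$n_patches * 16), c(3, m@config$n_patches, 16))
  y <- c(1, 0, 1)
  fw <- plasmoKAN:::fullForward(m, X3, cache = TRUE)
  dlogit <- (pmin(pmax(fw$p, 1e-7), 1 - 1e-7) - y) / 3
  gr <- plasmoKAN:::fullBackward(m, fw, dlogit)
  lossAt <- function(params) { m@params <- params
    bceLoss(y, plasmoKAN:::fullForward(m, X3)) }
  for (nm in c("embed.W", "att1.Wq", "att2.Wv", "att2.ln.g", "pool.ln.b",
               "head1.coef", "head2.w")) {
    idx <- sample(length(m@params[[nm]]), 3)
    for (i in idx) {
      p2 <- m@params; p2[[nm]][i] <- p2[[nm]][i] + 1e-5
      expect_equal((lossAt(p2) - lossAt(m@params)) / 1e-5, gr[[nm]][i],
                   tolerance = 2e-3)
    }
  }
})

test_that("subject scores average replicate probabilities", {
  probs <- c(0.2, 0.4, 0.9, 0.7)
  subj <- c("a", "a", "b", "b")
  sc <- subjectScores(probs, subj, labels = c(0, 0, 1, 1))
  expect_equal(sc$score[sc$subject_id == "a"], 0.3)
  expect_equal(sc$score[sc$subject_id == "b"], 0.8)
  expect_equal(sc$label, c(0, 1))
  expect_error(subjectScores(probs, subj, labels = c(0, 1, 1, 1)), "differ")
})
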