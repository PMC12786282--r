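test_that("trough detection refines to sub-grid precision", {
  grid <- defaultGrid()
  on <- synthesizeSpectrum(oneMode(center = 700), grid)
  tr <- detectModeTroughs(on, windows = list(P4 = c(680, 760)))
  expect_false(tr$flagged)
  expect_lt(abs(tr$lambda_res - 700), 0.25)
  expect_equal(tr$R_min, 0.95 - 0.45, tolerance = 1e-3)
  # dip centered between grid points
  off <- synthesizeSpectrum(oneMode(center = 700.25), grid)
  tro <- detectModeTroughs(off, windows = list(P4 = c(680, 760)))
  expect_lt(abs(tro$lambda_res - 700.25), 0.05)
  # flat spectrum: every window flagged
  flat <- data.frame(wavelength_nm = grid, reflectance = rep(0.9, length(grid)))
  expect_true(all(detectModeTroughs(flat)$flagged))
})

test_that("trough detection is translation-consistent", {
  grid <- defaultGrid()
  w <- list(M = c(650, 760))
  for (k in c(2, 5, 11)) {
    a <- detectModeTroughs(synthesizeSpectrum(oneMode(center = 700), grid), w)
    b <- detectModeTroughs(synthesizeSpectrum(oneMode(center = 700 + k * 0.5),
                                              grid), w)
    expect_equal(b$lambda_res - a$lambda_res, k * 0.5, tolerance = 1e-6)
  }
})

test_that("effect features measure the injected pre/post changes", {
  grid <- defaultGrid()
  pre <- synthesizeSpectrum(defaultModes(), grid)
  expect_equal(unname(extractEffectFeatures(pre, pre, "NLE")), rep(0, 8))
  expect_length(extractEffectFeatures(pre, pre, "NLE"), 8)
  expect_length(extractEffectFeatures(pre, pre, "RE"), 4)
  # shift only P4 by 2 nm
  m2 <- defaultModes()
  m2$center_wavelength_nm[4] <- 730
  post <- synthesizeSpectrum(m2, grid)
  re <- extractEffectFeatures(pre, post, "RE")
  expect_equal(unname(re["dlambda_P4"]), 2, tolerance = 0.05)
  expect_true(all(abs(re[c("dlambda_P1", "dlambda_P2")]) < 0.05))
  # single-mode variant
  expect_length(extractEffectFeatures(pre, post, "RE", mode_set = "P4"), 1)
  # grid mismatch rejected
  shifted <- pre; shifted$wavelength_nm <- shifted$wavelength_nm + 1
  expect_error(extractEffectFeatures(shifted, post, "RE"), "grid")
})

test_that("batch feature extraction matches the single-pair path", {
  se <- tinyDataset(12, seed = 77)
  tab <- suppressWarnings(extractFeatureTable(se, "NLE"))
  grid <- wavelengthGrid(se)
  i <- which(colnames(se) %in% tab$record_id)[5]
  single <- extractEffectFeatures(
    data.frame(wavelength_nm = grid, reflectance = preSpectra(se)[, i]),
    data.frame(wavelength_nm = grid, reflectance = postSpectra(se)[, i]), "NLE")
  row <- tab[tab$record_id == colnames(se)[i], ]
  expect_equal(unname(as.numeric(row[, names(single)])), unname(single),
               tolerance = 1e-12)
})

test_that("patch tiling is exact and invertible", {
  grid <- seq(500, 799.5, by = 0.5)   # 600 points
  pre <- synthesizeSpectrum(defaultModes(), grid)
  post <- synthesizeSpectrum(applyBinding(defaultModes(),
                                          bindingState(x = 1),
                                          materialModel()), grid)
  ps <- patchSequence(pre, post, 16)
  expect_equal(nrow(ps$patches), 38)          # ceiling(600/16)
  expect_equal(ps$pos, 0:37)
  rt <- unpatchSequence(ps)
  expect_equal(rt$pre, pre$reflectance)
  expect_equal(rt$post, post$reflectance)
  # identical channels: difference of the two channel blocks is zero
  same <- patchSequence(pre, pre, 16)
  expect_equal(same$patches[, 1:16], same$patches[, 17:32])
})

test_that("patch wavelength bookkeeping covers the band", {
  grid <- defaultGrid()   # 601 points
  pw <- patchWavelengths(grid, 16)
  expect_equal(nrow(pw), 38)
  expect_equal(pw$lo[1], 500)
  expect_equal(pw$hi[38], 800)
  expect_true(all(pw$lo <= pw$hi))
})

test_that("normalization statistics come from the designated records only", {
  se <- tinyDataset(12, seed = 77)
  tr <- which(recordData(se)$partition == "train")
  norm <- spectrumNormalization(se, tr)
  expect_equal(norm$mean_pre, rowMeans(preSpectra(se)[, tr]))
  X <- plasmoKAN:::buildPatchTensor(se, tr, norm, 16)
  expect_equal(dim(X), c(length(tr), ceiling(nrow(se) / 16), 32))
  # z-scored training channels have mean ~0 per wavelength
  expect_lt(max(abs(apply(X, 3, mean))), 0.3)
})
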