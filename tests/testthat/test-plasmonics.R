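test_that("Wood anomaly wavelength follows the grating condition", {
  chip <- chipGeometry(period_nm = 500)
  expect_equal(woodAnomalyWavelength(chip, c(1, 0), materialModel(n_medium = 1.33)),
               665, tolerance = 1e-9)
  expect_equal(woodAnomalyWavelength(chip, c(1, 0), materialModel(n_medium = 1)),
               500)
  expect_equal(woodAnomalyWavelength(chip, c(1, 1), materialModel(n_medium = 1.33)),
               665 / sqrt(2), tolerance = 1e-9)
  expect_error(woodAnomalyWavelength(chip, c(0, 0), materialModel()), "0,0|order")
  # decreasing in the order norm
  lams <- sapply(list(c(1, 0), c(1, 1), c(2, 0), c(2, 1)), function(o)
    woodAnomalyWavelength(chip, o, materialModel(n_medium = 1.33)))
  expect_true(all(diff(lams) < 0))
})

test_that("SPP resonance matches the closed form and its limits", {
  chip <- chipGeometry(period_nm = 500)
  mat <- materialModel(eps_metal = -20, n_medium = 1.33)
  eps_d <- 1.33^2
  expect_equal(sppWavelength(chip, c(1, 0), mat),
               500 * sqrt(eps_d * -20 / (eps_d - 20)), tolerance = 1e-12)
  expect_equal(sppWavelength(chip, c(1, 1), mat),
               sppWavelength(chip, c(1, 0), mat) / sqrt(2), tolerance = 1e-12)
  # metallic limit: SPP condition degenerates to the Wood anomaly
  expect_equal(sppWavelength(chip, c(1, 0), materialModel(eps_metal = -1e9)),
               665, tolerance = 1e-3)
  # SPP always red of the WA for the same order while bound
  for (em in c(-5, -10, -30, -100))
    expect_gt(sppWavelength(chip, c(1, 0), materialModel(eps_metal = em)),
              woodAnomalyWavelength(chip, c(1, 0), materialModel()))
  expect_error(sppWavelength(chip, c(1, 0), materialModel(eps_metal = -1)),
               "bound-mode")
})

test_that("dispersive SPP fixed point agrees with a direct root solve", {
  chip <- chipGeometry(period_nm = 500)
  emf <- function(l) -12 - 0.03 * (l - 600)   # simple linear dispersion
  got <- sppWavelength(chip, c(1, 0), materialModel(eps_metal = emf),
                       lambda_init = 650)
  eps_d <- 1.33^2
  f <- function(l) l - 500 * sqrt(eps_d * emf(l) / (eps_d + emf(l)))
  want <- uniroot(f, c(600, 800), tol = 1e-10)$root
  expect_equal(got, want, tolerance = 1e-5)
  # constant function matches the constant closed form
  expect_equal(sppWavelength(chip, c(1, 0),
                             materialModel(eps_metal = function(l) -20)),
               sppWavelength(chip, c(1, 0), materialModel(eps_metal = -20)),
               tolerance = 1e-5)
})

test_that("Langmuir coverage is bounded, monotone and concave", {
  expect_equal(langmuirCoverage(1, 1), 0.5)
  expect_equal(langmuirCoverage(1, 0), 0)
  expect_equal(langmuirCoverage(2, 3), 6 / 7)
  expect_error(langmuirCoverage(-1, 1), "non-negative")
  expect_error(langmuirCoverage(1, -1), "non-negative")
  x <- seq(0, 50, by = 0.25)
  th <- langmuirCoverage(0.7, x)
  expect_true(all(th >= 0 & th < 1))
  expect_true(all(diff(th) > 0))
  expect_true(all(diff(diff(th)) < 1e-12))  # concave
})

test_that("effective index is an exact convex combination", {
  mat <- materialModel(n_medium = 1.33, n_analyte = 1.60)
  expect_equal(effectiveIndex(0, mat), 1.33)
  expect_equal(effectiveIndex(1, mat), 1.60)
  expect_equal(effectiveIndex(0.5, mat), 1.465)
  th <- runif(20)
  n <- effectiveIndex(th, mat)
  expect_true(all(n >= 1.33 & n <= 1.60))
  expect_equal(n, 1.33 + th * 0.27)
  expect_error(effectiveIndex(1.2, mat), "\\[0, 1\\]")
})

test_that("refractometric shift is S * delta_n and zero for Wood-anomaly modes", {
  spp <- oneMode(S = 500)
  expect_equal(refractometricShift(spp, 0.01), 5)
  expect_equal(refractometricShift(oneMode(S = 0), 0.3), 0)
  expect_equal(refractometricShift(spp, 0), 0)
  wa <- oneMode(S = 500, kind = "WA")
  expect_equal(refractometricShift(wa, 0.05), 0)
  expect_error(refractometricShift(spp, -0.1), ">= 0")
})

test_that("Beer-Lambert attenuation follows A = eps*c*l", {
  expect_equal(absorbanceAttenuation(bindingState(x = 0)), 1)
  # theta_abs = 0.5 at K*x = gamma; eps = 2, c_max = 1, l = 1 -> A = 1
  b <- bindingState(K = 1, x = 1, molar_absorptivity = 2, path_length = 1,
                    concentration_scale = 1, absorption_saturation = 1)
  expect_equal(absorbanceAttenuation(b), 0.1)
  # doubling the absorbing concentration doubles A (halves log-fraction)
  b1 <- bindingState(K = 1, x = 1, molar_absorptivity = 0.4,
                     concentration_scale = 1, absorption_saturation = 1)
  b2 <- bindingState(K = 1, x = 1, molar_absorptivity = 0.4,
                     concentration_scale = 2, absorption_saturation = 1)
  expect_equal(log10(absorbanceAttenuation(b2)),
               2 * log10(absorbanceAttenuation(b1)))
})

test_that("spectrum synthesis and binding response compose correctly", {
  grid <- defaultGrid()
  flat <- synthesizeSpectrum(defaultModes()[0, ], grid, 0.9)
  expect_true(all(flat$reflectance == 0.9))
  one <- synthesizeSpectrum(oneMode(center = 700), grid, 0.95)
  expect_equal(one$reflectance[grid == 700], 0.95 - 0.45)
  # four-mode synthesis/detection round trip within one grid step
  tr <- detectModeTroughs(synthesizeSpectrum(defaultModes(), grid))
  expect_true(all(!tr$flagged))
  expect_true(all(abs(tr$lambda_res - c(580, 665, 680, 728)) <= 0.5))
  expect_error(synthesizeSpectrum(rbind(oneMode(), oneMode()), grid),
               "duplicated")
})

test_that("applyBinding shifts, attenuates and broadens SPP modes only", {
  mat <- materialModel()
  m0 <- defaultModes()
  expect_equal(applyBinding(m0, bindingState(x = 0), mat), m0)
  # hand composition: K=1, x=1 -> theta 0.5 -> delta_n 0.135 -> 13.5 nm at S=100
  m1 <- applyBinding(oneMode(S = 100), bindingState(K = 1, x = 1), mat)
  expect_equal(m1$center_wavelength_nm, 700 + 13.5)
  expect_equal(m1$linewidth_nm, 14 * 1.1)   # beta = 0.2, theta = 0.5
  # Wood anomaly untouched
  wa <- applyBinding(defaultModes(), bindingState(x = 5), mat)
  expect_equal(wa$center_wavelength_nm[2], 665)
  expect_equal(wa$depth[2], defaultModes()$depth[2])
  # Langmuir saturation plateau
  far <- applyBinding(oneMode(S = 100), bindingState(K = 1, x = 1e9), mat)
  expect_equal(far$center_wavelength_nm, 700 + 100 * 0.27, tolerance = 1e-5)
})

test_that("seeded noise is reproducible and calibrated", {
  sp <- synthesizeSpectrum(defaultModes(), defaultGrid())
  clean <- noiseModel(0, 0, 0, 0, seed = 1)
  expect_equal(addNoise(sp, clean), sp)
  nz <- noiseModel(0.01, 0.003, 0.2, 0.01, seed = 42)
  expect_equal(addNoise(sp, nz), addNoise(sp, nz))
  expect_false(isTRUE(all.equal(addNoise(sp, nz),
                                addNoise(sp, noiseModel(0.01, 0.003, 0.2, 0.01,
                                                        seed = 43)))))
  # additive noise s.d. calibration on a long flat spectrum
  big <- data.frame(wavelength_nm = seq_len(10000), reflectance = rep(0.5, 10000))
  noisy <- addNoise(big, noiseModel(0.005, 0, 0, 0, seed = 7))
  expect_lt(abs(sd(noisy$reflectance - 0.5) - 0.005), 0.05 * 0.005)
})

test_that("wavelength-shift and intensity responses cross over once", {
  sw <- modeResponseSweep()
  r_lambda <- sw$delta_lambda_nm / max(sw$delta_lambda_nm)
  r_refl <- sw$delta_R_fixed / max(sw$delta_R_fixed)
  d <- r_lambda - r_refl
  d <- d[abs(d) > 1e-12]
  expect_equal(sum(diff(sign(d)) != 0), 1)   # exactly one sign change
  expect_gt(d[1], 0)                          # shift dominates at low x
  # the trough-minimum (spectroscopic) response keeps growing past the
  # saturation of the wavelength response
  rel_growth <- function(v) (v[length(v)] - v[length(v) - 8]) / v[length(v)]
  expect_gt(rel_growth(sw$delta_R_min), rel_growth(sw$delta_lambda_nm))
})

test_that("the Langmuir constant is recoverable from shift curves", {
  K_true <- 0.8
  x <- 10^seq(-1.5, 1.5, length.out = 12) / K_true
  shifts <- 16.2 * langmuirCoverage(K_true, x)
  fit <- fitLangmuirK(x, shifts)
  expect_equal(fit$K, K_true, tolerance = 1e-6)
  expect_equal(fit$delta_lambda_max, 16.2, tolerance = 1e-6)
})
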