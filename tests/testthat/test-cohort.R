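test_that("cohort sampling reproduces the designed class structure", {
  d <- cohortDesign(seed = 3)
  expect_equal(sum(d@class_counts), 1800L)
  small <- scaleDesign(d, 90)
  cohort <- sampleCohort(small)
  expect_equal(nrow(cohort), 90L)
  expect_equal(unname(table(cohort$class_label)[names(small@class_counts)]),
               unname(table(rep(names(small@class_counts),
                                small@class_counts))[names(small@class_counts)]))
  # identical seed, identical cohort; different seed differs
  expect_identical(cohort, sampleCohort(small))
  small2 <- small; small2@seed <- 4L
  expect_false(identical(cohort, sampleCohort(small2)))
})

test_that("marker concentrations encode PDAC elevation", {
  d <- cohortDesign(seed = 5)   # full 600/900/100/100/100 design
  cohort <- sampleCohort(d)
  for (mk in c("GPC1", "EphA2")) {
    v <- cohort[[paste0("conc_", mk)]]
    expect_gt(median(v[cohort$class_label == "PDAC"]),
              median(v[cohort$class_label == "HC"]))
  }
  # GPC1 stays near-baseline in the non-PDAC cancer classes, EphA2 is
  # mildly elevated there (specificity anchor vs sensitivity amplifier)
  med <- function(mk, cl) median(cohort[[paste0("conc_", mk)]][cohort$class_label == cl])
  expect_lt(med("GPC1", "CCA") / med("GPC1", "PDAC"), 0.3)
  expect_gt(med("EphA2", "CCA"), med("EphA2", "HC"))
})

test_that("zeroing the effect scale collapses every class onto the control level", {
  d <- cohortDesign(effect_scale = 0, seed = 9)
  med <- plasmoKAN:::scaledMedians(d)
  for (r in rownames(med)) expect_equal(unname(med[r, ]), unname(med["HC", ]))
})

test_that("dataset generation yields the exact record bookkeeping", {
  d <- scaleDesign(cohortDesign(seed = 21), 10)
  cohort <- sampleCohort(d)
  se <- generateDataset(cohort, d)
  expect_s4_class(se, "SpectrumExperiment")
  expect_equal(ncol(se), 10 * 2 * 5)   # subjects x markers x replicates
  d1 <- cohortDesign(class_counts = c(PDAC = 5L, HC = 5L), markers = "GPC1",
                     replicates_per_marker = 1L, seed = 21)
  se1 <- generateDataset(sampleCohort(d1), d1)
  expect_equal(ncol(se1), 10L)
  # grids shared, reflectance in range, labels constant within subject
  cd <- as.data.frame(recordData(se))
  expect_true(all(tapply(cd$label, cd$subject_id, function(v) length(unique(v))) == 1))
  expect_true(all(preSpectra(se) >= 0 & preSpectra(se) <= 1))
})

test_that("partitions are subject-exclusive and apportioned exactly", {
  d <- scaleDesign(cohortDesign(seed = 33), 101)  # odd total: rounding exercised
  cohort <- sampleCohort(d)
  tab <- table(cohort$partition)
  want <- 101 * d@partition_fractions
  expect_true(all(abs(tab[names(want)] - want) <= 1))
  se <- generateDataset(cohort, d)
  cd <- as.data.frame(recordData(se))
  per_subj <- tapply(cd$partition, cd$subject_id, function(v) length(unique(v)))
  expect_true(all(per_subj == 1))
})

test_that("dataset generation is deterministic in (design, seed)", {
  d <- scaleDesign(cohortDesign(seed = 8), 12)
  cohort <- sampleCohort(d)
  se1 <- generateDataset(cohort, d)
  se2 <- generateDataset(cohort, d)
  expect_identical(preSpectra(se1), preSpectra(se2))
  expect_identical(postSpectra(se1), postSpectra(se2))
  expect_identical(as.data.frame(recordData(se1)), as.data.frame(recordData(se2)))
})

test_that("binding signal appears in the post spectrum, not the pre spectrum", {
  d <- cohortDesign(class_counts = c(PDAC = 6L), markers = "GPC1",
                    replicates_per_marker = 1L, seed = 2)
  cohort <- sampleCohort(d)
  cohort$conc_GPC1 <- 5   # strong, saturating concentration
  se <- generateDataset(cohort, d, noise = noiseModel(0, 0, 0, 0, 0, 0))
  tr_pre <- detectModeTroughs(data.frame(wavelength_nm = wavelengthGrid(se),
                                         reflectance = preSpectra(se)[, 1]))
  tr_post <- detectModeTroughs(data.frame(wavelength_nm = wavelengthGrid(se),
                                          reflectance = postSpectra(se)[, 1]))
  expect_equal(tr_pre$lambda_res[4], 728, tolerance = 0.3)
  expect_gt(tr_post$lambda_res[4] - tr_pre$lambda_res[4], 5)  # clear P4 shift
  expect_equal(tr_post$lambda_res[2], tr_pre$lambda_res[2], tolerance = 0.3)  # WA pinned
})
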