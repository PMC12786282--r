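# Shared fixtures: all synthetic, generated in code at test time.

# a small cohort/dataset used by several files; cached per session
tinyDataset <- local({
  cache <- NULL
  function(n_subjects = 40, seed = 101, markers = c("GPC1", "EphA2"),
           noise = noiseModel()) {
    key <- paste(n_subjects, seed, paste(markers, collapse = "+"),
                 noise@sigma_reflectance)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$se)
    d <- scaleDesign(cohortDesign(markers = markers, seed = seed), n_subjects)
    se <- generateDataset(sampleCohort(d), d, noise = noise)
    cache <<- list(key = key, se = se)
    se
  }
})

# single-mode table helper
oneMode <- function(center = 700, width = 14, depth = 0.45, S = 60,
                    kind = "SPP", label = "P4") {
  data.frame(label = label, kind = kind, center_wavelength_nm = center,
             linewidth_nm = width, depth = depth,
             bulk_sensitivity_nm_per_RIU = S, bulk_shift_nm_per_RIU = 500,
             interface = "medium", stringsAsFactors = FALSE)
}

# brute-force pairwise AUC oracle (ties counted 1/2)
aucPairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
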