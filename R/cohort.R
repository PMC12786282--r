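## Synthetic case-control cohorts and paired pre/post spectrum datasets with
## the statistical structure of the study: class-dependent serum marker
## levels, five replicate spectra per subject and marker, subject-level
## partitioning, seeded measurement noise.

defaultConcMedian <- function() {
  ## log-normal medians per class (rows) and marker (columns), in units of
  ## 1/K. GPC1 is near-exclusive to PDAC (the specificity anchor); EphA2 is
  ## strongly elevated in PDAC and mildly elevated in other cancers (the
  ## sensitivity amplifier).
  m <- rbind(
    PDAC         = c(GPC1 = 2.00, EphA2 = 2.50),
    HC           = c(GPC1 = 0.15, EphA2 = 0.20),
    pancreatitis = c(GPC1 = 0.18, EphA2 = 0.30),
    CCA          = c(GPC1 = 0.22, EphA2 = 0.50),
    HCC          = c(GPC1 = 0.22, EphA2 = 0.50),
    breast       = c(GPC1 = 0.20, EphA2 = 1.20),
    colorectal   = c(GPC1 = 0.20, EphA2 = 1.20))
  m
}

defaultConcSdlog <- function() {
  m <- defaultConcMedian()
  m[] <- 0.7
  m["PDAC", ] <- 0.8
  m
}

#' Construct a cohort design
#'
#' Defaults reproduce the study structure: 600 PDAC subjects and 1200
#' controls (900 healthy, 100 pancreatitis, 100 CCA, 100 HCC), two markers
#' (GPC1, EphA2) with five replicate spectra each (10 spectra per subject),
#' and a 0.6/0.2/0.2 train/test/external subject-level split. Optional
#' EphA2-positive other-cancer classes (breast, colorectal) can be added via
#' `class_counts`.
#'
#' @param class_counts named vector of subjects per class
#' @param conc_median,conc_sdlog log-normal concentration parameters per
#'   class (rows) and marker (columns); defaults are the package's calibrated
#'   study regime (see the methods vignette)
#' @param markers marker names
#' @param replicates_per_marker replicate spectra per subject and marker
#' @param partition_fractions named train/test/external fractions
#' @param replicate_jitter_sdlog replicate-level concentration jitter (log s.d.)
#' @param coupling_sdlog per-subject log-s.d. of the refractometric and
#'   absorptive channel couplings (vesicle optical heterogeneity)
#' @param effect_scale scaling of all class separations from the HC level
#'   (1 = default regime, 0 = null cohort)
#' @param seed integer seed
#' @return a [CohortDesign-class]
#' @examples
#' cohortDesign()                      # the full study design
#' scaleDesign(cohortDesign(), 150)   # a desk-scale version
#' @export
cohortDesign <- function(class_counts = c(PDAC = 600L, HC = 900L,
                                          pancreatitis = 100L, CCA = 100L,
                                          HCC = 100L),
                         conc_median = NULL, conc_sdlog = NULL,
                         markers = c("GPC1", "EphA2"),
                         replicates_per_marker = 5L,
                         partition_fractions = c(train = 0.6, test = 0.2,
                                                 external = 0.2),
                         replicate_jitter_sdlog = 0.05,
                         coupling_sdlog = 0.8,
                         effect_scale = 1, seed = 1L) {
  cls <- names(class_counts)
  if (is.null(conc_median)) {
    full <- defaultConcMedian()
    unknown <- setdiff(cls, rownames(full))
    if (length(unknown))
      stop("no default concentration distribution for class(es): ",
           paste(unknown, collapse = ", "), "; supply conc_median/conc_sdlog")
    conc_median <- full[cls, markers, drop = FALSE]
  }
  if (is.null(conc_sdlog)) conc_sdlog <- defaultConcSdlog()[cls, markers, drop = FALSE]
  new("CohortDesign",
      class_counts = setNames(as.integer(class_counts), cls),
      conc_median = conc_median, conc_sdlog = conc_sdlog,
      markers = markers,
      replicates_per_marker = as.integer(replicates_per_marker),
      partition_fractions = partition_fractions,
      replicate_jitter_sdlog = replicate_jitter_sdlog,
      coupling_sdlog = coupling_sdlog,
      effect_scale = effect_scale, seed = as.integer(seed))
}

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:",
      paste(sprintf("%s=%d", names(object@class_counts), object@class_counts),
            collapse = " "), "\n")
  cat(sprintf("  markers: %s | replicates/marker: %d | effect_scale: %g | seed: %d\n",
              paste(object@markers, collapse = ", "),
              object@replicates_per_marker, object@effect_scale, object@seed))
  cat("  partitions:",
      paste(sprintf("%s=%.2f", names(object@partition_fractions),
                    object@partition_fractions), collapse = " "), "\n")
})

## class-stratified partition assignment: per-class quotas rounded by
## largest fractional part under the global largest-remainder totals, so the
## overall split is exact to one subject and every class is spread across
## partitions. Assumes the RNG is already seeded by the caller.
stratifiedPartition <- function(cls, fractions) {
  n <- length(cls)
  parts <- names(fractions)
  targets <- apportion(n, fractions)
  classes <- unique(cls)
  q <- outer(as.numeric(table(factor(cls, classes))), fractions)
  base <- floor(q)
  cap <- targets - colSums(base)
  rem <- as.numeric(table(factor(cls, classes))) - rowSums(base)
  frac <- q - base
  ord <- order(frac, decreasing = TRUE)
  for (cell in ord) {
    ci <- (cell - 1) %% nrow(q) + 1
    pi <- (cell - 1) %/% nrow(q) + 1
    take <- min(rem[ci], cap[pi])
    if (take > 0) { base[ci, pi] <- base[ci, pi] + take
      rem[ci] <- rem[ci] - take; cap[pi] <- cap[pi] - take }
  }
  partition <- character(n)
  for (ci in seq_along(classes)) {
    idx <- which(cls == classes[ci])
    idx <- idx[sample.int(length(idx))]
    partition[idx] <- rep(parts, times = base[ci, ])
  }
  partition
}

## largest-remainder apportionment of n into parts proportional to w
apportion <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Scale a cohort design to a smaller total size
#'
#' Keeps class proportions (largest-remainder apportionment) and all other
#' design parameters.
#'
#' @param design a [CohortDesign-class]
#' @param n_subjects target total subject count
#' @return a rescaled [CohortDesign-class]
#' @export
scaleDesign <- function(design, n_subjects) {
  counts <- apportion(n_subjects, as.numeric(design@class_counts))
  design@class_counts <- setNames(counts, names(design@class_counts))
  validObject(design)
  design
}

## class/marker medians after applying the effect-scale dial (separations
## from the HC row are scaled on the log axis; without an HC row the
## geometric mean across classes is the reference)
scaledMedians <- function(design) {
  m <- log(design@conc_median)
  ref <- if ("HC" %in% rownames(m)) m["HC", , drop = TRUE]
         else colMeans(m)
  for (j in seq_len(ncol(m)))
    m[, j] <- ref[j] + design@effect_scale * (m[, j] - ref[j])
  exp(m)
}

#' Sample a synthetic cohort
#'
#' Draws one subject table from the design: per-class subject counts exactly
#' as designed, with per-marker serum concentrations drawn from the
#' class/marker log-normal distributions, and a subject-level partition
#' assignment (no subject's records ever span two partitions).
#'
#' @param design a [CohortDesign-class]
#' @return data.frame with subject_id, class_label, label (1 = PDAC),
#'   partition, and one `conc_<marker>` column per marker
#' @examples
#' cohort <- sampleCohort(scaleDesign(cohortDesign(), 30))
#' table(cohort$class_label)
#' @export
sampleCohort <- function(design) {
  validObject(design)
  n <- sum(design@class_counts)
  cls <- rep(names(design@class_counts), times = design@class_counts)
  med <- scaledMedians(design)
  withSeed(deriveSeed(design@seed, "cohort"), {
    conc <- sapply(design@markers, function(mk) {
      rlnorm(n, meanlog = log(med[cls, mk]), sdlog = design@conc_sdlog[cls, mk])
    })
    conc <- matrix(conc, nrow = n,
                   dimnames = list(NULL, paste0("conc_", design@markers)))
    re_coupling <- rlnorm(n, meanlog = 0, sdlog = design@coupling_sdlog)
    se_coupling <- rlnorm(n, meanlog = 0, sdlog = design@coupling_sdlog)
    partition <- stratifiedPartition(cls, design@partition_fractions)
    df <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                     class_label = cls,
                     label = as.integer(cls == "PDAC"),
                     partition = partition,
                     re_coupling = re_coupling,
                     se_coupling = se_coupling,
                     stringsAsFactors = FALSE)
    cbind(df, conc)
  })
}

#' Generate the paired pre/post spectrum dataset for a cohort
#'
#' For every subject, marker and replicate: a pre-detection spectrum of the
#' unbound chip and a post-detection spectrum produced by [applyBinding()]
#' at the subject's marker concentration (with replicate-level multiplicative
#' log-normal jitter), both with independent seeded measurement noise.
#'
#' @param cohort subject table from [sampleCohort()]
#' @param design the [CohortDesign-class] used to sample it
#' @param modes mode table (default [defaultModes()])
#' @param material a [MaterialModel-class]
#' @param binding template [BindingState-class] (its `x` is replaced per record)
#' @param noise a [NoiseModel-class] (its seed is ignored; the noise stream
#'   derives from the design seed)
#' @param grid wavelength grid
#' @param baseline_reflectance baseline level
#' @param beta linewidth loading factor
#' @return a [SpectrumExperiment-class] with one column per spectrum record
#' @examples
#' d <- scaleDesign(cohortDesign(), 10)
#' se <- generateDataset(sampleCohort(d), d)
#' @export
generateDataset <- function(cohort, design, modes = defaultModes(),
                            material = materialModel(),
                            binding = bindingState(), noise = noiseModel(),
                            grid = defaultGrid(), baseline_reflectance = 0.95,
                            beta = 0.2) {
  validateModes(modes)
  n_sub <- nrow(cohort)
  reps <- design@replicates_per_marker
  markers <- design@markers
  n_rec <- n_sub * length(markers) * reps

  manifest <- data.frame(
    record_id = sprintf("R%06d", seq_len(n_rec)),
    subject_id = rep(cohort$subject_id, each = length(markers) * reps),
    class_label = rep(cohort$class_label, each = length(markers) * reps),
    marker = rep(rep(markers, each = reps), times = n_sub),
    replicate = rep(seq_len(reps), times = n_sub * length(markers)),
    partition = rep(cohort$partition, each = length(markers) * reps),
    label = rep(cohort$label, each = length(markers) * reps),
    stringsAsFactors = FALSE)

  subj_conc <- as.matrix(cohort[, paste0("conc_", markers), drop = FALSE])
  rec_sub <- rep(seq_len(n_sub), each = length(markers) * reps)
  re_cpl <- if ("re_coupling" %in% colnames(cohort))
    cohort$re_coupling[rec_sub] else rep(1, n_rec)
  se_cpl <- if ("se_coupling" %in% colnames(cohort))
    cohort$se_coupling[rec_sub] else rep(1, n_rec)
  x_base <- subj_conc[cbind(rep(seq_len(n_sub), each = length(markers) * reps),
                            rep(rep(seq_along(markers), each = reps),
                                times = n_sub))]

  G <- length(grid)
  withSeed(deriveSeed(design@seed, "spectra"), {
    jitter <- rlnorm(n_rec, meanlog = 0, sdlog = design@replicate_jitter_sdlog)
    x_rec <- x_base * jitter
    manifest$concentration <- x_rec

    theta <- langmuirCoverage(binding@K, x_rec)
    ## per-subject channel couplings modulate the refractive-index contrast
    ## and the absorptivity of the bound vesicles (biological heterogeneity)
    delta_n <- (effectiveIndex(theta, material) - material@n_medium) * re_cpl
    load <- langmuirCoverage(binding@K / binding@absorption_saturation, x_rec)
    atten <- 10^(-binding@molar_absorptivity * se_cpl *
                   binding@concentration_scale * load * binding@path_length)

    ## per-record instrument state: rigid wavelength-calibration shift and
    ## multiplicative gain, drawn independently for pre and post acquisitions
    dl_pre <- rnorm(n_rec, sd = noise@lambda_jitter_nm)
    dl_post <- rnorm(n_rec, sd = noise@lambda_jitter_nm)
    gain_pre <- 1 + rnorm(n_rec, sd = noise@gain_sd)
    gain_post <- 1 + rnorm(n_rec, sd = noise@gain_sd)
    ## record-level matrix nuisances on the post acquisition: residual bulk
    ## refractive-index change (moves all bulk-sensitive modes) and
    ## non-specific adsorption scaling every dip depth
    dn_bulk <- rnorm(n_rec, sd = noise@bulk_index_sd)
    depth_scale <- exp(rnorm(n_rec, sd = noise@depth_scale_sd))

    dipSum <- function(centers_by_mode, depths_by_mode, widths_by_mode) {
      out <- matrix(0, G, n_rec)
      base_dev <- matrix(grid, G, n_rec)
      for (m in seq_along(centers_by_mode)) {
        dev <- sweep(base_dev, 2, centers_by_mode[[m]], "-")
        dev <- sweep(dev, 2, widths_by_mode[[m]] / 2, "/")
        out <- out + sweep(1 / (1 + dev^2), 2, depths_by_mode[[m]], "*")
      }
      out
    }
    cpre <- cpost <- dpre <- dpost <- wpre <- wpost <- vector("list", nrow(modes))
    for (m in seq_len(nrow(modes))) {
      cpre[[m]] <- rep(modes$center_wavelength_nm[m], n_rec) + dl_pre
      dpre[[m]] <- rep(modes$depth[m], n_rec)
      wpre[[m]] <- rep(modes$linewidth_nm[m], n_rec)
      bulk <- modes$bulk_shift_nm_per_RIU[m] * dn_bulk
      if (modes$kind[m] == "WA") {
        cpost[[m]] <- rep(modes$center_wavelength_nm[m], n_rec) + dl_post + bulk
        dpost[[m]] <- dpre[[m]] * depth_scale
        wpost[[m]] <- wpre[[m]]
      } else {
        cpost[[m]] <- modes$center_wavelength_nm[m] +
          modes$bulk_sensitivity_nm_per_RIU[m] * delta_n + dl_post + bulk
        dpost[[m]] <- modes$depth[m] * atten * depth_scale
        wpost[[m]] <- modes$linewidth_nm[m] * (1 + beta * theta)
      }
    }
    pre <- sweep(baseline_reflectance - dipSum(cpre, dpre, wpre), 2, gain_pre, "*")
    post <- sweep(baseline_reflectance - dipSum(cpost, dpost, wpost), 2, gain_post, "*")
    if (noise@sigma_reflectance > 0 || noise@baseline_tilt > 0) {
      frac <- if (G > 1) 2 * ((seq_len(G) - 1) / (G - 1) - 0.5) else 0
      pre <- pre + matrix(rnorm(G * n_rec, sd = noise@sigma_reflectance), G) +
        outer(frac, runif(n_rec, -noise@baseline_tilt, noise@baseline_tilt))
      post <- post + matrix(rnorm(G * n_rec, sd = noise@sigma_reflectance), G) +
        outer(frac, runif(n_rec, -noise@baseline_tilt, noise@baseline_tilt))
    }
    pre <- clip01(pre); post <- clip01(post)
    colnames(pre) <- colnames(post) <- manifest$record_id

    new("SpectrumExperiment", SummarizedExperiment::SummarizedExperiment(
      assays = list(pre = pre, post = post),
      rowData = S4Vectors::DataFrame(wavelength_nm = grid),
      colData = S4Vectors::DataFrame(manifest, row.names = manifest$record_id)))
  })
}
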