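#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm rlnorm runif median sd quantile setNames predict
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

#' Chip geometry of the periodic gold nanohole array
#'
#' Holds the lattice parameters of the metasurface: center-to-center hole
#' spacing (the grating period P), hole diameter and hole depth, all in nm.
#'
#' @slot period_nm center-to-center hole spacing P (nm)
#' @slot hole_diameter_nm hole diameter (nm), strictly smaller than the period
#' @slot depth_nm hole depth (nm)
#' @export
setClass("ChipGeometry",
  representation(period_nm = "numeric", hole_diameter_nm = "numeric",
                 depth_nm = "numeric"),
  prototype(period_nm = 500, hole_diameter_nm = 200, depth_nm = 200))

setValidity("ChipGeometry", function(object) {
  msg <- character()
  for (s in c("period_nm", "hole_diameter_nm", "depth_nm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  if (length(msg) == 0L && object@hole_diameter_nm >= object@period_nm)
    msg <- c(msg, "hole_diameter_nm must be smaller than period_nm")
  if (length(msg)) msg else TRUE
})

#' Optical material model of the metal/dielectric/analyte system
#'
#' The metal permittivity may be a single (negative real part) constant or a
#' function of wavelength in nm returning the (possibly complex) permittivity,
#' in which case resonance conditions are solved by damped fixed-point
#' iteration. The ambient dielectric enters through its refractive index
#' (eps_d = n_medium^2); bound analyte particles through n_analyte.
#'
#' @slot eps_metal numeric constant or function(wavelength_nm) -> permittivity
#' @slot n_medium refractive index of the ambient medium (water: 1.33)
#' @slot n_analyte refractive index of the bound particles (default 1.60)
#' @export
setClass("MaterialModel",
  representation(eps_metal = "ANY", n_medium = "numeric",
                 n_analyte = "numeric"),
  prototype(eps_metal = -20, n_medium = 1.33, n_analyte = 1.60))

setValidity("MaterialModel", function(object) {
  msg <- character()
  em <- object@eps_metal
  if (is.numeric(em) || is.complex(em)) {
    if (length(em) != 1L || Re(em) >= 0)
      msg <- c(msg, "constant eps_metal must have negative real part")
  } else if (!is.function(em)) {
    msg <- c(msg, "eps_metal must be a number or a function of wavelength")
  }
  if (length(object@n_medium) != 1L || object@n_medium <= 0)
    msg <- c(msg, "n_medium must be a single positive number")
  if (length(object@n_analyte) != 1L || object@n_analyte < object@n_medium)
    msg <- c(msg, "n_analyte must be >= n_medium")
  if (length(msg)) msg else TRUE
})

#' Langmuir binding state of the sensor surface
#'
#' Couples the Langmuir adsorption parameters (equilibrium constant K,
#' analyte concentration x) to the Beer-Lambert intensity channel
#' (molar absorptivity, fixed near-field path length, and the map from
#' fractional load to the absorbing concentration). The absorbance channel
#' carries its own, slower Langmuir scale K/absorption_saturation,
#' representing accumulated particle load in the near-field volume rather
#' than first-monolayer coverage.
#'
#' @slot K Langmuir equilibrium constant (reciprocal concentration units)
#' @slot x analyte concentration (units of 1/K)
#' @slot molar_absorptivity absorptivity of the bound layer (per unit c*l)
#' @slot path_length fixed near-field optical path length
#' @slot concentration_scale maximal absorbing concentration (c = scale * load)
#' @slot absorption_saturation ratio by which the absorbance channel
#'   saturates later than surface coverage (gamma >= 1)
#' @export
setClass("BindingState",
  representation(K = "numeric", x = "numeric", molar_absorptivity = "numeric",
                 path_length = "numeric", concentration_scale = "numeric",
                 absorption_saturation = "numeric"),
  prototype(K = 1, x = 0, molar_absorptivity = 0.35, path_length = 1,
            concentration_scale = 1, absorption_saturation = 5))

setValidity("BindingState", function(object) {
  msg <- character()
  for (s in c("K", "x", "molar_absorptivity", "path_length",
              "concentration_scale")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single non-negative number", s))
  }
  if (length(object@absorption_saturation) != 1L ||
      object@absorption_saturation < 1)
    msg <- c(msg, "absorption_saturation must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Measurement noise model for synthetic spectra
#'
#' Four spectrometer-like noise sources, fully determined by the seed
#' (identical seed, identical realization): additive Gaussian reflectance
#' noise, a linear baseline tilt across the band, a rigid
#' wavelength-calibration jitter of the whole spectrum (which corrupts
#' wavelength readouts but not intensities), and a multiplicative intensity
#' gain fluctuation (which corrupts intensity readouts but not wavelengths).
#'
#' @slot sigma_reflectance additive Gaussian standard deviation
#' @slot baseline_tilt maximal linear drift over the band (peak-to-peak/2)
#' @slot lambda_jitter_nm s.d. of the rigid wavelength calibration shift (nm)
#' @slot gain_sd s.d. of the multiplicative intensity gain (relative)
#' @slot bulk_index_sd s.d. of the residual bulk refractive-index change of
#'   the post-detection medium (RIU); moves every bulk-sensitive mode via its
#'   bulk_shift_nm_per_RIU and so corrupts wavelength readouts
#' @slot depth_scale_sd log-s.d. of the record-level non-specific depth
#'   scaling of the post-detection dips; corrupts intensity readouts
#' @slot seed integer seed for the realization
#' @export
setClass("NoiseModel",
  representation(sigma_reflectance = "numeric", baseline_tilt = "numeric",
                 lambda_jitter_nm = "numeric", gain_sd = "numeric",
                 bulk_index_sd = "numeric", depth_scale_sd = "numeric",
                 seed = "integer"),
  prototype(sigma_reflectance = 0.004, baseline_tilt = 0.002,
            lambda_jitter_nm = 0.15, gain_sd = 0.01,
            bulk_index_sd = 0.002, depth_scale_sd = 0.06, seed = 1L))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@sigma_reflectance < 0) msg <- c(msg, "sigma_reflectance must be >= 0")
  if (object@baseline_tilt < 0) msg <- c(msg, "baseline_tilt must be >= 0")
  if (object@lambda_jitter_nm < 0) msg <- c(msg, "lambda_jitter_nm must be >= 0")
  if (object@gain_sd < 0) msg <- c(msg, "gain_sd must be >= 0")
  if (object@bulk_index_sd < 0) msg <- c(msg, "bulk_index_sd must be >= 0")
  if (object@depth_scale_sd < 0) msg <- c(msg, "depth_scale_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Design of a synthetic case-control cohort
#'
#' Class counts, per-class/per-marker log-normal serum concentration
#' distributions, replicate structure and subject-level partition fractions.
#' `effect_scale` scales all log-median separations from the reference
#' (healthy-control) level: 1 is the default study regime, 0 a null cohort in
#' which every class shares the control distribution.
#'
#' @slot class_counts named integer vector (e.g. PDAC, HC, pancreatitis, CCA, HCC)
#' @slot conc_median classes x markers matrix of log-normal medians
#' @slot conc_sdlog classes x markers matrix of log-sd values
#' @slot markers marker names (columns of the matrices)
#' @slot replicates_per_marker spectra per subject and marker
#' @slot partition_fractions named fractions (train/test/external) summing to 1
#' @slot replicate_jitter_sdlog log-normal s.d. of replicate concentration jitter
#' @slot coupling_sdlog log-normal s.d. of the per-subject optical channel
#'   couplings (vesicle refractive-index contrast for the wavelength channel,
#'   vesicle absorptivity for the intensity channel), drawn independently
#' @slot effect_scale scaling of class separations (0 = null cohort)
#' @slot seed integer seed
#' @export
setClass("CohortDesign",
  representation(class_counts = "integer", conc_median = "matrix",
                 conc_sdlog = "matrix", markers = "character",
                 replicates_per_marker = "integer",
                 partition_fractions = "numeric",
                 replicate_jitter_sdlog = "numeric",
                 coupling_sdlog = "numeric",
                 effect_scale = "numeric", seed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (length(object@class_counts) == 0L || is.null(names(object@class_counts)))
    msg <- c(msg, "class_counts must be a named integer vector")
  if (any(object@class_counts < 0L)) msg <- c(msg, "class counts must be >= 0")
  if (sum(object@class_counts) == 0L) msg <- c(msg, "cohort is empty")
  if (!identical(rownames(object@conc_median), names(object@class_counts)) ||
      !identical(colnames(object@conc_median), object@markers))
    msg <- c(msg, "conc_median must have classes as rows and markers as columns")
  if (!identical(dim(object@conc_sdlog), dim(object@conc_median)))
    msg <- c(msg, "conc_sdlog must match conc_median in shape")
  if (any(object@conc_median <= 0)) msg <- c(msg, "concentration medians must be positive")
  if (abs(sum(object@partition_fractions) - 1) > 1e-8)
    msg <- c(msg, "partition_fractions must sum to 1")
  if (is.null(names(object@partition_fractions)))
    msg <- c(msg, "partition_fractions must be named")
  if (object@replicates_per_marker < 1L)
    msg <- c(msg, "replicates_per_marker must be >= 1")
  if (object@effect_scale < 0) msg <- c(msg, "effect_scale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Paired pre-/post-detection spectrum dataset
#'
#' A SummarizedExperiment subclass: rows are wavelengths (rowData column
#' `wavelength_nm`, strictly ascending), columns are spectrum records, and the
#' two assays `pre` and `post` hold reflectance in [0,1] on the shared grid.
#' colData carries the record manifest (subject_id, class_label, marker,
#' replicate, partition, label).
#'
#' @export
setClass("SpectrumExperiment", contains = "SummarizedExperiment")

setValidity("SpectrumExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("pre", "post") %in% an))
    msg <- c(msg, "assays 'pre' and 'post' are required")
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl)) {
    msg <- c(msg, "rowData must contain 'wavelength_nm'")
  } else if (nrow(object) > 1L && any(diff(wl) <= 0)) {
    msg <- c(msg, "wavelength grid must be strictly ascending")
  }
  for (a in intersect(c("pre", "post"), an)) {
    m <- SummarizedExperiment::assay(object, a)
    if (anyNA(m)) msg <- c(msg, sprintf("assay '%s' contains missing values", a))
    else if (length(m) && (min(m) < -1e-9 || max(m) > 1 + 1e-9))
      msg <- c(msg, sprintf("assay '%s' has reflectance outside [0,1]", a))
  }
  need <- c("subject_id", "class_label", "marker", "replicate",
            "partition", "label")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData misses:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Kolmogorov-Arnold network classifier
#'
#' Container for a trained (or freshly initialized) classifier: either a
#' stack of KAN layers over a feature table (`type = "feature"`), a matched
#' multilayer-perceptron reference (`type = "mlp"`), or the full-spectrum
#' model (`type = "fullspectrum"`: patch embedding, positional encoding,
#' multi-head self-attention, KAN head).
#'
#' @slot type one of "feature", "mlp", "fullspectrum"
#' @slot params named list of parameter arrays
#' @slot config architecture and spline configuration
#' @slot norm frozen training-set normalization statistics
#' @slot history training history (per-epoch losses, validation AUC/accuracy)
#' @slot trained logical
#' @export
setClass("KANClassifier",
  representation(type = "character", params = "list", config = "list",
                 norm = "list", history = "list", trained = "logical"),
  prototype(type = "feature", params = list(), config = list(),
            norm = list(), history = list(), trained = FALSE))

setValidity("KANClassifier", function(object) {
  if (!object@type %in% c("feature", "mlp", "fullspectrum"))
    "type must be 'feature', 'mlp' or 'fullspectrum'" else TRUE
})
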