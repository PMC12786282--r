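#' Construct a chip geometry
#'
#' Defaults correspond to the fabricated array: 200 nm diameter nanoholes in
#' 500 nm periodic spacing, 200 nm deep.
#'
#' @param period_nm center-to-center hole spacing (nm)
#' @param hole_diameter_nm hole diameter (nm)
#' @param depth_nm hole depth (nm)
#' @return a [ChipGeometry-class] object
#' @examples
#' chipGeometry()
#' @export
chipGeometry <- function(period_nm = 500, hole_diameter_nm = 200,
                         depth_nm = 200) {
  new("ChipGeometry", period_nm = period_nm,
      hole_diameter_nm = hole_diameter_nm, depth_nm = depth_nm)
}

#' Construct a material model
#'
#' @param eps_metal gold permittivity: a negative-real-part constant, or a
#'   function of wavelength (nm)
#' @param n_medium ambient refractive index (water 1.33)
#' @param n_analyte refractive index of bound particles (default 1.60)
#' @return a [MaterialModel-class] object
#' @examples
#' materialModel(n_medium = 1.33)
#' @export
materialModel <- function(eps_metal = -20, n_medium = 1.33, n_analyte = 1.60) {
  new("MaterialModel", eps_metal = eps_metal, n_medium = n_medium,
      n_analyte = n_analyte)
}

#' Construct a Langmuir binding state
#'
#' @param K Langmuir equilibrium constant
#' @param x analyte concentration (units of 1/K)
#' @param molar_absorptivity Beer-Lambert absorptivity
#' @param path_length fixed near-field path length
#' @param concentration_scale maximal absorbing concentration
#' @param absorption_saturation how much later the absorbance channel
#'   saturates than surface coverage (>= 1)
#' @return a [BindingState-class] object
#' @examples
#' bindingState(K = 1, x = 1)
#' @export
bindingState <- function(K = 1, x = 0, molar_absorptivity = 0.35,
                         path_length = 1, concentration_scale = 1,
                         absorption_saturation = 5) {
  new("BindingState", K = K, x = x, molar_absorptivity = molar_absorptivity,
      path_length = path_length, concentration_scale = concentration_scale,
      absorption_saturation = absorption_saturation)
}

#' Construct a measurement noise model
#'
#' @param sigma_reflectance additive Gaussian s.d. on reflectance
#' @param baseline_tilt maximal linear drift over the band
#' @param lambda_jitter_nm s.d. of the rigid wavelength calibration shift
#' @param gain_sd s.d. of the multiplicative intensity gain
#' @param bulk_index_sd s.d. of the residual bulk-index change after serum
#'   incubation (RIU), applied to the post spectrum
#' @param depth_scale_sd log-s.d. of non-specific depth scaling of the post
#'   spectrum dips
#' @param seed integer seed
#' @return a [NoiseModel-class] object
#' @examples
#' noiseModel(sigma_reflectance = 0.004, seed = 7)
#' @export
noiseModel <- function(sigma_reflectance = 0.004, baseline_tilt = 0.002,
                       lambda_jitter_nm = 0.15, gain_sd = 0.01,
                       bulk_index_sd = 0.002, depth_scale_sd = 0.06,
                       seed = 1L) {
  new("NoiseModel", sigma_reflectance = sigma_reflectance,
      baseline_tilt = baseline_tilt, lambda_jitter_nm = lambda_jitter_nm,
      gain_sd = gain_sd, bulk_index_sd = bulk_index_sd,
      depth_scale_sd = depth_scale_sd, seed = as.integer(seed))
}

setMethod("show", "ChipGeometry", function(object) {
  cat(sprintf("ChipGeometry: period %g nm, hole diameter %g nm, depth %g nm\n",
              object@period_nm, object@hole_diameter_nm, object@depth_nm))
})

setMethod("show", "MaterialModel", function(object) {
  em <- if (is.function(object@eps_metal)) "tabulated(function)" else
    format(object@eps_metal)
  cat(sprintf("MaterialModel: eps_metal = %s, n_medium = %g (eps_d = %g), n_analyte = %g\n",
              em, object@n_medium, object@n_medium^2, object@n_analyte))
})

setMethod("show", "BindingState", function(object) {
  cat(sprintf(
    "BindingState: K = %g, x = %g (coverage %.4f), eps = %g, l = %g, c_max = %g, gamma = %g\n",
    object@K, object@x, langmuirCoverage(object@K, object@x),
    object@molar_absorptivity, object@path_length,
    object@concentration_scale, object@absorption_saturation))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: sigma = %g, tilt = %g, lambda jitter = %g nm, gain sd = %g, seed = %d\n",
              object@sigma_reflectance, object@baseline_tilt,
              object@lambda_jitter_nm, object@gain_sd, object@seed))
})

setMethod("show", "SpectrumExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("SpectrumExperiment: %d wavelengths x %d records\n",
              nrow(object), ncol(object)))
  if (nrow(object))
    cat(sprintf("  band: %.1f-%.1f nm\n",
                min(wavelengthGrid(object)), max(wavelengthGrid(object))))
  if (ncol(object)) {
    cat(sprintf("  subjects: %d | markers: %s\n",
                length(unique(cd$subject_id)),
                paste(unique(cd$marker), collapse = ", ")))
    cat("  classes: ",
        paste(sprintf("%s=%d", names(table(cd$class_label[!duplicated(cd$subject_id)])),
                      table(cd$class_label[!duplicated(cd$subject_id)])),
              collapse = " "), "\n", sep = "")
  }
})

setMethod("show", "KANClassifier", function(object) {
  cat(sprintf("KANClassifier <%s>%s\n", object@type,
              if (object@trained) " (trained)" else " (untrained)"))
  cat(sprintf("  parameters: %d\n", parameterCount(object)))
  if (object@trained && length(object@history)) {
    h <- object@history
    cat(sprintf("  best epoch %d: val BCE %.4g, val AUC %.4f\n",
                h$best_epoch, h$val_loss[h$best_epoch], h$val_auc[h$best_epoch]))
  }
})

#' Accessors for plasmoKAN objects
#'
#' `wavelengthGrid` returns the shared wavelength grid of a
#' [SpectrumExperiment-class]; `preSpectra`/`postSpectra` the reflectance
#' assays; `recordData` the record manifest; `parameterCount` the number of
#' trainable parameters of a classifier; `trainingHistory` its learning curve.
#'
#' @param x a SpectrumExperiment or KANClassifier
#' @return see the individual descriptions
#' @name accessors
NULL

#' @rdname accessors
#' @export
wavelengthGrid <- function(x) SummarizedExperiment::rowData(x)$wavelength_nm

#' @rdname accessors
#' @export
preSpectra <- function(x) SummarizedExperiment::assay(x, "pre")

#' @rdname accessors
#' @export
postSpectra <- function(x) SummarizedExperiment::assay(x, "post")

#' @rdname accessors
#' @export
recordData <- function(x) SummarizedExperiment::colData(x)

#' @rdname accessors
#' @export
parameterCount <- function(x) {
  stopifnot(is(x, "KANClassifier"))
  sum(vapply(x@params, length, integer(1)))
}

#' @rdname accessors
#' @export
trainingHistory <- function(x) {
  stopifnot(is(x, "KANClassifier"))
  x@history
}
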