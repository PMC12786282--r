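## Closed-form resonance physics of the gold nanohole array and the
## analyte-response model composed into a parametric spectrum synthesizer.

orderNorm <- function(order) {
  i <- order[[1]]; j <- order[[2]]
  if (i == 0 && j == 0) stop("diffraction order (0,0) is not a resonance")
  if (i != round(i) || j != round(j)) stop("diffraction orders must be integers")
  sqrt(i^2 + j^2)
}

epsDielectric <- function(material) material@n_medium^2

#' Wood-Rayleigh anomaly wavelength
#'
#' Grazing-diffraction condition of the periodic array:
#' lambda_WA = P / sqrt(i^2 + j^2) * sqrt(eps_d). Depends only on the period
#' and the bulk dielectric, which is what makes this mode insensitive to
#' surface binding.
#'
#' @param geometry a [ChipGeometry-class]
#' @param order diffraction order, a length-2 integer vector (i, j), not both 0
#' @param material a [MaterialModel-class]; eps_d = n_medium^2
#' @return anomaly wavelength in nm
#' @examples
#' woodAnomalyWavelength(chipGeometry(period_nm = 500), c(1, 0),
#'                       materialModel(n_medium = 1.33))  # 665 nm in water
#' @export
woodAnomalyWavelength <- function(geometry, order, material) {
  eps_d <- epsDielectric(material)
  if (!is.finite(eps_d) || eps_d <= 0) stop("eps_dielectric must be positive")
  geometry@period_nm / orderNorm(order) * sqrt(eps_d)
}

sppFactor <- function(eps_d, eps_m) {
  ratio <- eps_d * Re(eps_m) / (eps_d + Re(eps_m))
  if (ratio <= 0) stop("bound-mode condition violated: |Re(eps_metal)| must exceed eps_d")
  sqrt(ratio)
}

#' Surface plasmon polariton resonance wavelength
#'
#' Momentum-matching condition of the array:
#' lambda_SPP = P / sqrt(i^2 + j^2) * sqrt(eps_d * eps_Au / (eps_d + eps_Au)).
#' With a constant metal permittivity the closed form is exact; with a
#' dispersive (function-valued) permittivity the fixed point
#' lambda = f(eps_Au(lambda)) is solved by damped iteration (damping 0.5,
#' tolerance 1e-6 nm, at most 100 iterations).
#'
#' @inheritParams woodAnomalyWavelength
#' @param lambda_init starting wavelength (nm) for the dispersive solver
#' @return resonance wavelength in nm
#' @examples
#' sppWavelength(chipGeometry(period_nm = 500), c(1, 0),
#'               materialModel(eps_metal = -20, n_medium = 1.33))
#' @export
sppWavelength <- function(geometry, order, material, lambda_init = 650) {
  eps_d <- epsDielectric(material)
  nrm <- orderNorm(order)
  em <- material@eps_metal
  if (!is.function(em)) {
    if (Re(em) >= 0 || abs(Re(em)) <= eps_d)
      stop("bound-mode condition violated: need Re(eps_metal) < 0 and |Re(eps_metal)| > eps_d")
    return(geometry@period_nm / nrm * sppFactor(eps_d, em))
  }
  lam <- lambda_init
  damping <- 0.5
  for (it in seq_len(100L)) {
    e <- em(lam)
    if (Re(e) >= 0 || abs(Re(e)) <= eps_d)
      stop(sprintf("bound-mode condition violated at lambda = %.3f nm", lam))
    target <- geometry@period_nm / nrm * sppFactor(eps_d, e)
    new_lam <- (1 - damping) * lam + damping * target
    if (abs(new_lam - lam) < 1e-6) return(new_lam)
    lam <- new_lam
  }
  stop(sprintf("SPP fixed point did not converge within 100 iterations; last iterate %.6f nm", lam))
}

#' Langmuir fractional surface coverage
#'
#' theta = K x / (1 + K x): monotone, concave, bounded below 1.
#'
#' @param K Langmuir equilibrium constant (>= 0)
#' @param x analyte concentration (>= 0), vectorized
#' @return fractional coverage in [0, 1)
#' @examples
#' langmuirCoverage(2, 3)  # 6/7
#' @export
langmuirCoverage <- function(K, x) {
  if (any(K < 0) || any(x < 0)) stop("K and x must be non-negative")
  K * x / (1 + K * x)
}

#' Effective refractive index of the partly covered surface
#'
#' Linear mixing n = theta * n_analyte + (1 - theta) * n_medium.
#'
#' @param theta fractional coverage in [0, 1], vectorized
#' @param material a [MaterialModel-class]
#' @return effective refractive index
#' @examples
#' effectiveIndex(0.5, materialModel())  # 1.465 for water/1.60 particles
#' @export
effectiveIndex <- function(theta, material) {
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  theta * material@n_analyte + (1 - theta) * material@n_medium
}

#' Refractometric resonance shift
#'
#' delta_lambda = S * delta_n, the first-order response of a resonance to an
#' interfacial refractive-index change. Wood-anomaly modes do not respond to
#' surface binding and return 0.
#'
#' @param mode one row of a mode table (see [defaultModes()]), or a list with
#'   fields `kind` and `bulk_sensitivity_nm_per_RIU`
#' @param delta_n refractive index change (>= 0 for binding), vectorized
#' @return wavelength shift in nm
#' @export
refractometricShift <- function(mode, delta_n) {
  if (any(delta_n < 0)) stop("delta_n must be >= 0 for binding events")
  if (identical(as.character(mode$kind), "WA")) return(rep(0, length(delta_n)))
  mode$bulk_sensitivity_nm_per_RIU * delta_n
}

absorbanceLoad <- function(binding) {
  langmuirCoverage(binding@K / binding@absorption_saturation, binding@x)
}

#' Beer-Lambert intensity attenuation
#'
#' A = eps * c * l with c = concentration_scale * load, where load is the
#' fractional particle load of the absorbance channel; returns the
#' transmitted fraction 10^(-A) in (0, 1], which multiplies the mode's dip
#' contrast.
#'
#' @param binding a [BindingState-class]
#' @return transmitted fraction in (0, 1]
#' @examples
#' absorbanceAttenuation(bindingState(x = 0))  # 1: no analyte, no loss
#' @export
absorbanceAttenuation <- function(binding) {
  c_abs <- binding@concentration_scale * absorbanceLoad(binding)
  A <- binding@molar_absorptivity * c_abs * binding@path_length
  10^(-A)
}

#' The four default optical modes of the chip
#'
#' Centers follow the observed modes: P1 at 580 nm (SPP, gold-water), P2 at
#' 665 nm (Wood anomaly), P3 at 680 nm (SPP at the gold-silicon substrate
#' interface, configured rather than derived), P4 at 728 nm (SPP,
#' gold-water, the most sensitive mode). Linewidths, dip depths and
#' refractometric sensitivities are model parameters of the phenomenological
#' lineshape (see the methods vignette).
#'
#' @return data.frame with one row per mode: label, kind, center_wavelength_nm,
#'   linewidth_nm, depth, bulk_sensitivity_nm_per_RIU, interface
#' @export
defaultModes <- function() {
  data.frame(
    label = c("P1", "P2", "P3", "P4"),
    kind = c("SPP", "WA", "SPP", "SPP"),
    center_wavelength_nm = c(580, 665, 680, 728),
    linewidth_nm = c(22, 10, 16, 14),
    depth = c(0.30, 0.22, 0.28, 0.45),
    bulk_sensitivity_nm_per_RIU = c(30, 0, 10, 60),
    bulk_shift_nm_per_RIU = c(440, 500, 0, 560),
    interface = c("medium", "medium", "substrate", "medium"),
    stringsAsFactors = FALSE)
}

validateModes <- function(modes) {
  need <- c("label", "kind", "center_wavelength_nm", "linewidth_nm", "depth",
            "bulk_sensitivity_nm_per_RIU", "bulk_shift_nm_per_RIU", "interface")
  miss <- setdiff(need, colnames(modes))
  if (length(miss)) stop("mode table misses columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(modes$label)) stop("duplicated mode labels")
  if (any(modes$linewidth_nm <= 0)) stop("linewidths must be positive")
  if (any(modes$depth <= 0 | modes$depth > 1)) stop("depths must lie in (0, 1]")
  invisible(modes)
}

#' Default wavelength grid of the spectrometer band
#'
#' @param from,to band limits in nm
#' @param step grid step in nm
#' @return ascending numeric grid (default 500-800 nm at 0.5 nm)
#' @export
defaultGrid <- function(from = 500, to = 800, step = 0.5) seq(from, to, by = step)

lorentzianDips <- function(grid, centers, widths, depths) {
  r <- numeric(length(grid))
  for (m in seq_along(centers)) {
    hw <- widths[m] / 2
    r <- r + depths[m] / (1 + ((grid - centers[m]) / hw)^2)
  }
  r
}

#' Synthesize a reflectance spectrum from a mode table
#'
#' Phenomenological lineshape: a flat baseline minus a sum of inverted
#' Lorentzian dips (one per mode), clipped to [0, 1].
#'
#' @param modes mode table as from [defaultModes()]
#' @param grid ascending wavelength grid (nm)
#' @param baseline_reflectance baseline level in (0, 1]
#' @return data.frame with columns `wavelength_nm`, `reflectance`
#' @examples
#' sp <- synthesizeSpectrum(defaultModes(), defaultGrid())
#' @export
synthesizeSpectrum <- function(modes, grid = defaultGrid(),
                               baseline_reflectance = 0.95) {
  if (length(grid) > 1L && any(diff(grid) <= 0)) stop("grid must be strictly ascending")
  if (baseline_reflectance <= 0 || baseline_reflectance > 1)
    stop("baseline_reflectance must lie in (0, 1]")
  if (nrow(modes)) validateModes(modes)
  refl <- baseline_reflectance - if (nrow(modes))
    lorentzianDips(grid, modes$center_wavelength_nm, modes$linewidth_nm,
                   modes$depth) else 0
  data.frame(wavelength_nm = grid, reflectance = pmin(1, pmax(0, refl)))
}

#' Apply analyte binding to a mode table
#'
#' Composes the analyte-response model: each SPP mode's center shifts by
#' S * (n_eff(theta) - n_medium) (Langmuir coverage, effective-index mixing,
#' refractometric shift), its depth is multiplied by the Beer-Lambert
#' transmitted fraction, and its linewidth broadens by the loading factor
#' (1 + beta * theta). Wood-anomaly modes are left untouched. The returned
#' table re-synthesizes the post-detection spectrum.
#'
#' @param modes mode table
#' @param binding a [BindingState-class]
#' @param material a [MaterialModel-class]
#' @param beta linewidth loading factor (default 0.2)
#' @return modified mode table
#' @examples
#' applyBinding(defaultModes(), bindingState(x = 1), materialModel())
#' @export
applyBinding <- function(modes, binding, material, beta = 0.2) {
  validateModes(modes)
  theta <- langmuirCoverage(binding@K, binding@x)
  delta_n <- effectiveIndex(theta, material) - material@n_medium
  atten <- absorbanceAttenuation(binding)
  out <- modes
  for (r in seq_len(nrow(modes))) {
    if (modes$kind[r] == "WA") next
    out$center_wavelength_nm[r] <- modes$center_wavelength_nm[r] +
      refractometricShift(modes[r, ], delta_n)
    out$depth[r] <- modes$depth[r] * atten
    out$linewidth_nm[r] <- modes$linewidth_nm[r] * (1 + beta * theta)
  }
  out
}

#' Add seeded measurement noise to a spectrum
#'
#' Applies, in order: a rigid wavelength-calibration shift (the spectrum is
#' re-read at shifted wavelengths by linear interpolation), a multiplicative
#' intensity gain, a linear baseline tilt (drawn uniformly in
#' +-baseline_tilt across the band) and i.i.d. Gaussian reflectance noise,
#' then clips to [0, 1]. Identical seeds give identical realizations.
#'
#' @param spectrum data.frame with `wavelength_nm`, `reflectance`
#' @param noise a [NoiseModel-class]
#' @return noisy spectrum data.frame
#' @export
addNoise <- function(spectrum, noise) {
  n <- nrow(spectrum)
  r <- withSeed(noise@seed, {
    y <- spectrum$reflectance
    if (noise@lambda_jitter_nm > 0) {
      dl <- rnorm(1, sd = noise@lambda_jitter_nm)
      y <- stats::approx(spectrum$wavelength_nm, y,
                         xout = spectrum$wavelength_nm + dl, rule = 2)$y
    }
    if (noise@gain_sd > 0) y <- y * (1 + rnorm(1, sd = noise@gain_sd))
    tilt <- runif(1, -noise@baseline_tilt, noise@baseline_tilt)
    frac <- if (n > 1) (seq_len(n) - 1) / (n - 1) - 0.5 else 0
    y + rnorm(n, sd = noise@sigma_reflectance) + tilt * 2 * frac
  })
  spectrum$reflectance <- clip01(r)
  spectrum
}

#' Concentration response curves of one mode
#'
#' Sweeps analyte concentration and records the resonance wavelength shift
#' and two intensity responses: the change in reflectance at the fixed
#' pre-binding resonance wavelength (intensity interrogation, the quantity
#' that exhibits the shift-then-intensity crossover) and the change of the
#' trough minimum (the spectroscopic-effect feature).
#'
#' @param mode a single-row mode table (default: mode P4)
#' @param material a [MaterialModel-class]
#' @param binding template [BindingState-class]; its `x` is swept
#' @param x concentrations to sweep (default logarithmic, 1e-2..1e2 / K)
#' @param beta linewidth loading factor
#' @return data.frame with columns x, delta_lambda_nm, delta_R_fixed, delta_R_min
#' @export
modeResponseSweep <- function(mode = defaultModes()[4, ],
                              material = materialModel(),
                              binding = bindingState(),
                              x = 10^seq(-2, 2, length.out = 41),
                              beta = 0.2) {
  lam0 <- mode$center_wavelength_nm
  out <- data.frame(x = x, delta_lambda_nm = NA_real_,
                    delta_R_fixed = NA_real_, delta_R_min = NA_real_)
  for (i in seq_along(x)) {
    b <- binding; b@x <- x[i]
    m2 <- applyBinding(mode, b, material, beta = beta)
    out$delta_lambda_nm[i] <- m2$center_wavelength_nm - lam0
    hw <- m2$linewidth_nm / 2
    dip_at_lam0 <- m2$depth / (1 + ((lam0 - m2$center_wavelength_nm) / hw)^2)
    out$delta_R_fixed[i] <- mode$depth - dip_at_lam0   # reflectance rise at lam0
    out$delta_R_min[i] <- mode$depth - m2$depth        # trough-minimum change
  }
  out
}

#' Fit the Langmuir constant from a shift-concentration curve
#'
#' Fits delta_lambda(x) = dmax * K x / (1 + K x) by nonlinear least squares
#' (Levenberg-Marquardt) and returns the estimated K and saturation shift.
#'
#' @param x concentrations
#' @param delta_lambda measured shifts (nm)
#' @param K_init,dmax_init starting values (defaults: reciprocal median
#'   concentration; maximal observed shift)
#' @return list with elements `K`, `delta_lambda_max`, and the `fit` object
#' @export
fitLangmuirK <- function(x, delta_lambda,
                         K_init = 1 / stats::median(x[x > 0]),
                         dmax_init = max(delta_lambda)) {
  df <- data.frame(x = x, y = delta_lambda)
  fit <- minpack.lm::nlsLM(y ~ dmax * K * x / (1 + K * x), data = df,
                           start = list(K = K_init, dmax = dmax_init),
                           lower = c(K = 1e-8, dmax = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  list(K = unname(est["K"]), delta_lambda_max = unname(est["dmax"]), fit = fit)
}
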