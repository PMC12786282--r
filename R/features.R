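## Conventional biosensing readouts: per-mode trough detection with sub-grid
## parabolic refinement, RE/SE/NLE feature extraction with four-mode fusion,
## and the full-spectrum patch vectorization used by the attention model.

#' Default per-mode wavelength windows
#'
#' Half-open intervals [lo, hi) around the four modes, used to split a
#' spectrum into the P1..P4 regions.
#'
#' @return named list of length-2 numeric vectors (nm)
#' @export
defaultModeWindows <- function() {
  list(P1 = c(560, 610), P2 = c(650, 672), P3 = c(672, 700), P4 = c(700, 760))
}

## 3-point parabolic refinement around grid index k (interior); ties already
## broken toward the lower wavelength by which.min. Returns c(lambda, value).
parabolicMin <- function(wl, y, k) {
  h <- wl[k + 1] - wl[k]
  y1 <- y[k - 1]; y2 <- y[k]; y3 <- y[k + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom <= 0) return(c(wl[k], y2))
  off <- 0.5 * (y1 - y3) / denom * h
  off <- max(-h / 2, min(h / 2, off))
  val <- y2 - (y1 - y3)^2 / (8 * denom)
  c(wl[k] + off, val)
}

#' Detect resonance troughs per mode window
#'
#' In every window the global reflectance minimum is located and refined to
#' sub-grid precision by 3-point parabolic interpolation (ties broken toward
#' the lower wavelength). A window whose minimum sits on the window edge (no
#' interior minimum, e.g. a flat or monotone spectrum) is flagged rather than
#' failed.
#'
#' @param spectrum data.frame with `wavelength_nm` and `reflectance`
#' @param windows named list of [lo, hi) windows (default [defaultModeWindows()])
#' @return data.frame: label, lambda_res, R_min, flagged
#' @examples
#' sp <- synthesizeSpectrum(defaultModes(), defaultGrid())
#' detectModeTroughs(sp)
#' @export
detectModeTroughs <- function(spectrum, windows = defaultModeWindows()) {
  wl <- spectrum$wavelength_nm
  y <- spectrum$reflectance
  out <- data.frame(label = names(windows), lambda_res = NA_real_,
                    R_min = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (w in seq_along(windows)) {
    idx <- which(wl >= windows[[w]][1] & wl < windows[[w]][2])
    if (length(idx) < 3L) stop(sprintf("window %s holds fewer than 3 grid points",
                                       names(windows)[w]))
    k <- idx[which.min(y[idx])]
    if (k == idx[1] || k == idx[length(idx)]) {
      out$flagged[w] <- TRUE
      out$lambda_res[w] <- wl[k]; out$R_min[w] <- y[k]
    } else {
      pm <- parabolicMin(wl, y, k)
      out$lambda_res[w] <- pm[1]; out$R_min[w] <- pm[2]
    }
  }
  out
}

## vectorized trough detection over the columns of a G x R reflectance matrix
troughMatrix <- function(wl, M, windows) {
  R <- ncol(M)
  lam <- rmin <- matrix(NA_real_, R, length(windows),
                        dimnames = list(NULL, names(windows)))
  flagged <- matrix(FALSE, R, length(windows))
  for (w in seq_along(windows)) {
    idx <- which(wl >= windows[[w]][1] & wl < windows[[w]][2])
    sub <- M[idx, , drop = FALSE]
    k <- max.col(-t(sub), ties.method = "first")
    edge <- k == 1L | k == length(idx)
    kc <- pmin(pmax(k, 2L), length(idx) - 1L)
    h <- wl[idx[2]] - wl[idx[1]]
    cols <- seq_len(R)
    y1 <- sub[cbind(kc - 1L, cols)]; y2 <- sub[cbind(kc, cols)]
    y3 <- sub[cbind(kc + 1L, cols)]
    denom <- y1 - 2 * y2 + y3
    ok <- denom > 0 & !edge
    off <- ifelse(ok, pmax(-h / 2, pmin(h / 2, 0.5 * (y1 - y3) / denom * h)), 0)
    val <- ifelse(ok, y2 - (y1 - y3)^2 / (8 * denom), y2)
    lam[, w] <- wl[idx][k] + ifelse(edge, 0, off)
    rmin[, w] <- ifelse(edge, sub[cbind(k, cols)], val)
    flagged[, w] <- edge
  }
  list(lambda = lam, rmin = rmin, flagged = flagged)
}

#' Extract conventional-effect features from a pre/post spectrum pair
#'
#' RE (refractometric effect): resonance wavelength shift per mode
#' (post - pre). SE (spectroscopic effect): trough reflectance change per
#' mode. NLE (nanoplasmonic loading effect): concatenation of the RE and SE
#' channels. Any subset of modes may be used (single-mode variants or
#' four-mode fusion).
#'
#' @param pre,post spectra on identical grids
#' @param effect "RE", "SE" or "NLE"
#' @param windows mode windows
#' @param mode_set labels of the modes to use (default: all windows)
#' @return named numeric feature vector (length |modes|, or 2x for NLE)
#' @examples
#' sp <- synthesizeSpectrum(defaultModes(), defaultGrid())
#' extractEffectFeatures(sp, sp, "NLE")  # zero vector
#' @export
extractEffectFeatures <- function(pre, post, effect = c("NLE", "RE", "SE"),
                                  windows = defaultModeWindows(),
                                  mode_set = names(windows)) {
  effect <- match.arg(effect)
  if (!isTRUE(all.equal(pre$wavelength_nm, post$wavelength_nm)))
    stop("pre and post spectra must share one wavelength grid")
  windows <- windows[mode_set]
  tp <- detectModeTroughs(pre, windows)
  tq <- detectModeTroughs(post, windows)
  bad <- tp$flagged | tq$flagged
  if (any(bad))
    stop("no trough found for mode(s): ", paste(tp$label[bad], collapse = ", "))
  dl <- setNames(tq$lambda_res - tp$lambda_res, paste0("dlambda_", tp$label))
  dr <- setNames(tq$R_min - tp$R_min, paste0("dR_", tp$label))
  switch(effect, RE = dl, SE = dr, NLE = c(dl, dr))
}

#' Extract a feature table from a spectrum dataset
#'
#' Vectorized [extractEffectFeatures()] over every record of a
#' [SpectrumExperiment-class]. Records in which any requested mode lacks an
#' interior trough are dropped with a warning.
#'
#' @param se a [SpectrumExperiment-class]
#' @param effect "RE", "SE" or "NLE"
#' @param windows mode windows
#' @param mode_set labels of the modes to use
#' @return data.frame: record metadata columns, then the feature columns
#' @export
extractFeatureTable <- function(se, effect = c("NLE", "RE", "SE"),
                                windows = defaultModeWindows(),
                                mode_set = names(windows)) {
  effect <- match.arg(effect)
  windows <- windows[mode_set]
  wl <- wavelengthGrid(se)
  tp <- troughMatrix(wl, preSpectra(se), windows)
  tq <- troughMatrix(wl, postSpectra(se), windows)
  keep <- !(rowSums(tp$flagged) + rowSums(tq$flagged) > 0)
  if (!all(keep))
    warning(sprintf("dropped %d record(s) without interior troughs", sum(!keep)))
  dl <- tq$lambda[keep, , drop = FALSE] - tp$lambda[keep, , drop = FALSE]
  colnames(dl) <- paste0("dlambda_", mode_set)
  dr <- tq$rmin[keep, , drop = FALSE] - tp$rmin[keep, , drop = FALSE]
  colnames(dr) <- paste0("dR_", mode_set)
  feats <- switch(effect, RE = dl, SE = dr, NLE = cbind(dl, dr))
  meta <- as.data.frame(recordData(se))[keep, , drop = FALSE]
  cbind(meta, as.data.frame(feats))
}

featureColumns <- function(tab) grep("^(dlambda|dR)_", colnames(tab), value = TRUE)

#' Tile a pre/post spectrum pair into a patch sequence
#'
#' The two reflectance channels (optionally normalized per wavelength) are
#' cut into contiguous non-overlapping patches of `patch_length` grid points;
#' the last patch is padded by edge replication. Patch p holds
#' [pre segment, post segment] and carries position index pos = p - 1.
#'
#' @param pre,post spectra on identical grids (data.frames)
#' @param patch_length grid points per patch (default 16)
#' @return list: `patches` (P x 2*patch_length matrix), `pos` (0-based),
#'   `n_grid` (original grid length), `patch_length`
#' @export
patchSequence <- function(pre, post, patch_length = 16L) {
  if (!isTRUE(all.equal(pre$wavelength_nm, post$wavelength_nm)))
    stop("pre and post spectra must share one wavelength grid")
  G <- nrow(pre)
  P <- ceiling(G / patch_length)
  pad <- P * patch_length - G
  a <- c(pre$reflectance, rep(pre$reflectance[G], pad))
  b <- c(post$reflectance, rep(post$reflectance[G], pad))
  patches <- cbind(matrix(a, nrow = P, byrow = TRUE),
                   matrix(b, nrow = P, byrow = TRUE))
  list(patches = patches, pos = seq_len(P) - 1L, n_grid = G,
       patch_length = as.integer(patch_length))
}

#' Reconstruct the channel pair from a patch sequence
#'
#' Inverse of [patchSequence()]: concatenates the patches and trims the
#' edge-replication padding.
#'
#' @param ps result of [patchSequence()]
#' @return list with numeric vectors `pre` and `post` of the original length
#' @export
unpatchSequence <- function(ps) {
  pl <- ps$patch_length
  a <- as.vector(t(ps$patches[, seq_len(pl), drop = FALSE]))
  b <- as.vector(t(ps$patches[, pl + seq_len(pl), drop = FALSE]))
  list(pre = a[seq_len(ps$n_grid)], post = b[seq_len(ps$n_grid)])
}

#' Per-wavelength normalization statistics from a training partition
#'
#' Means and standard deviations of the pre and post channels computed on the
#' given records only (leakage guard: compute on the training partition and
#' freeze).
#'
#' @param se a [SpectrumExperiment-class]
#' @param records indices or record_ids of the training records
#' @return list with mean/sd vectors for both channels
#' @export
spectrumNormalization <- function(se, records) {
  pre <- preSpectra(se)[, records, drop = FALSE]
  post <- postSpectra(se)[, records, drop = FALSE]
  sdfloor <- function(s) pmax(s, 1e-6)
  list(mean_pre = rowMeans(pre), sd_pre = sdfloor(apply(pre, 1, sd)),
       mean_post = rowMeans(post), sd_post = sdfloor(apply(post, 1, sd)))
}

## n_records x P x (2*patch_length) tensor of normalized patches
buildPatchTensor <- function(se, records, norm, patch_length = 16L) {
  pre <- preSpectra(se)[, records, drop = FALSE]
  post <- postSpectra(se)[, records, drop = FALSE]
  pre <- (pre - norm$mean_pre) / norm$sd_pre
  post <- (post - norm$mean_post) / norm$sd_post
  G <- nrow(pre); R <- ncol(pre)
  P <- ceiling(G / patch_length)
  pad <- P * patch_length - G
  if (pad > 0) {
    pre <- rbind(pre, matrix(pre[G, ], pad, R, byrow = TRUE))
    post <- rbind(post, matrix(post[G, ], pad, R, byrow = TRUE))
  }
  ## element (r, p, k): channel value at grid point (p-1)*pl + k
  arr <- array(0, dim = c(R, P, 2L * patch_length))
  for (p in seq_len(P)) {
    rows <- (p - 1L) * patch_length + seq_len(patch_length)
    arr[, p, seq_len(patch_length)] <- t(pre[rows, , drop = FALSE])
    arr[, p, patch_length + seq_len(patch_length)] <- t(post[rows, , drop = FALSE])
  }
  arr
}

#' Wavelength range covered by each patch
#'
#' @param grid wavelength grid
#' @param patch_length grid points per patch
#' @return data.frame with patch index (1-based), pos (0-based), lo, hi (nm)
#' @export
patchWavelengths <- function(grid, patch_length = 16L) {
  G <- length(grid)
  P <- ceiling(G / patch_length)
  lo <- grid[pmin((seq_len(P) - 1L) * patch_length + 1L, G)]
  hi <- grid[pmin(seq_len(P) * patch_length, G)]
  data.frame(patch = seq_len(P), pos = seq_len(P) - 1L, lo = lo, hi = hi)
}
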