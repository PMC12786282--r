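## Kolmogorov-Arnold layers: every edge (input p -> output q) carries a
## learnable univariate function, parameterized as a B-spline on a fixed
## uniform grid plus a weighted silu base activation; node outputs are sums
## over incoming edges. Forward and backward passes are hand-vectorized; the
## B-spline basis itself is evaluated by splines::splineDesign.

#' Spline specification of a KAN layer
#'
#' A uniform B-spline basis of order `k` (polynomial degree k) on `G` grid
#' points spanning `range`, extended by k knots on each side, giving
#' G + k - 1 basis functions per edge with partition of unity on the range.
#' Inputs are clamped to the range before evaluation.
#'
#' @param G grid size (knots per edge across the input range), >= 2
#' @param k spline order (polynomial degree), >= 1
#' @param range length-2 input range (default c(-3, 3))
#' @return list with knots, order, basis count and range
#' @export
splineSpec <- function(G = 5L, k = 3L, range = c(-3, 3)) {
  stopifnot(G >= 2L, k >= 1L, range[2] > range[1])
  h <- (range[2] - range[1]) / (G - 1)
  knots <- range[1] + (seq_len(G + 2L * k) - 1L - k) * h
  list(knots = knots, ord = k + 1L, m = G + k - 1L, range = range, G = G, k = k)
}

clampToRange <- function(x, spec) {
  eps <- 1e-9 * (spec$range[2] - spec$range[1])
  pmin(pmax(x, spec$range[1]), spec$range[2] - eps)
}

## basis (and optionally derivative) matrix for a numeric vector, n x m
kanBasis <- function(x, spec, deriv = 0L) {
  splines::splineDesign(spec$knots, clampToRange(x, spec), ord = spec$ord,
                        derivs = rep(deriv, length(x)))
}

## reshape the stacked basis of a n x p input matrix into n x (p*m) with
## column order (p-major, basis index fast) matching the coefficient matrix
kanPhi <- function(X, spec, deriv = 0L) {
  n <- nrow(X); p <- ncol(X)
  B <- kanBasis(as.vector(X), spec, deriv)        # rows: (i, p) column-major
  matrix(aperm(array(B, c(n, p, spec$m)), c(1, 3, 2)), n, p * spec$m)
}

#' Initialize one KAN layer
#'
#' Spline coefficients are drawn Normal(0, 0.1); base-activation weights
#' start at 1/p_in so that node sums are O(1) at any width (a unit base
#' weight summed over many incoming edges would saturate the downstream
#' clamp/sigmoid and kill the gradient).
#'
#' @param p_in,p_out input and output widths
#' @param spec spline specification from [splineSpec()]
#' @param seed integer seed
#' @return list with `coef` ((p_in * m) x p_out matrix; rows ordered by input
#'   then basis index) and `w` (p_in x p_out base weights)
#' @export
kanLayerInit <- function(p_in, p_out, spec = splineSpec(), seed = 1L) {
  withSeed(seed, list(
    coef = matrix(rnorm(p_in * spec$m * p_out, sd = 0.1), p_in * spec$m, p_out),
    w = matrix(1 / p_in, p_in, p_out)))
}

#' Forward pass of one KAN layer
#'
#' output_q = sum_p [ spline_qp(x_p) + w_qp * silu(x_p) ], evaluated for a
#' batch. Inputs are clamped to the spline range.
#'
#' @param X n x p_in input matrix (finite)
#' @param layer layer parameters from [kanLayerInit()]
#' @param spec spline specification
#' @param cache logical: also return what the backward pass needs
#' @return n x p_out output matrix (with attribute-free list when `cache`)
#' @export
kanLayerForward <- function(X, layer, spec = splineSpec(), cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (any(!is.finite(X))) stop("non-finite input to KAN layer")
  if (nrow(layer$w) != ncol(X))
    stop(sprintf("input width %d does not match layer width %d",
                 ncol(X), nrow(layer$w)))
  Xc <- clampToRange(X, spec)
  Phi <- kanPhi(Xc, spec)
  S <- silu(Xc)
  Y <- Phi %*% layer$coef + S %*% layer$w
  if (!cache) return(Y)
  list(Y = Y, Xc = Xc, Phi = Phi, S = S,
       inrange = (X > spec$range[1]) & (X < spec$range[2]))
}

## gradients of one KAN layer; returns dX and parameter gradients
kanLayerBackward <- function(dY, layer, fwd, spec = splineSpec()) {
  m <- spec$m
  p_in <- nrow(layer$w)
  dCoef <- crossprod(fwd$Phi, dY)
  dW <- crossprod(fwd$S, dY)
  dPhi <- kanPhi(fwd$Xc, spec, deriv = 1L)
  D <- (dY %*% t(layer$coef)) * dPhi
  dXs <- vapply(seq_len(p_in),
                function(p) rowSums(D[, (p - 1L) * m + seq_len(m), drop = FALSE]),
                numeric(nrow(dY)))
  dX <- (matrix(dXs, nrow(dY), p_in) + (dY %*% t(layer$w)) * siluGrad(fwd$Xc)) *
    fwd$inrange
  list(dX = dX, coef = dCoef, w = dW)
}

#' Brute-force KAN layer evaluation (reference oracle)
#'
#' Triple loop over samples, outputs and inputs, evaluating each edge's
#' spline one point at a time. Slow by construction; used to verify the
#' vectorized forward pass.
#'
#' @inheritParams kanLayerForward
#' @return n x p_out output matrix
#' @export
kanLayerForwardNaive <- function(X, layer, spec = splineSpec()) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  n <- nrow(X); p_in <- ncol(X); p_out <- ncol(layer$w)
  Y <- matrix(0, n, p_out)
  for (i in seq_len(n)) for (q in seq_len(p_out)) {
    acc <- 0
    for (p in seq_len(p_in)) {
      x <- clampToRange(X[i, p], spec)
      b <- splines::splineDesign(spec$knots, x, ord = spec$ord)
      cf <- layer$coef[(p - 1L) * spec$m + seq_len(spec$m), q]
      acc <- acc + sum(b * cf) + layer$w[p, q] * silu(x)
    }
    Y[i, q] <- acc
  }
  Y
}

#' Construct spline coefficients interpolating a target function on one edge
#'
#' Solves the linear system B c = f(grid) on a dense evaluation grid (least
#' squares) so that the edge's spline approximates `f` over the spec range.
#' Used in tests (e.g. reproducing the identity on one edge).
#'
#' @param f univariate function
#' @param spec spline specification
#' @return coefficient vector of length `spec$m`
#' @export
splineInterpolate <- function(f, spec = splineSpec()) {
  xs <- seq(spec$range[1], spec$range[2], length.out = 10L * spec$m)
  B <- kanBasis(xs, spec)
  qr.solve(B, f(xs))
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of binary labels under predicted
#' probabilities, with predictions clipped to [eps, 1 - eps].
#'
#' @param labels vector of 0/1 labels
#' @param predictions predicted probabilities
#' @param eps clipping constant (default 1e-7)
#' @return non-negative scalar loss
#' @examples
#' bceLoss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
bceLoss <- function(labels, predictions, eps = 1e-7) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

## ---- feature-table models ------------------------------------------------

#' Build a KAN classifier over a feature table
#'
#' A stack of KAN layers of the given widths ending in one unit, followed by
#' a sigmoid. Feature normalization statistics are attached at training time.
#'
#' @param n_features input width K
#' @param hidden hidden widths (default c(16, 8))
#' @param spec spline specification
#' @param seed integer seed (deterministic initialization)
#' @return an untrained [KANClassifier-class] of type "feature"
#' @export
buildFeatureModel <- function(n_features, hidden = c(16L, 8L),
                              spec = splineSpec(), seed = 1L) {
  widths <- c(n_features, hidden, 1L)
  params <- list()
  for (l in seq_len(length(widths) - 1L)) {
    lay <- kanLayerInit(widths[l], widths[l + 1L], spec,
                        seed = deriveSeed(seed, paste0("kan", l)))
    params[[paste0("L", l, ".coef")]] <- lay$coef
    params[[paste0("L", l, ".w")]] <- lay$w
  }
  new("KANClassifier", type = "feature", params = params,
      config = list(widths = widths, spec = spec, seed = as.integer(seed)))
}

#' Build a multilayer-perceptron reference classifier
#'
#' Plain dense/ReLU stack ending in a sigmoid unit; serves as the matched
#' reference against which the KAN's parameter economy and convergence are
#' compared.
#'
#' @param n_features input width
#' @param hidden hidden widths (default c(64, 32))
#' @param seed integer seed
#' @return an untrained [KANClassifier-class] of type "mlp"
#' @export
buildMLPModel <- function(n_features, hidden = c(64L, 32L), seed = 1L) {
  widths <- c(n_features, hidden, 1L)
  params <- list()
  withSeed(deriveSeed(seed, "mlp"), {
    for (l in seq_len(length(widths) - 1L)) {
      sdv <- sqrt(2 / widths[l])
      params[[paste0("L", l, ".W")]] <-
        matrix(rnorm(widths[l] * widths[l + 1L], sd = sdv),
               widths[l], widths[l + 1L])
      params[[paste0("L", l, ".b")]] <- numeric(widths[l + 1L])
    }
  })
  new("KANClassifier", type = "mlp", params = params,
      config = list(widths = widths, seed = as.integer(seed)))
}

featureForward <- function(model, X, cache = FALSE) {
  widths <- model@config$widths
  L <- length(widths) - 1L
  caches <- vector("list", L)
  H <- X
  if (model@type == "feature") {
    spec <- model@config$spec
    for (l in seq_len(L)) {
      lay <- list(coef = model@params[[paste0("L", l, ".coef")]],
                  w = model@params[[paste0("L", l, ".w")]])
      fw <- kanLayerForward(H, lay, spec, cache = TRUE)
      caches[[l]] <- fw
      H <- fw$Y
    }
  } else {
    for (l in seq_len(L)) {
      Z <- sweep(H %*% model@params[[paste0("L", l, ".W")]], 2,
                 model@params[[paste0("L", l, ".b")]], "+")
      A <- if (l < L) pmax(Z, 0) else Z
      caches[[l]] <- list(H = H, Z = Z)
      H <- A
    }
  }
  logit <- H[, 1L]
  p <- sigmoid(logit)
  if (cache) list(p = p, logit = logit, caches = caches, X = X) else p
}

featureBackward <- function(model, fwd, dlogit) {
  widths <- model@config$widths
  L <- length(widths) - 1L
  grads <- list()
  dH <- matrix(dlogit, ncol = 1L)
  if (model@type == "feature") {
    spec <- model@config$spec
    for (l in rev(seq_len(L))) {
      lay <- list(coef = model@params[[paste0("L", l, ".coef")]],
                  w = model@params[[paste0("L", l, ".w")]])
      bk <- kanLayerBackward(dH, lay, fwd$caches[[l]], spec)
      grads[[paste0("L", l, ".coef")]] <- bk$coef
      grads[[paste0("L", l, ".w")]] <- bk$w
      dH <- bk$dX
    }
  } else {
    for (l in rev(seq_len(L))) {
      cc <- fwd$caches[[l]]
      dZ <- if (l < L) dH * (cc$Z > 0) else dH
      grads[[paste0("L", l, ".W")]] <- crossprod(cc$H, dZ)
      grads[[paste0("L", l, ".b")]] <- colSums(dZ)
      dH <- dZ %*% t(model@params[[paste0("L", l, ".W")]])
    }
  }
  grads
}
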