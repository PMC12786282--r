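## Full-spectrum model: linear patch embedding + sinusoidal positional
## encoding + a stack of pre-norm multi-head self-attention layers + mean
## pooling + a KAN head. All passes hand-vectorized with analytic gradients.

#' Sinusoidal positional encoding
#'
#' angle(pos, i) = pos / 10000^(2i / d_model); even embedding dimensions
#' carry sin(angle), odd dimensions cos(angle) (standard interleaving).
#' Defined directly (not through logarithms) so position 0 is valid.
#'
#' @param num_positions number of sequence positions (pos = 0 .. n-1)
#' @param d_model embedding dimension (even)
#' @return num_positions x d_model matrix with entries in [-1, 1]
#' @examples
#' positionalEncoding(4, 8)
#' @export
positionalEncoding <- function(num_positions, d_model) {
  stopifnot(num_positions >= 1)
  if (d_model %% 2 != 0) stop("d_model must be even")
  pos <- seq_len(num_positions) - 1
  i <- rep(seq_len(d_model / 2) - 1, each = 2)
  angle <- outer(pos, i, function(p, ii) p / 10000^(2 * ii / d_model))
  enc <- angle
  even <- seq(1, d_model, by = 2)   # columns holding sin (0-based even dims)
  enc[, even] <- sin(angle[, even])
  enc[, -even] <- cos(angle[, -even])
  enc
}

layerNormForward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + 1e-6)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layerNormBackward <- function(dY, g, cc) {
  d <- ncol(dY)
  dg <- colSums(dY * cc$xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, "*")
  rs1 <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * cc$xhat)
  dX <- cc$inv * (dxhat - rs1 / d - cc$xhat * rs2 / d)
  list(dX = dX, g = dg, b = db)
}

softmaxRows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Build the full-spectrum KAN classifier
#'
#' Pipeline: linear patch embedding -> additive positional encoding -> L
#' pre-norm multi-head self-attention layers with residual connections
#' (every head's attention weight matrix is exportable) -> gated pooling
#' over patches (a learned per-patch, per-dimension gain followed by the
#' mean; with the linear embedding this spans every linear readout of the
#' full spectrum, which plain mean pooling cannot) -> layer norm -> KAN
#' head -> sigmoid probability, plus a zero-initialized global linear
#' shortcut from the flattened input to the logit (the shortcut carries the
#' linear spectral readout exactly; the attention + KAN path models the
#' nonlinear residual structure).
#'
#' @param n_grid wavelength grid length
#' @param patch_length grid points per patch (default 16)
#' @param d_model embedding dimension (default 64, divisible by `heads`)
#' @param layers number of attention layers L (default 2)
#' @param heads heads per layer H (default 4)
#' @param head_hidden hidden width of the KAN head (default 16)
#' @param spec spline specification of the head
#' @param seed integer seed
#' @return an untrained [KANClassifier-class] of type "fullspectrum"
#' @export
buildFullSpectrumModel <- function(n_grid, patch_length = 16L, d_model = 64L,
                                   layers = 2L, heads = 4L, head_hidden = 16L,
                                   spec = splineSpec(), seed = 1L) {
  if (layers < 2L || heads < 2L)
    stop("the attention stack needs at least 2 layers and 2 heads")
  if (d_model %% heads != 0) stop("d_model must be divisible by heads")
  P <- ceiling(n_grid / patch_length)
  c_in <- 2L * patch_length
  params <- list()
  withSeed(deriveSeed(seed, "embed"), {
    params[["embed.W"]] <- matrix(rnorm(c_in * d_model, sd = sqrt(1 / c_in)),
                                  c_in, d_model)
    params[["embed.b"]] <- numeric(d_model)
    for (l in seq_len(layers)) {
      pre <- paste0("att", l, ".")
      params[[paste0(pre, "ln.g")]] <- rep(1, d_model)
      params[[paste0(pre, "ln.b")]] <- numeric(d_model)
      for (nm in c("Wq", "Wk", "Wv", "Wo"))
        params[[paste0(pre, nm)]] <-
          matrix(rnorm(d_model^2, sd = sqrt(1 / d_model)), d_model, d_model)
      for (nm in c("bq", "bk", "bv", "bo"))
        params[[paste0(pre, nm)]] <- numeric(d_model)
    }
    params[["pool.G"]] <- matrix(1, P, d_model)
    params[["skip.W"]] <- matrix(0, P, c_in)
    params[["pool.ln.g"]] <- rep(1, d_model)
    params[["pool.ln.b"]] <- numeric(d_model)
  })
  h1 <- kanLayerInit(d_model, head_hidden, spec, deriveSeed(seed, "head1"))
  h2 <- kanLayerInit(head_hidden, 1L, spec, deriveSeed(seed, "head2"))
  params[["head1.coef"]] <- h1$coef; params[["head1.w"]] <- h1$w
  params[["head2.coef"]] <- h2$coef; params[["head2.w"]] <- h2$w
  cfg <- list(n_grid = as.integer(n_grid), patch_length = as.integer(patch_length),
              n_patches = as.integer(P), d_model = as.integer(d_model),
              layers = as.integer(layers), heads = as.integer(heads),
              head_hidden = as.integer(head_hidden), spec = spec,
              seed = as.integer(seed),
              posenc = positionalEncoding(P, d_model))
  new("KANClassifier", type = "fullspectrum", params = params, config = cfg)
}

## X3: n x P x (2*patch_length). Internal sequence layout: rows (s-1)*P + p.
fwd_skip_rows <- function(X2, W, n, P) {
  matrix(rowSums(X2 * W[rep(seq_len(P), n), , drop = FALSE]), ncol = 1L)
}

fullForward <- function(model, X3, cache = FALSE, keep_attention = FALSE) {
  cfg <- model@config; pm <- model@params
  n <- dim(X3)[1]; P <- cfg$n_patches; d <- cfg$d_model
  heads <- cfg$heads; dh <- d %/% heads
  X2 <- matrix(aperm(X3, c(2, 1, 3)), n * P, dim(X3)[3])
  H <- sweep(X2 %*% pm[["embed.W"]], 2, pm[["embed.b"]], "+") +
    cfg$posenc[rep(seq_len(P), n), ]
  lcache <- vector("list", cfg$layers)
  attw <- if (keep_attention)
    lapply(seq_len(cfg$layers), function(l) array(0, c(P, P, heads, n)))
  for (l in seq_len(cfg$layers)) {
    pre <- paste0("att", l, ".")
    ln <- layerNormForward(H, pm[[paste0(pre, "ln.g")]], pm[[paste0(pre, "ln.b")]])
    N <- ln$Y
    Q <- sweep(N %*% pm[[paste0(pre, "Wq")]], 2, pm[[paste0(pre, "bq")]], "+")
    K <- sweep(N %*% pm[[paste0(pre, "Wk")]], 2, pm[[paste0(pre, "bk")]], "+")
    V <- sweep(N %*% pm[[paste0(pre, "Wv")]], 2, pm[[paste0(pre, "bv")]], "+")
    O <- matrix(0, n * P, d)
    A_all <- array(0, c(P, P, heads, n))
    for (s in seq_len(n)) {
      rs <- (s - 1L) * P + seq_len(P)
      for (h in seq_len(heads)) {
        hd <- (h - 1L) * dh + seq_len(dh)
        A <- softmaxRows(Q[rs, hd, drop = FALSE] %*%
                           t(K[rs, hd, drop = FALSE]) / sqrt(dh))
        A_all[, , h, s] <- A
        O[rs, hd] <- A %*% V[rs, hd, drop = FALSE]
      }
    }
    if (keep_attention) attw[[l]] <- A_all
    Hout <- H + sweep(O %*% pm[[paste0(pre, "Wo")]], 2, pm[[paste0(pre, "bo")]], "+")
    lcache[[l]] <- list(ln = ln, N = N, Q = Q, K = K, V = V, O = O, A = A_all)
    H <- Hout
  }
  Hg <- H * pm[["pool.G"]][rep(seq_len(P), n), , drop = FALSE]
  Z <- rowsum(Hg, group = rep(seq_len(n), each = P), reorder = FALSE) / P
  pln <- layerNormForward(Z, pm[["pool.ln.g"]], pm[["pool.ln.b"]])
  spec <- cfg$spec
  f1 <- kanLayerForward(pln$Y, list(coef = pm[["head1.coef"]], w = pm[["head1.w"]]),
                        spec, cache = TRUE)
  f2 <- kanLayerForward(f1$Y, list(coef = pm[["head2.coef"]], w = pm[["head2.w"]]),
                        spec, cache = TRUE)
  skip <- rowsum(rowSums(fwd_skip <- fwd_skip_rows(X2, pm[["skip.W"]], n, P)),
                 group = rep(seq_len(n), each = P), reorder = FALSE)[, 1L]
  logit <- f2$Y[, 1L] + skip
  p <- sigmoid(logit)
  if (!cache) {
    if (keep_attention) return(list(p = p, attention = attw))
    return(p)
  }
  list(p = p, logit = logit, lcache = lcache, pln = pln, f1 = f1, f2 = f2,
       X2 = X2, H = H, n = n, attention = if (keep_attention) attw)
}

fullBackward <- function(model, fwd, dlogit) {
  cfg <- model@config; pm <- model@params
  n <- fwd$n; P <- cfg$n_patches; d <- cfg$d_model
  heads <- cfg$heads; dh <- d %/% heads
  spec <- cfg$spec
  grads <- list()
  dlog_rep <- rep(dlogit, each = P)
  grads[["skip.W"]] <- rowsum(fwd$X2 * dlog_rep,
                              group = rep(seq_len(P), n), reorder = FALSE)
  dY2 <- matrix(dlogit, ncol = 1L)
  b2 <- kanLayerBackward(dY2, list(coef = pm[["head2.coef"]], w = pm[["head2.w"]]),
                         fwd$f2, spec)
  grads[["head2.coef"]] <- b2$coef; grads[["head2.w"]] <- b2$w
  b1 <- kanLayerBackward(b2$dX, list(coef = pm[["head1.coef"]], w = pm[["head1.w"]]),
                         fwd$f1, spec)
  grads[["head1.coef"]] <- b1$coef; grads[["head1.w"]] <- b1$w
  pb <- layerNormBackward(b1$dX, pm[["pool.ln.g"]], fwd$pln)
  grads[["pool.ln.g"]] <- pb$g; grads[["pool.ln.b"]] <- pb$b
  dZ_rep <- pb$dX[rep(seq_len(n), each = P), , drop = FALSE] / P
  Grep <- pm[["pool.G"]][rep(seq_len(P), n), , drop = FALSE]
  grads[["pool.G"]] <- rowsum(fwd$H * dZ_rep,
                              group = rep(seq_len(P), n), reorder = FALSE)
  dH <- dZ_rep * Grep
  for (l in rev(seq_len(cfg$layers))) {
    pre <- paste0("att", l, ".")
    cc <- fwd$lcache[[l]]
    dO <- dH %*% t(pm[[paste0(pre, "Wo")]])
    grads[[paste0(pre, "Wo")]] <- crossprod(cc$O, dH)
    grads[[paste0(pre, "bo")]] <- colSums(dH)
    dQ <- dK <- dV <- matrix(0, n * P, d)
    for (s in seq_len(n)) {
      rs <- (s - 1L) * P + seq_len(P)
      for (h in seq_len(heads)) {
        hd <- (h - 1L) * dh + seq_len(dh)
        A <- cc$A[, , h, s]
        dOs <- dO[rs, hd, drop = FALSE]
        Vs <- cc$V[rs, hd, drop = FALSE]
        dA <- dOs %*% t(Vs)
        dV[rs, hd] <- crossprod(A, dOs)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dh)
        dQ[rs, hd] <- dS %*% cc$K[rs, hd, drop = FALSE]
        dK[rs, hd] <- crossprod(dS, cc$Q[rs, hd, drop = FALSE])
      }
    }
    dN <- dQ %*% t(pm[[paste0(pre, "Wq")]]) + dK %*% t(pm[[paste0(pre, "Wk")]]) +
      dV %*% t(pm[[paste0(pre, "Wv")]])
    grads[[paste0(pre, "Wq")]] <- crossprod(cc$N, dQ)
    grads[[paste0(pre, "bq")]] <- colSums(dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(cc$N, dK)
    grads[[paste0(pre, "bk")]] <- colSums(dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(cc$N, dV)
    grads[[paste0(pre, "bv")]] <- colSums(dV)
    lb <- layerNormBackward(dN, pm[[paste0(pre, "ln.g")]], cc$ln)
    grads[[paste0(pre, "ln.g")]] <- lb$g
    grads[[paste0(pre, "ln.b")]] <- lb$b
    dH <- dH + lb$dX   # residual
  }
  grads[["embed.W"]] <- crossprod(fwd$X2, dH)
  grads[["embed.b"]] <- colSums(dH)
  grads
}

#' Attention weight maps of a trained full-spectrum model
#'
#' Runs the given patch tensor through the model and returns, per layer and
#' head, the attention weight matrix averaged over records. Every row of
#' every map sums to 1 (softmax normalization).
#'
#' @param model a trained full-spectrum [KANClassifier-class]
#' @param X3 patch tensor (records x patches x channels)
#' @return list (per layer) of lists (per head) of P x P matrices
#' @export
attentionMaps <- function(model, X3) {
  if (model@type != "fullspectrum")
    stop("attention maps require a full-spectrum model")
  fw <- fullForward(model, X3, cache = FALSE, keep_attention = TRUE)
  lapply(fw$attention, function(A_all) {
    lapply(seq_len(dim(A_all)[3]), function(h) {
      apply(A_all[, , h, , drop = FALSE], c(1, 2), mean)
    })
  })
}
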