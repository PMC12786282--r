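## Seed plumbing and small helpers. All randomness in the package flows
## through explicit seeds; the caller's RNG state is always restored.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Fans one global seed out to independent per-stage seeds by mixing a hash
#' of the stage name into the seed modulo 2^31 - 1. Deterministic; distinct
#' stages get distinct streams.
#'
#' @param seed global integer seed
#' @param stage stage name (character)
#' @return integer seed below 2^31
#' @export
deriveSeed <- function(seed, stage) {
  h <- rollHash(charToRaw(as.character(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

## rolling polynomial hash over a raw vector; exact in double arithmetic
rollHash <- function(raw) {
  h <- 0
  for (b in as.integer(raw)) h <- (h * 257 + b + 1) %% 2147483647
  h
}

configHash <- function(x) {
  sprintf("%08x", as.integer(rollHash(serialize(x, NULL, version = 2))))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)
siluGrad <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }
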