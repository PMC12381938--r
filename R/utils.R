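#' @keywords internal
"_PACKAGE"

# Deterministic polynomial hash of an R object's serialized bytes.
# Used for config hashes and stage caching; not cryptographic.
# Modulus chosen < sqrt(2^53) so all intermediate products are exact doubles.
obj_hash <- function(x) {
  bytes <- as.double(serialize(x, NULL, version = 2L))
  mod <- 94906249
  base <- 257
  # precompute base^i mod for one chunk
  chunk <- 256L
  pows <- numeric(chunk)
  pows[1] <- 1
  if (chunk > 1) for (i in 2:chunk) pows[i] <- (pows[i - 1] * base) %% mod
  pow_chunk <- (pows[chunk] * base) %% mod
  h <- 0
  n <- length(bytes)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    blk <- bytes[i:j]
    k <- length(blk)
    # h <- h * base^k + poly(blk), all mod
    hk <- if (k == chunk) pow_chunk else (pows[k] * base) %% mod
    h <- (h * hk) %% mod
    h <- (h + sum(blk * rev(pows[seq_len(k)])) %% mod) %% mod
    i <- j + 1L
  }
  sprintf("%08x", as.integer(h))
}

#' Derive a reproducible stage seed from a global seed
#'
#' Fans a single global seed out to independent per-stage RNG streams by
#' hashing the pair (seed, tag). The result is always a valid 32-bit R seed.
#'
#' @param seed Integer global seed.
#' @param tag Character stage label (e.g. `"codec"`, `"ldm"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  v <- c(as.integer(seed), utf8ToInt(tag))
  mod <- 2147483629
  h <- 17
  for (b in v) h <- (h * 31 + (b %% mod)) %% mod
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

silu <- function(x) {
  s <- 1 / (1 + exp(-x))
  x * s
}

dsilu <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
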