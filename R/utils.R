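# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Counter-based seed derivation: two rounds of a Lehmer multiplicative
# generator mod the Mersenne prime 2^31 - 1. Multiplications stay below
# 2^53, so the arithmetic is exact in doubles; results are valid set.seed()
# inputs and independent of evaluation order.
M31 <- 2147483647
derive_seed <- function(master, ...) {
  x <- (as.numeric(master) %% M31) + 1
  for (k in as.numeric(c(...))) {
    x <- (x * 48271) %% M31
    x <- (x + k + 1) %% M31
    x <- (x * 16807) %% M31
  }
  as.integer(x)
}

# Short content stamp for output provenance (not cryptographic): a 31-bit
# polynomial hash of the serialized object, hex-encoded.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(s))
  h <- 17
  for (ch in v) h <- (h * 31 + ch) %% M31
  sprintf("%08x", h)
}
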