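# Internal helpers: seeded evaluation, seed derivation, clamping.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed derivation from a master seed and index coordinates.
# Arithmetic stays below 2^53 so the double-precision modular reduction is
# exact; result lies in [1, 2147483628] (always a valid 32-bit seed).
derive_seed <- function(master, ...) {
  p <- 2147483629
  idx <- c(...)
  h <- as.numeric(master) %% p
  mult <- c(40503, 70423, 99991, 65537, 31337)
  for (i in seq_along(idx)) {
    h <- (h * 48271 + as.numeric(idx[i]) * mult[((i - 1) %% length(mult)) + 1]) %% p
  }
  as.integer(h %% (p - 1) + 1)
}

clip_unit <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
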