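# Internal helpers shared across modules.

# Deterministic child-seed derivation. Mixes a master seed with up to three
# stream indices into a positive integer < 2^31 so that every work unit
# (chromosome x partition, generation, group, ...) owns an independent,
# reproducible RNG stream. Arithmetic in doubles stays exact below 2^53.
derive_seed <- function(master, i = 0L, j = 0L, k = 0L) {
  x <- (as.double(master) %% 2147483647) +
    as.double(i) * 1299709 + as.double(j) * 15485863 + as.double(k) * 32452843
  as.integer(x %% 2147483629) + 1L
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the caller's
# state afterwards (or leaving it untouched when seed is NULL).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
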