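# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named random stream. Using named
# streams keeps e.g. bootstrap draws independent of reference-panel draws,
# so changing one setting does not perturb the other stage's randomness.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647L)
}

with_stream <- function(seed, stream, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# Half-up rounding to `digits` decimals (round() rounds half to even, which
# does not reproduce conventional reported percentages).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
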