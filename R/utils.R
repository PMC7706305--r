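# Internal helpers: scoped RNG and derived seeds.

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed below 2^31, exact in double arithmetic
# (|seed| < 2^31 keeps the product below 2^53).
childSeed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(i)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stressHours <- function(treatment) unname(STRESS_HOURS[treatment])
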