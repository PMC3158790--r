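# Internal helpers.

# Evaluate expr with a locally set RNG state, restoring the caller's state
# afterwards so seeded generators never perturb the session RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  eval.parent(substitute(expr))
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(index)) %% 2147483647)
}
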