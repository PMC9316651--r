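# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL means "use the ambient RNG",
# which is how composite simulators pass determinism down to their parts.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a per-unit child seed below 2^31 from a base seed and an index.
childSeed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

stopIfNot0Based <- function(pos, what = "position") {
  if (any(pos < 0)) stop("negative ", what, " not allowed (0-based coordinates)")
}
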