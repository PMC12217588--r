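`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a local RNG state: seeds reproducibly when seed is given,
# and restores the caller's .Random.seed either way.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
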