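# Run `expr` under a fixed RNG state without disturbing the caller's RNG.
# All randomness in the package goes through this helper, so results are a
# pure function of the supplied seed.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
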