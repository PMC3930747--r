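## Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## wrap angles in degrees to (-180, 180]
wrap_angle <- function(theta) {
  out <- theta - 360 * ceiling((theta - 180) / 360)
  out[out == -180] <- 180
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## derive a stream-specific 31-bit sub-seed from a master seed
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 48271 + stream * 7919) %% 2147483647L
}
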