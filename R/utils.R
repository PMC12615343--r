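#' @keywords internal
"_PACKAGE"

## Run an expression with a private RNG stream, restoring the caller's state.
## All generators in the package route their randomness through this so that
## a seed in a spec object gives bit-identical output without disturbing the
## session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

## Derive a stream-specific child seed from a base seed; kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L
}

## 90-degree counter-clockwise rotation of a square matrix.
rot90 <- function(m) {
  stopifnot(nrow(m) == ncol(m))
  t(m)[ncol(m):1, , drop = FALSE]
}

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
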