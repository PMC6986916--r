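## Internal helpers shared across modules.

## Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Full m x m matrix of squared Euclidean distances between rows of X.
squaredDistances <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

## Run expr, rethrowing any error tagged with the pipeline stage name.
stageCall <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

## Derive a stream of sub-seeds from one master seed, kept below 2^31.
subSeed <- function(seed, i) {
  ((as.double(seed) %% 1000003) * 1009 + 7919 * as.double(i)) %% 2147483647
}
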