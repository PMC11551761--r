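#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages of the pipeline draw their seeds from a single root
#' seed through this function, so that e.g. the kymograph simulator and the
#' bootstrap use independent but fully reproducible random streams.
#'
#' @param seed integer root seed.
#' @param stream character name of the consumer stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid 32-bit integers
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards; a `NULL` seed leaves the global RNG untouched
#' (caller-managed randomness).
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)  # force RNG initialization so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
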