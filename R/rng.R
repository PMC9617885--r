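#' Derive an independent sub-stream seed from a root seed
#'
#' All stochastic components (input-weight draw, sampled circuit noise,
#' fabrication mismatch, dataset generation, training shuffles) consume seeds
#' derived from one root seed through distinct named streams, so that toggling
#' one noise source never perturbs another (e.g. enabling sampled noise does
#' not change the input weight matrix).
#'
#' @param seed root seed (integer).
#' @param stream stream name, one of the names in `.rc_streams`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  if (!stream %in% names(.rc_streams)) {
    stop("unknown rng stream: ", stream)
  }
  offset <- .rc_streams[[stream]]
  # multiplicative mix modulo a Mersenne prime keeps everything in 32-bit range
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  ((s * 48271 + offset * 69621) %% m)
}

.rc_streams <- c(
  weights  = 1L,
  noise    = 2L,
  mismatch = 3L,
  dataset  = 4L,
  train    = 5L,
  split    = 6L
)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never disturb the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
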