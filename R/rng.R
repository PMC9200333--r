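#' Derive a named sub-seed from a root seed
#'
#' Every source of randomness in the package draws from a named substream of
#' a single root seed, so that re-running any command with the same seed is
#' bit-reproducible and adding a new random component never perturbs the
#' draws of existing ones.
#'
#' @param seed integer root seed.
#' @param stream character label of the substream (e.g. `"warmup"`,
#'   `"perturb"`, `"env"`, `"noise"`).
#' @return an integer seed in `[0, 2^31 - 2]`, deterministic in
#'   `(seed, stream)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  # polynomial string hash mod the Mersenne prime 2^31 - 1; all intermediate
  # values stay below 2^53 so double arithmetic is exact
  m <- 2147483647
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h * 7919 + 12345) %% m)
}

#' Create an isolated RNG stream
#'
#' Returns a stream object holding its own `.Random.seed` state, so stateful
#' components (e.g. the noise wrapper) can draw random numbers without
#' disturbing, or being disturbed by, the global RNG.
#'
#' @param seed integer seed for the stream.
#' @return an environment of class `rng_stream`.
#' @keywords internal
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under an isolated RNG stream
#'
#' @param stream an [rng_stream()] object; its state is advanced by the draw.
#' @param expr expression using R's RNG.
#' @return the value of `expr`.
#' @keywords internal
#' @export
with_rng <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
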