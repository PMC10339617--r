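#' Derive a substream seed from a master seed and a stream name
#'
#' Every stochastic stage of the pipeline draws from its own named RNG
#' substream derived from one master seed, so adding or reordering a stage
#' never perturbs the draws of another stage.
#'
#' @param master integer master seed (0 <= master < 2^31).
#' @param name character stream name (e.g. "genotypes.reference").
#' @return An integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, !is.na(master))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in utf8ToInt(name)) {
    h <- (h * 131 + k) %% m
  }
  as.integer((abs(master) %% m * 48271 + h) %% m)
}

#' Evaluate an expression under a named RNG substream
#'
#' Sets the RNG state from [substream_seed()] for the duration of `expr` and
#' restores the previous global state afterwards.
#'
#' @param master integer master seed.
#' @param name substream name.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_substream <- function(master, name, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(master, name))
  expr
}
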