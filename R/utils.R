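#' @useDynLib taskmo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif predict qnorm pnorm quantile prcomp sd
#'   rbinom dnorm fft chisq.test
#' @importFrom utils write.csv read.csv modifyList
NULL

#' Evaluate code under a fixed RNG state, restoring the caller's stream
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a named sub-seed from a master seed
#'
#' A single master seed drives every stochastic component of an experiment;
#' independent streams (backgrounds, signal angles, splits, weight
#' initialization, ...) use sub-seeds derived deterministically from the
#' master seed and a stream label, so that fixing the master seed fixes every
#' artifact while the streams remain decoupled.
#'
#' @param seed master seed (integer).
#' @param label character stream label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% m
  as.integer((abs(seed) %% m * 48271 + h * 16807 + 12345) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_taskmo <- function(...) stop(..., call. = FALSE)
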