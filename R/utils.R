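#' @useDynLib readrsa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rnorm runif sd qt pt setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

#' Derive a named RNG substream seed
#'
#' Deterministically combines a top-level seed with a stream name so that
#' independent stages (lexicon, nonwords, projections, noise, ...) draw from
#' unrelated but reproducible streams. The result is always a positive
#' integer below 2^31.
#'
#' @param seed integer top-level seed
#' @param name character stream name
#' @return integer seed
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483629 + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards.
#' @param seed integer seed
#' @param expr expression
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
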