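#' @keywords internal
#' @useDynLib mlmisim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Derive a reproducible child seed
#'
#' Mixes a base seed with one or more integer salts through a
#' Lehmer-style multiplicative congruential step so that distinct
#' purposes (predictor draws, outcome draws, amputation, each imputation
#' chain, each replication) consume non-overlapping random streams while
#' remaining a pure function of the base seed.
#'
#' @param seed integer base seed.
#' @param ... integer salts identifying the sub-stream.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- as.double(seed) %% m
  for (salt in c(...)) {
    x <- (x * 48271 + (as.double(salt) + 1) * 16807) %% m
  }
  s <- as.integer(x %% (m - 2)) + 1L
  s
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
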