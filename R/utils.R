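#' @importFrom methods new validObject is slot
#' @importFrom stats optim rbinom rpois runif setNames ecdf
#' @importFrom utils head read.delim write.table
NULL

## Run expr with a locally-set RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package funnel through this helper so that
## a user-supplied seed fully determines the output without clobbering the
## session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Stable per-query seed derived from the run seed and the query identifier,
## so results do not depend on the order in which queries are processed or on
## the number of workers. Kept below 2^31 - 1.
querySeed <- function(seed, queryId) {
  codes <- utf8ToInt(queryId)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1000000007
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## numeric formatting for show() methods
fmtNum <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
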