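#' @useDynLib antmine, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim rpois rbinom runif rexp quantile sd setNames
#'   dexp aggregate
#' @importFrom utils head read.csv write.csv
#' @importFrom tools md5sum
NULL

#' Trait categories used throughout the package
#'
#' The four ant-plant mutualism categories scored as binary traits:
#' nesting in domatia, visiting extrafloral nectaries, consuming plant food
#' bodies, and dispersing seeds.
#'
#' @return Character vector of the four category names.
#' @export
trait_categories <- function() {
  c("domatia", "efn", "food_bodies", "seed_dispersal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
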