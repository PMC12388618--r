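#' @useDynLib amfassembly, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov optimise p.adjust pt quantile rbinom rexp rgamma
#'   rlnorm rmultinom rnorm runif sd setNames
#' @importFrom utils combn head write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_value <- function(...) stop(sprintf(...), call. = FALSE)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_value("`seed` must be a single finite number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Upper-triangle (i < j) values of a square matrix, as a vector.
upper_tri_values <- function(m) m[upper.tri(m)]
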