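#' @keywords internal
"_PACKAGE"

#' @importFrom stats median coef quantile rnorm rpois rlnorm runif sd setNames uniroot
#' @importFrom utils head tail write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

is_unit <- function(v, tol = 1e-6) abs(vnorm(v) - 1) < tol

#' Evaluate code with a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, runs `code`, and restores the state,
#' so deterministic sub-draws (e.g. per-frame noise fields) do not perturb the
#' experiment-level random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

## deterministic per-(scene, time, plane) seed for the rendering noise field
hash_seed <- function(base_seed, t, focal_z) {
  h <- (as.double(base_seed) * 1009 +
          round(t * 1e4) * 97 +
          round((focal_z + 5000) * 64) * 31) %% 2147483629
  as.integer(h)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
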