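#' @useDynLib flexfold, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef dist dnorm lm median optim plogis rnorm
#'   runif sd uniroot vcov
#' @importFrom utils read.table write.table
#' @importFrom tools md5sum
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards.  All stochastic entry points funnel through
## this so that a recorded seed fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a per-task child seed from a master seed.  Kept below 2^31 - 1.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + as.double(index) * 104729) %% 2147483629) + 1L
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

## Rodrigues rotation matrix: angle in radians about (unit) axis.
rotation_matrix <- function(axis, angle) {
  a <- unit(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

## Rotate the rows of an n x 3 matrix about an axis through `point`.
rotate_about <- function(xyz, point, axis, angle) {
  R <- rotation_matrix(axis, angle)
  sweep(sweep(xyz, 2, point) %*% t(R), 2, point, "+")
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
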