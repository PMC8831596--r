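## DEER inter-subunit distance distributions -> symmetric pentamer restraints.
##
## One spin label per subunit of a C5 ring gives exactly two unique
## inter-label distances (5 adjacent and 5 diagonal pairs) with the fixed
## pentagon ratio d_diag / d_adj = 2 cos 36 = 1.618...; a bimodal P(r) is
## therefore decomposed as a constrained two-Gaussian mixture.

PENTAGON_RATIO <- 2 * cos(36 * pi / 180) # = golden ratio

#' Load a DEER distance distribution
#'
#' @param path two-column whitespace-separated text: r (Angstrom), density.
#' @param n_grid number of points of the uniform grid the density is
#'   resampled onto.
#' @return list of class `ff_deer_dist` with `r` (uniform grid) and `p`
#'   (density integrating to 1).
#' @export
load_distribution <- function(path, n_grid = 512) {
  df <- tryCatch(read.table(path, header = FALSE),
                 error = function(e) stop("cannot parse distribution file '",
                                          path, "': ", conditionMessage(e),
                                          call. = FALSE))
  if (!nrow(df) || ncol(df) < 2) stop("distribution file needs two numeric columns")
  r <- as.numeric(df[[1]]); p <- as.numeric(df[[2]])
  if (any(diff(r) <= 0)) stop("distance grid must be strictly increasing")
  if (any(p < -1e-9)) stop("negative densities in distribution")
  p <- pmax(p, 0)
  grid <- seq(min(r), max(r), length.out = n_grid)
  pg <- approx(r, p, xout = grid)$y
  dr <- grid[2] - grid[1]
  tot <- sum(pg) * dr
  if (tot <= 0) stop("distribution integrates to zero")
  structure(list(r = grid, p = pg / tot), class = "ff_deer_dist")
}

#' Write a DEER distribution to two-column text
#' @param dist `ff_deer_dist`.
#' @param path output path.
#' @export
write_distribution <- function(dist, path) {
  write.table(data.frame(r = dist$r, p = dist$p), path, sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

gauss_mix <- function(r, m1, s1, m2, s2, w) {
  w * dnorm(r, m1, s1) + (1 - w) * dnorm(r, m2, s2)
}

#' Decompose a pentamer DEER distribution into adjacent/diagonal modes
#'
#' Fits a two-Gaussian mixture by least squares on the density grid, with the
#' pentagon ratio 2 cos 36 between the means used for initialization.  When
#' only one mode is resolvable the fitted mode is taken as adjacent and the
#' diagonal inferred by the ratio (flagged).
#'
#' @param dist `ff_deer_dist`.
#' @return list with `adjacent` and `diagonal` (each `c(d0, width)`),
#'   `diagonal_inferred` flag, and the fitted mixing weight `w_adjacent`.
#' @export
split_pentamer_modes <- function(dist) {
  r <- dist$r; p <- dist$p
  if (max(p) <= 0) stop("empty distribution")
  m0 <- r[which.max(p)]
  mu <- sum(r * p) / sum(p)
  ## decide where the dominant peak sits: if the density mean is above the
  ## main mode, the main mode is the adjacent (shorter) distance
  if (m0 <= mu) { m1 <- m0; m2 <- m0 * PENTAGON_RATIO }
  else { m2 <- m0; m1 <- m0 / PENTAGON_RATIO }
  s0 <- max((max(r) - min(r)) / 30, 0.5)
  obj <- function(par) {
    m1 <- par[1]; s1 <- exp(par[2]); m2 <- par[3]; s2 <- exp(par[4])
    w <- plogis(par[5])
    sum((gauss_mix(r, m1, s1, m2, s2, w) - p)^2)
  }
  fit <- optim(c(m1, log(s0), m2, log(s0), 0), obj,
               method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-12))
  if (fit$convergence != 0) stop("mixture fit did not converge")
  m1 <- fit$par[1]; s1 <- exp(fit$par[2])
  m2 <- fit$par[3]; s2 <- exp(fit$par[4])
  w <- plogis(fit$par[5])
  if (m1 > m2) { tmp <- c(m1, s1); m1 <- m2; s1 <- s2; m2 <- tmp[1]; s2 <- tmp[2]; w <- 1 - w }
  ## single-mode case: modes collapsed or one mode carries (almost) no weight
  inferred <- FALSE
  if (abs(m2 / m1 - 1) < 0.15 || w > 0.98 || w < 0.02) {
    if (w < 0.02) { m1 <- m2; s1 <- s2 }
    m2 <- m1 * PENTAGON_RATIO
    s2 <- s1
    w <- 0.5
    inferred <- TRUE
  }
  list(adjacent = c(d0 = m1, width = s1),
       diagonal = c(d0 = m2, width = s2),
       diagonal_inferred = inferred, w_adjacent = w)
}

#' DEER modes to harmonic pentamer restraints
#'
#' @param modes output of [split_pentamer_modes] (or a list with `adjacent`
#'   and `diagonal` `c(d0, width)` entries).
#' @param label_residue residue carrying the spin label.
#' @return `ff_restraints` with one adjacent (chain offset 1) and one
#'   diagonal (chain offset 2) harmonic restraint, weights proportional to
#'   1/width^2.
#' @export
deer_to_restraints <- function(modes, label_residue) {
  stopifnot(modes$adjacent[["d0"]] > 0, modes$diagonal[["d0"]] > 0,
            modes$adjacent[["width"]] > 0, modes$diagonal[["width"]] > 0)
  distance_restraints(
    res_a = c(label_residue, label_residue), atom_a = "LABEL",
    off_a = 0L,
    res_b = c(label_residue, label_residue), atom_b = "LABEL",
    off_b = c(1L, 2L),
    d0 = c(modes$adjacent[["d0"]], modes$diagonal[["d0"]]),
    lower = 0, upper = Inf,
    kind = "DEER",
    weight = 1 / c(modes$adjacent[["width"]], modes$diagonal[["width"]])^2,
    potential = "harmonic")
}
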