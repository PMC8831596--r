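## Shared fixtures, built once per test run.  Everything is generated in
## code; nothing is read from stored data files.

fixture_env <- new.env()

## synthetic bundle (ground truth + observables on disk + derived restraints)
get_bundle <- function() {
  if (is.null(fixture_env$bundle)) {
    fixture_env$bundle <- make_bundle(dir = file.path(tempdir(), "ff-bundle"),
                                      master_seed = 1)
    fixture_env$restraints <- derive_restraints(fixture_env$bundle)
  }
  fixture_env$bundle
}

get_restraints <- function() {
  get_bundle()
  fixture_env$restraints
}

## small C5 pentamer from an arbitrary 3-residue subunit
tiny_pentamer <- function(radius = 20) {
  sub <- subunit_df(matrix(c(radius, 0, 0,
                             radius + 2, 1, 3,
                             radius + 4, 0, 6), 3, 3, byrow = TRUE))
  symmetrize_c5(sub)
}

subunit_df <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A") {
  ff_structure(data.frame(chain = chain, resno = resno, resname = "ALA",
                          atom = "CA", elem = "C",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE), resolution = "calpha")
}

rot3 <- function(axis, angle) flexfold:::rotation_matrix(axis, angle)

transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  s$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, t, "+")
  s
}

## brute-force rigid superposition oracle: coarse search over rotations
## (axis-angle grid) followed by Nelder-Mead polish; independent of the SVD
## path under test
brute_force_rmsd <- function(P, Q) {
  rmsd_of <- function(par) {
    R <- flexfold:::rotation_matrix(
      c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1])),
      par[3])
    P0 <- sweep(P, 2, colMeans(P))
    Q0 <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }
  best <- NULL
  for (th in seq(0.1, pi, length.out = 7))
    for (ph in seq(0, 2 * pi, length.out = 9)[-9])
      for (an in seq(-pi, pi, length.out = 13)) {
        v <- rmsd_of(c(th, ph, an))
        if (is.null(best) || v < best$value)
          best <- list(par = c(th, ph, an), value = v)
      }
  o <- optim(best$par, rmsd_of, method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-14))
  o$value
}
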