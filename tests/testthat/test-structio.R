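test_that("multi-model PDB files round-trip through read and write", {
  pent <- tiny_pentamer()
  pent2 <- transform_structure(pent, rot3(c(1, 1, 0), 0.7), c(3, -2, 1))
  f <- tempfile(fileext = ".pdb")
  write_structure(ff_ensemble(list(pent, pent2)), f)
  ens <- read_structure(f)
  expect_length(ens, 2)
  expect_equal(length(unique(ens$models[[1]]$atoms$chain)), 5)
  expect_equal(as.matrix(ens$models[[1]]$atoms[, c("x", "y", "z")]),
               as.matrix(pent$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  ens1 <- read_structure(f, model = 2)
  expect_length(ens1, 1)
  expect_error(read_structure(f, model = 3), "out of range")
  expect_error(read_structure(tempfile()), "no such file")
})

test_that("structures without CA for every residue are rejected", {
  df <- data.frame(chain = "A", resno = c(1, 2), resname = "ALA",
                   atom = c("CA", "N"), elem = c("C", "N"),
                   x = 0, y = 0, z = c(0, 3))
  expect_error(ff_structure(df, "full"), "missing CA")
})

test_that("kabsch superposition matches a brute-force rotation search", {
  set.seed(7)
  P <- matrix(rnorm(12, sd = 4), 4, 3)
  Q <- matrix(rnorm(12, sd = 4), 4, 3)
  fit <- flexfold:::kabsch_fit(P, Q)
  expect_equal(fit$rmsd, brute_force_rmsd(P, Q), tolerance = 1e-6)
  ## rigid invariance: a rotated translated copy superposes to zero
  a <- subunit_df(P)
  b <- transform_structure(a, rot3(c(0, 1, 0), pi / 2), c(10, 0, 0))
  expect_lt(kabsch_superpose(b, a)$rmsd, 1e-9)
  expect_lt(kabsch_superpose(a, a)$rmsd, 1e-12)
  expect_error(kabsch_superpose(subunit_df(P[1:2, ]), subunit_df(Q[1:2, ])),
               "degenerate")
})

test_that("ca_rmsd behaves as a pseudo-metric and honors superpose flag", {
  pent <- tiny_pentamer()
  shifted <- transform_structure(pent, t = c(3, 4, 0))
  expect_equal(ca_rmsd(pent, shifted, superpose = FALSE), 5)
  expect_lt(ca_rmsd(pent, shifted, superpose = TRUE), 1e-9)
  expect_equal(ca_rmsd(pent, pent), 0)
  ## symmetry and triangle inequality on random triples
  set.seed(11)
  for (k in 1:5) {
    xs <- lapply(1:3, function(i) subunit_df(matrix(rnorm(15, sd = 5), 5, 3)))
    d12 <- ca_rmsd(xs[[1]], xs[[2]]); d21 <- ca_rmsd(xs[[2]], xs[[1]])
    d13 <- ca_rmsd(xs[[1]], xs[[3]]); d23 <- ca_rmsd(xs[[2]], xs[[3]])
    expect_equal(d12, d21, tolerance = 1e-9)
    expect_lte(d13, d12 + d23 + 1e-9)
  }
  other <- tiny_pentamer(radius = 30)
  other$atoms$resno <- other$atoms$resno + 1
  expect_error(ca_rmsd(pent, other), "topology")
})

test_that("C5 symmetrization places chains by 72-degree rotation", {
  sub <- subunit_df(matrix(c(20, 0, 0, 22, 1, 3, 24, 0, 6), 3, 3, byrow = TRUE))
  pent <- symmetrize_c5(sub)
  d <- measure_distance(pent, list(chain = "A", resno = 1, atom = "CA"),
                        list(chain = "B", resno = 1, atom = "CA"))
  expect_equal(d, 2 * 20 * sin(36 * pi / 180), tolerance = 1e-9)
  ## explicit rotation of a single point
  one <- subunit_df(matrix(c(20, 0, 0), 1, 3))
  p2 <- symmetrize_c5(one)
  xyz <- as.matrix(p2$atoms[p2$atoms$chain == "B", c("x", "y", "z")])
  expect_equal(as.numeric(xyz),
               c(20 * cos(72 * pi / 180), 20 * sin(72 * pi / 180), 0),
               tolerance = 1e-9)
  ## exact invariance under a further 72-degree rotation
  rot <- transform_structure(pent, rot3(c(0, 0, 1), 2 * pi / 5))
  perm <- rot$atoms
  perm$chain <- c(A = "B", B = "C", C = "D", D = "E", E = "A")[perm$chain]
  perm <- perm[order(match(perm$chain, LETTERS[1:5]), perm$resno), ]
  expect_lt(max(abs(as.matrix(perm[, c("x", "y", "z")]) -
                    as.matrix(pent$atoms[, c("x", "y", "z")]))), 1e-9)
  expect_error(symmetrize_c5(pent), "one chain")
})

test_that("distance measurement is Euclidean and errors on missing atoms", {
  s <- subunit_df(matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE))
  expect_equal(measure_distance(s, list(chain = "A", resno = 1, atom = "CA"),
                                list(chain = "A", resno = 2, atom = "CA")), 5)
  expect_equal(measure_distance(s, list(chain = "A", resno = 1, atom = "CA"),
                                list(chain = "A", resno = 1, atom = "CA")), 0)
  expect_error(measure_distance(s, list(chain = "A", resno = 1, atom = "CB"),
                                list(chain = "A", resno = 2, atom = "CA")),
               "no atom")
})

test_that("symmetry-axis estimation recovers the construction axis", {
  sub <- subunit_df(ideal_ca_helix(8, origin = c(14, 0, 0)))
  pent <- symmetrize_c5(sub)
  fr <- estimate_symmetry_axis(pent)
  expect_equal(fr$axis_direction, c(0, 0, 1), tolerance = 1e-6)
  ## equivariance under rigid rotation
  R <- rot3(c(1, 2, 0), 0.8)
  fr2 <- estimate_symmetry_axis(transform_structure(pent, R))
  expect_equal(abs(sum(fr2$axis_direction * (R %*% c(0, 0, 1)))), 1,
               tolerance = 1e-6)
  ## noisy pentamer: axis within 1 degree
  set.seed(3)
  noisy <- pent
  noisy$atoms[, c("x", "y", "z")] <-
    noisy$atoms[, c("x", "y", "z")] + matrix(rnorm(3 * nrow(noisy$atoms), 0, 0.1),
                                             ncol = 3)
  fr3 <- estimate_symmetry_axis(noisy)
  ang <- acos(abs(sum(fr3$axis_direction * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
})
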