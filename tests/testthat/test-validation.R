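test_that("holdout split is seeded, disjoint and sized like the study", {
  rs <- distance_restraints(res_a = rep(1, 560), res_b = 1:560, d0 = 15,
                            lower = 11, upper = 19, kind = "PRE",
                            potential = "sigmoid")
  sp <- holdout_split(rs, 0.1, seed = 4)
  expect_equal(nrow(sp$free), 56)
  expect_equal(nrow(sp$working), 504)
  sp2 <- holdout_split(rs, 0.1, seed = 4)
  expect_identical(sp$free$res_b, sp2$free$res_b)
  expect_length(intersect(sp$free$res_b, sp$working$res_b), 0)
  expect_setequal(c(sp$free$res_b, sp$working$res_b), 1:560)
  expect_error(holdout_split(rs, 1.2), "fraction")
})

test_that("q_report is zero on the generating truth and tracks perturbations", {
  b <- get_bundle()
  gt <- b$gt
  ## noiseless restraints from the truth itself
  p <- pre_params()
  rs <- pre_table_to_restraints(forward_pre(gt, 30, p, noise = NULL), 30, p)
  two <- validate_restraints(rs[!is.na(rs$d0), ])
  ens <- ff_ensemble(list(gt$structure))
  qr <- q_report(ens, two)
  expect_equal(qr$q_pre, 0, tolerance = 1e-6)
  ## a uniform +2 A shift on one restrained pair raises Q by hand arithmetic
  one <- two[1, ]
  d <- restraint_distances(gt$structure, one)
  fake <- one; fake$d0 <- fake$d0 + 2; fake$lower <- fake$lower + 2
  fake$upper <- fake$upper + 2
  qr2 <- q_report(ens, validate_restraints(fake))
  expect_equal(qr2$q_pre, sqrt(4 / (one$d0 + 2)^2), tolerance = 1e-9)
  ## q_pre_free is computed over exactly the held-out set
  sp <- holdout_split(two, 0.2, seed = 1)
  qr3 <- q_report(ens, sp$working, free = sp$free)
  expect_equal(qr3$n$pre_free, nrow(sp$free))
  expect_equal(qr3$q_pre_free, 0, tolerance = 1e-6)
})

test_that("hydrogen-bond assignment labels helices and extended chains", {
  hel <- build_peptide(16, phi = -57, psi = -47)
  lab <- assign_secondary_structure(hel)$label
  expect_true(all(lab[3:14] == "H"))
  ext <- build_peptide(16, phi = 180, psi = 180)
  lab_e <- assign_secondary_structure(ext)$label
  expect_false(any(lab_e %in% c("H", "G")))
  ## invariance under rigid placement
  hel2 <- transform_structure(hel, rot3(c(1, 0, 2), 1.1), c(20, -4, 7))
  expect_identical(assign_secondary_structure(hel2)$label, lab)
  ## missing backbone atoms are an error
  broken <- hel
  broken$atoms <- broken$atoms[broken$atoms$atom != "O", ]
  expect_error(assign_secondary_structure(broken), "backbone")
})

test_that("disorder fraction counts turn and coil labels", {
  mk <- function(labels) data.frame(chain = "A", resno = seq_along(labels),
                                    label = labels)
  expect_equal(disorder_fraction(mk(rep("H", 10)), c(1, 10)), 0)
  expect_equal(disorder_fraction(mk(rep("C", 10)), c(1, 10)), 1)
  expect_equal(disorder_fraction(mk(c(rep("C", 4), rep("H", 6))), c(1, 10)), 0.4)
  ## 3_10 helix counts as ordered
  expect_equal(disorder_fraction(mk(c("G", "G", "C", "C")), c(1, 4)), 0.5)
  ## ensemble mode averages over models
  expect_equal(disorder_fraction(list(mk(rep("C", 10)), mk(rep("H", 10))),
                                 c(1, 10)), 0.5)
  expect_error(disorder_fraction(mk(rep("H", 4)), c(8, 9)), "empty span")
})

test_that("pore profile recovers constructed ring geometry", {
  ## stacked rings of carbon-like atoms (vdw 1.7) at ring radius 5
  ring <- function(z) {
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    data.frame(chain = rep(LETTERS[1:4], length.out = 12)[order(rep(1:12))],
               resno = 1:12, resname = "ALA", atom = "CA", elem = "C",
               x = 5 * cos(ang), y = 5 * sin(ang), z = z)
  }
  atoms <- do.call(rbind, lapply(c(-4, -2, 0, 2, 4), ring))
  atoms$chain <- "A"; atoms$resno <- seq_len(nrow(atoms))
  model <- ff_structure(atoms, "full")
  pp <- pore_profile(model, frame = symmetry_frame(axis_point = c(0, 0, 0)),
                     z_range = c(-4, 4), step = 2, seed = 1)
  expect_equal(pp$radius[pp$z == 0], 5 - 1.7, tolerance = 0.05)
  ## far outside the stack the radius hits the clamp
  pp2 <- pore_profile(model, frame = symmetry_frame(), z_range = c(40, 41),
                      step = 1, clamp = 15)
  expect_equal(pp2$radius, rep(15, 2))
  ## radius shrinks when atoms get fatter
  fat <- model; fat$atoms$elem <- "S"
  ppf <- pore_profile(fat, frame = symmetry_frame(), z_range = c(0, 0),
                      step = 1, seed = 1)
  expect_lt(ppf$radius[1], pp$radius[pp$z == 0])
  expect_error(pore_profile(model, frame = symmetry_frame(),
                            z_range = c(1, 0), step = 1), "empty z")
})

test_that("lateral portal radius matches a drilled gap", {
  ## cylindrical wall of columns at radius 12, one sector per chain; drill a
  ## gap around the A-B interface midpoint (36 degrees)
  build_wall <- function(drop_deg) {
    angs <- setdiff(seq(0, 351, by = 9), drop_deg)
    rows <- do.call(rbind, lapply(angs, function(ad) {
      a <- ad * pi / 180
      sector <- ((round(ad / 72) %% 5) + 1)
      zs <- seq(-6, 10, by = 2)
      data.frame(chain = LETTERS[sector], resno = NA_integer_,
                 resname = "ALA", atom = "CA", elem = "C",
                 x = 12 * cos(a), y = 12 * sin(a), z = zs)
    }))
    rows <- rows[order(rows$chain), ]
    for (ch in unique(rows$chain))
      rows$resno[rows$chain == ch] <- seq_len(sum(rows$chain == ch))
    ff_structure(rows, "full")
  }
  gap_model <- build_wall(c(27, 36, 45))
  r <- lateral_portal_radius(gap_model, c("A", "B"), girdle_z = -6,
                             frame = symmetry_frame(), vestibule_dz = 8)
  expect_gt(r, 1.5)
  expect_lt(r, 6)
  ## fully occluded interface gives (near) zero
  solid <- build_wall(integer(0))
  r0 <- lateral_portal_radius(solid, c("A", "B"), girdle_z = -6,
                              frame = symmetry_frame(), vestibule_dz = 8)
  expect_lt(r0, 1.0)
  expect_gt(r, r0)
  expect_error(lateral_portal_radius(gap_model, c("A", "C"), girdle_z = -6,
                                     frame = symmetry_frame()), "adjacent")
})

test_that("salt-bridge distances take the side-chain minimum, unthresholded", {
  mk_res <- function(chain, resno, resname, atoms) {
    do.call(rbind, lapply(names(atoms), function(a)
      data.frame(chain = chain, resno = resno, resname = resname, atom = a,
                 elem = substr(a, 1, 1),
                 x = atoms[[a]][1], y = atoms[[a]][2], z = atoms[[a]][3])))
  }
  arg <- mk_res("A", 10, "ARG", list(CA = c(0, 0, 0), NH1 = c(2.8, 0, 0),
                                     NH2 = c(1.5, 1.5, 0), NE = c(1.2, -1, 0)))
  glu <- mk_res("A", 20, "GLU", list(CA = c(8, 0, 0), OE1 = c(5.6, 0, 0),
                                     OE2 = c(7.2, 1.4, 0)))
  model <- ff_structure(rbind(arg, glu), "full")
  out <- salt_bridge_distances(model, data.frame(res_a = 10, res_b = 20,
                                                 relation = "intra"))
  expect_equal(out$distance, 2.8, tolerance = 1e-9)
  far <- glu; far[, c("x")] <- far[, "x"] + 9.2
  model2 <- ff_structure(rbind(arg, far), "full")
  out2 <- salt_bridge_distances(model2, data.frame(res_a = 10, res_b = 20,
                                                   relation = "intra"))
  expect_equal(out2$distance, 12, tolerance = 1e-9)
  ## missing side chains flag the pair
  ala <- mk_res("A", 30, "ALA", list(CA = c(12, 0, 0)))
  model3 <- ff_structure(rbind(arg, glu, ala), "full")
  expect_warning(out3 <- salt_bridge_distances(
    model3, data.frame(res_a = 10, res_b = 30, relation = "intra")), "missing")
  expect_true(is.na(out3$distance))
})

test_that("the ensemble measurement report composes the analytics", {
  gt <- get_bundle()$gt
  ens <- ff_ensemble(list(gt$structure))
  rep <- pdb_report(ens, height_pair = c(1, 41), radius_residue = 30,
                    icd_span = c(21, 40), girdle_z = NULL,
                    salt_bridges = NULL, pore_step = 2)
  d_direct <- measure_distance(gt$structure,
                               list(chain = "A", resno = 1, atom = "CA"),
                               list(chain = "A", resno = 41, atom = "CA"))
  expect_equal(rep$height, d_direct, tolerance = 1e-9)
  expect_equal(rep$max_radius,
               sqrt(sum(gt$subunit[30, 1:2]^2)), tolerance = 0.2)
  expect_true(all(rep$pore$radius >= 0))
  expect_true(is.na(rep$disorder_fraction)) # CA-only model: skipped
})
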