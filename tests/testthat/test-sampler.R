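test_that("shift-derived secondary structure follows the run-length rules", {
  mk <- function(dca) data.frame(residue = seq_along(dca), resname = "ALA",
                                 ca_ppm = 52.5 + dca, cb_ppm = 19.1)
  expect_identical(ss_from_shifts(mk(rep(0, 12))), 
                   structure(rep("C", 12), source = "shift-derived"))
  lab <- ss_from_shifts(mk(c(rep(0, 3), rep(3, 10), rep(0, 3))))
  expect_identical(unname(lab[4:13]), rep("H", 10))
  ## three consecutive high-score residues stay coil (run below 4)
  lab3 <- ss_from_shifts(mk(c(rep(0, 4), 3, 3, 3, rep(0, 6))))
  expect_false(any(lab3 == "H"))
  lab_e <- ss_from_shifts(mk(c(rep(-3, 8), rep(0, 6))))
  expect_identical(unname(lab_e[1:7]), rep("E", 7))
  expect_error(ss_from_shifts(mk(rep(0, 12))[1:5, ], n_res = 12), "70%")
})

test_that("initial conformations are deterministic and respect annotation", {
  ss <- rep("H", 15)
  a <- init_conformation(15, ss, seed = 4)
  b <- init_conformation(15, ss, seed = 4)
  expect_equal(a$atoms, b$atoms)
  bonds <- sqrt(rowSums(diff(as.matrix(a$atoms[, c("x", "y", "z")]))^2))
  expect_true(all(abs(bonds - 3.8) < 0.01))
  ## zero perturbation returns the template unchanged
  tmpl <- toy_template()
  same <- init_conformation(60, get_bundle()$gt$ss, template = tmpl,
                            perturb_sigma = 0, seed = 9)
  expect_equal(unname(as.matrix(same$atoms[, c("x", "y", "z")])),
               unname(as.matrix(tmpl$atoms[, c("x", "y", "z")])),
               tolerance = 1e-12)
  expect_error(init_conformation(10, rep("H", 9)), "length")
})

test_that("annealing is reproducible and reaches the energy floor terms", {
  b <- get_bundle()
  rs <- get_restraints()
  sch <- anneal_schedule(moves_per_temp = 150, seed = 21)
  st <- init_conformation(60, b$gt$ss, template = toy_template(), seed = 21)
  f1 <- mc_fold(st, b$gt$ss, rs, sch)
  f2 <- mc_fold(st, b$gt$ss, rs, sch)
  expect_identical(f1$subunit, f2$subunit)
  expect_identical(f1$trace, f2$trace)
  ## the stored score equals an independent recomputation on the model
  expect_equal(f1$score$s_total,
               total_score(f1$model, rs, b$gt$ss)$s_total, tolerance = 1e-9)
  ## with no restraints, bonds stay near 3.8 A and no CA pair clashes hard
  none <- distance_restraints(res_a = integer(0))
  f0 <- mc_fold(st, b$gt$ss, none, anneal_schedule(moves_per_temp = 250, seed = 5))
  pc <- flexfold:::pentamer_ca(f0$model)
  dm <- as.matrix(dist(pc$xyz))
  bonded <- cbind(seq_len(nrow(dm) - 1), seq_len(nrow(dm) - 1) + 1)
  bonded <- bonded[pc$chain[bonded[, 1]] == pc$chain[bonded[, 2]], ]
  expect_true(all(abs(dm[bonded] - 3.8) < 0.2))
  diag(dm) <- Inf
  dm[bonded] <- Inf; dm[bonded[, c(2, 1)]] <- Inf
  expect_gt(min(dm), 3.5)
})

test_that("acceptance rate falls as the ladder cools", {
  b <- get_bundle()
  rs <- get_restraints()
  st <- init_conformation(60, b$gt$ss, seed = 2)   # de novo, far from minimum
  f <- mc_fold(st, b$gt$ss, rs,
               anneal_schedule(temps = c(20, 0.02), moves_per_temp = 600,
                               rep_ramp = c(1, 1), seed = 2))
  expect_gt(f$acceptance[1], f$acceptance[2])
})

test_that("recovery power grows with restraint coverage", {
  b <- get_bundle()
  rs <- get_restraints()
  pre_two <- which(rs$kind == "PRE" & !is.na(rs$d0))
  rich <- validate_restraints(rs[c(pre_two[1:60],
                                   which(rs$kind == "DEER")), ])
  poor <- validate_restraints(rs[c(pre_two[seq(1, 60, by = 6)],
                                   which(rs$kind == "DEER")), ])
  rms <- function(set, seed) {
    st <- init_conformation(60, b$gt$ss, template = toy_template(),
                            seed = seed, rebuild_loops = TRUE)
    f <- mc_fold(st, b$gt$ss, set,
                 anneal_schedule(moves_per_temp = 300, seed = seed))
    ca_rmsd(f$model, b$gt$structure)
  }
  seeds <- 1:3
  expect_lt(median(vapply(seeds, function(s) rms(rich, s), numeric(1))),
            median(vapply(seeds, function(s) rms(poor, s), numeric(1))))
})

test_that("local minimization never raises the score and relieves clashes", {
  b <- get_bundle()
  rs <- get_restraints()
  st <- init_conformation(60, b$gt$ss, template = toy_template(), seed = 3)
  f <- mc_fold(st, b$gt$ss, rs, anneal_schedule(moves_per_temp = 120, seed = 3))
  m <- minimize_fold(f, b$gt$ss, rs, n_steps = 150, seed = 3)
  expect_lte(m$score$s_total, f$score$s_total + 1e-9)
  ## a deliberate loop clash is relieved
  clash <- f$subunit
  clash[30, ] <- clash[45, ] + c(2, 0, 0)
  fc <- f; fc$subunit <- clash
  fc$model <- symmetrize_c5(flexfold:::subunit_from_xyz(clash, 1:60))
  fc$score <- total_score(fc$model, rs, b$gt$ss)
  m2 <- minimize_fold(fc, b$gt$ss, rs, n_steps = 400, seed = 8)
  pc <- flexfold:::pentamer_ca(m2$model)
  dm <- as.matrix(dist(pc$xyz)); diag(dm) <- Inf
  expect_gt(min(dm[30, c(45, 45 + 60)]), 3.0)
  expect_lt(m2$score$s_total, fc$score$s_total)
})
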