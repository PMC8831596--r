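test_that("toy pentamer construction is deterministic, C5 and low-strain", {
  gt1 <- build_toy_pentamer(seed = 7)
  gt2 <- build_toy_pentamer(seed = 7)
  expect_identical(gt1$subunit, gt2$subunit)
  ## exact C5: chain B equals chain A rotated by 72 degrees
  pA <- flexfold:::ca_coords(gt1$structure, chain = "A")
  pB <- flexfold:::ca_coords(gt1$structure, chain = "B")
  expect_lt(max(abs(pA %*% t(rot3(c(0, 0, 1), 2 * pi / 5)) - pB)), 1e-9)
  ## helix bonds exact, all virtual bonds near 3.8
  bonds <- sqrt(rowSums(diff(gt1$subunit)^2))
  expect_true(all(abs(bonds - 3.8) < 0.01))
  ## anchored loop: anchor residue sits against the long helix
  plan <- gt1$plan
  anchor <- gt1$subunit[plan$anchor_residue, ]
  helix_b <- gt1$subunit[plan$helix_b, ]
  expect_lt(min(sqrt(rowSums(sweep(helix_b, 2, anchor)^2))), 8)
  ## order parameters encode segment rigidity
  expect_true(all(gt1$dynamics$s2[gt1$ss == "H"] == 0.85))
  expect_true(all(gt1$dynamics$s2[gt1$ss != "H"] == 0.30))
  expect_error(build_toy_pentamer(list(helix_a = 1:10, loop = 11:20,
                                       helix_b = 21:30, label_sites = 5,
                                       deer_labels = 25, anchor_residue = 15)),
               "40-120")
})

test_that("forward PRE covers both window limits and inverts exactly", {
  gt <- get_bundle()$gt
  p <- pre_params()
  tab <- forward_pre(gt, 30, p, noise = NULL)
  ratio <- tab$intensity[tab$condition == "paramagnetic"] /
    tab$intensity[tab$condition == "diamagnetic"]
  truth_d <- sqrt(rowSums(sweep(gt$subunit, 2, gt$subunit[30, ])^2))[-30]
  ## distal residues look unbroadened, proximal ones vanish
  expect_true(all(ratio[truth_d > 40] > p$ratio_ceiling))
  expect_true(all(ratio[truth_d < 10] < p$ratio_floor))
  rs <- pre_table_to_restraints(tab, 30, p)
  two <- !is.na(rs$d0)
  expect_lt(max(abs(rs$d0[two] - truth_d[match(rs$res_b[two],
                                               setdiff(1:60, 30))])), 1e-6)
})

test_that("forward DEER places pentagon modes at the true ring distances", {
  gt <- get_bundle()$gt
  for (radius_site in c(50, 30)) {
    d <- forward_deer(gt, radius_site, width = 2.5)
    site <- gt$subunit[radius_site, ]
    d_adj <- sqrt(sum((site - site %*% t(rot3(c(0, 0, 1), 2 * pi / 5)))^2))
    expect_equal(d$r[which.max(d$p)], d_adj, tolerance = 1)
    m <- split_pentamer_modes(d)
    expect_equal(m$adjacent[["d0"]], d_adj, tolerance = 0.1)
    expect_equal(m$adjacent[["width"]], 2.5, tolerance = 0.25)
    expect_equal(m$diagonal[["d0"]] / m$adjacent[["d0"]],
                 2 * cos(36 * pi / 180), tolerance = 0.02)
  }
})

test_that("model-free forward relaxation matches fits and NOE signs", {
  gt <- get_bundle()$gt
  fwd <- forward_relaxation(gt, noise = NULL)
  ## rigid helix residues: positive NOE; fast loop residues: negative
  noes <- fwd$truth$noe
  expect_true(all(noes[gt$ss == "H"] > 0))
  expect_true(all(noes[gt$ss != "H"] < 0))
  ## exported decay series round-trip through the exponential fit
  for (rn in c(10, 30)) {
    s2 <- fwd$r2_series[fwd$r2_series$residue == rn, ]
    fit <- fit_relaxation_rate(list(delays = s2$delay_s,
                                    intensities = s2$intensity))
    expect_equal(fit$rate, fwd$truth$r2[rn], tolerance = 1e-6)
    s1 <- fwd$r1_series[fwd$r1_series$residue == rn, ]
    fit1 <- fit_relaxation_rate(list(delays = s1$delay_s,
                                     intensities = s1$intensity))
    expect_equal(fit1$rate, fwd$truth$r1[rn], tolerance = 1e-6)
  }
  ## saturation pairs reproduce the NOE through compute_hetnoe
  het <- fwd$hetnoe
  got <- compute_hetnoe(het[het$residue == 25 & het$condition == "saturated", ],
                        het[het$residue == 25 & het$condition == "unsaturated", ])
  expect_equal(got$noe, fwd$truth$noe[25], tolerance = 1e-9)
})

test_that("forward RDC hits the tensor limits and inverts through IPAP", {
  gt <- get_bundle()$gt
  ## theta = 0 (NH along z): D = 2 Da; magic angle with R = 0: D = 0
  gz <- gt
  gz$subunit <- cbind(0, 0, 3.8 * seq_len(10))
  fr <- forward_rdc(gz, da = 8, rhombicity = 0, noise = NULL)
  expect_equal(unique(round(fr$truth$d_hz, 9)), 16)
  magic <- acos(1 / sqrt(3))
  gm <- gt
  gm$subunit <- cbind(3.8 * sin(magic) * seq_len(10), 0,
                      3.8 * cos(magic) * seq_len(10))
  fr2 <- forward_rdc(gm, da = 8, rhombicity = 0, noise = NULL)
  expect_lt(max(abs(fr2$truth$d_hz)), 1e-9)
})

test_that("temperature series reproduce the hydrogen-bond map at zero noise", {
  gt <- get_bundle()$gt
  tn <- forward_temp_and_noe(gt, noise = NULL)
  flags <- vapply(seq_along(gt$hbond_map), function(i)
    temperature_coefficient(tn$temp_series[tn$temp_series$residue == i, ])$hbond_flag,
    logical(1))
  expect_identical(flags, gt$hbond_map)
  ## NOE list: helix-diagnostic i,i+3 contacts present (at CA resolution the
  ## i,i+4 pair sits just above the 5.5 A cutoff); nothing beyond 5.5 A
  noe <- tn$noe_peaks
  expect_true(any(noe$residue_j - noe$residue_i == 3))
  dm <- as.matrix(dist(gt$subunit))
  expect_true(all(dm[cbind(noe$residue_i, noe$residue_j)] < 5.5))
})

test_that("shift tables drive the annotation back to the generating one", {
  gt <- get_bundle()$gt
  expect_identical(as.vector(ss_from_shifts(forward_shifts(gt))), gt$ss)
})

test_that("bundles are reproducible and internally consistent", {
  d1 <- file.path(tempdir(), "bb1"); d2 <- file.path(tempdir(), "bb2")
  b1 <- make_bundle(d1, master_seed = 3)
  b2 <- make_bundle(d2, master_seed = 3)
  expect_identical(b1$manifest$md5, b2$manifest$md5)
  ## manifest lists every written file with its checksum
  expect_true(all(file.exists(file.path(d1, b1$manifest$file))))
  expect_identical(vapply(file.path(d1, b1$manifest$file), function(p)
    as.character(tools::md5sum(p)), character(1), USE.NAMES = FALSE),
    b1$manifest$md5)
  ## a different seed changes the data
  b3 <- make_bundle(file.path(tempdir(), "bb3"), master_seed = 4)
  expect_false(identical(b1$manifest$md5, b3$manifest$md5))
  ## derived restraints are satisfied by the generating structure
  rs <- derive_restraints(b1)
  expect_gt(sum(rs$kind == "PRE" & !is.na(rs$d0)), 60)
  expect_equal(sum(rs$kind == "DEER"), 2 * length(b1$gt$deer_labels))
  sc <- total_score(b1$gt$structure, rs, b1$gt$ss)
  expect_lt(sc$s_noe, 1)
  expect_lt(sc$s_deer, 0.5)
})
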