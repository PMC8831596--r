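test_that("exponential relaxation fits recover noiseless and noisy rates", {
  delays <- c(16, 48, 96, 160, 240, 320, 480, 640) / 1000
  fit <- fit_relaxation_rate(list(residue = 7, delays = delays,
                                  intensities = 100 * exp(-2 * delays)))
  expect_true(fit$ok)
  expect_equal(fit$rate, 2, tolerance = 1e-8)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  ## noiseless exactness across the physiological rate range
  for (r in c(0.1, 1, 10, 50)) {
    f <- fit_relaxation_rate(list(delays = delays,
                                  intensities = 50 * exp(-r * delays)))
    expect_equal(f$rate, r, tolerance = 1e-7)
  }
  ## degenerate series
  expect_false(fit_relaxation_rate(list(delays = delays,
                                        intensities = rep(5, 8)))$ok)
  expect_error(fit_relaxation_rate(list(delays = delays[1:3],
                                        intensities = 1:3)), "at least 4")
  ## simulation: mean recovered rate within 2 standard errors of the truth
  set.seed(42)
  rates <- replicate(500, {
    y <- 100 * exp(-2 * delays) + rnorm(length(delays), 0, 2)
    fit_relaxation_rate(list(delays = delays, intensities = y))$rate
  })
  expect_lt(abs(mean(rates, na.rm = TRUE) - 2),
            2 * sd(rates, na.rm = TRUE) / sqrt(sum(!is.na(rates))))
})

test_that("heteronuclear NOE ratios and uncertainties propagate correctly", {
  mk <- function(i, s = 0) list(residue = 1, intensity = i, noise = s)
  expect_equal(compute_hetnoe(mk(70), mk(70))$noe, 1)
  expect_equal(compute_hetnoe(mk(-30), mk(100))$noe, -0.3)
  r <- compute_hetnoe(mk(50, 5), mk(100, 5))
  expect_equal(r$noe, 0.5)
  expect_equal(r$sigma, 0.5 * sqrt(0.01 + 0.0025), tolerance = 1e-12)
  expect_error(compute_hetnoe(mk(10), mk(0)), "zero unsaturated")
})

test_that("temperature coefficients flag hydrogen bonding by magnitude", {
  mk <- function(slope_ppb) {
    t <- 273.15 + c(25, 30, 35, 40, 45)
    data.frame(residue = 1, temperature = t,
               shift_h_ppm = 8 + slope_ppb * (t - t[1]) / 1000)
  }
  r <- temperature_coefficient(mk(-3))
  expect_equal(r$coefficient, -3, tolerance = 1e-9)
  expect_true(r$hbond_flag)
  expect_false(temperature_coefficient(mk(-6))$hbond_flag)
  flat <- temperature_coefficient(mk(0))
  expect_equal(flat$coefficient, 0, tolerance = 1e-9)
  expect_true(flat$hbond_flag)
  ## threshold sweep: the flag depends only on |slope| vs threshold
  for (s in c(-8, -5, -4.4, -2, 2, 5)) {
    for (th in c(3, 4.5, 6)) {
      expect_identical(temperature_coefficient(mk(s), threshold = th)$hbond_flag,
                       abs(s) < th)
    }
  }
  expect_error(temperature_coefficient(
    data.frame(temperature = c(298, 303), shift_h_ppm = c(8, 8))), "at least 3")
})

test_that("intensity-ratio inversion round-trips the two-condition model", {
  expect_equal(r2sp_from_ratio(1, 20), 0)
  r2dia <- 50
  fwd <- flexfold:::pre_ratio(50, r2dia, 0.010)
  expect_equal(fwd, 50 * exp(-0.5) / 100, tolerance = 1e-12)
  expect_equal(r2sp_from_ratio(fwd, r2dia / pi, 0.010), 50, tolerance = 1e-6)
  ## monotonicity on a ratio grid
  rsp <- vapply(seq(0.05, 0.95, by = 0.1), r2sp_from_ratio,
                numeric(1), linewidth_dia = 20, t_evol = 0.01)
  expect_true(all(diff(rsp) < 0))
  expect_error(r2sp_from_ratio(1.2, 20), "ratio > 1")
  expect_error(r2sp_from_ratio(-0.1, 20), "vanished")
})

test_that("Solomon-Bloembergen conversion inverts exactly and scales as r^-6", {
  p <- pre_params()
  for (r in c(8, 12, 15, 22, 35)) {
    expect_equal(pre_distance(sb_rate(r, p), p), r, tolerance = 1e-9)
  }
  r1 <- pre_distance(10, p)
  expect_equal(pre_distance(20, p) / r1, 2^(-1 / 6), tolerance = 1e-12)
  ## tau_c -> 0 limit: vanishing enhancement prefactor pushes r -> 0
  expect_lt(pre_distance(10, pre_params(tau_c = 1e-25)), 0.1)
  expect_lt(pre_distance(10, pre_params(tau_c = 1e-15)),
            pre_distance(10, pre_params(tau_c = 1e-12)))
  expect_error(pre_distance(-1, p), "positive")
})

test_that("PRE tables map to window-rule restraints that recover distances", {
  p <- pre_params()
  mk_tab <- function(ratio) {
    rbind(data.frame(residue = 5, condition = "paramagnetic",
                     intensity = 100 * ratio, linewidth_hz = NA,
                     shift_h_ppm = NA, shift_n_ppm = NA, noise = 0),
          data.frame(residue = 5, condition = "diamagnetic", intensity = 100,
                     linewidth_hz = 20, shift_h_ppm = NA, shift_n_ppm = NA,
                     noise = 0))
  }
  hi <- pre_table_to_restraints(mk_tab(0.95), 1, p)
  expect_true(is.na(hi$d0) && is.infinite(hi$upper) && hi$lower > 0)
  lo <- pre_table_to_restraints(mk_tab(0.02), 1, p)
  expect_true(is.na(lo$d0) && lo$lower == 0 && is.finite(lo$upper))
  ## forward round trip on the synthetic ground truth
  gt <- get_bundle()$gt
  lab <- gt$label_sites[2]
  rs <- pre_table_to_restraints(forward_pre(gt, lab, p, noise = NULL), lab, p)
  two <- !is.na(rs$d0)
  truth_d <- sqrt(rowSums(sweep(gt$subunit, 2, gt$subunit[lab, ])^2))
  expect_gt(sum(two), 5)
  expect_lt(max(abs(rs$d0[two] - truth_d[rs$res_b[two]])), 1e-6)
  expect_warning(pre_table_to_restraints(mk_tab(0.5)[1, ], 1, p), "unmatched")
})

test_that("IPAP splittings difference out to the dipolar coupling", {
  mk <- function(sn) list(residue = 3, shift_n_ppm = sn, noise = 0)
  n_mhz <- 700 * flexfold:::GAMMA_N_OVER_H
  r <- rdc_from_ipap(mk(120 + 95 / 2 / n_mhz), mk(120 - 95 / 2 / n_mhz),
                     mk(120 + 93 / 2 / n_mhz), mk(120 - 93 / 2 / n_mhz))
  expect_equal(r$d_hz, 2, tolerance = 1e-9)
  same <- rdc_from_ipap(mk(120.4), mk(119.6), mk(120.4), mk(119.6))
  expect_equal(same$d_hz, 0, tolerance = 1e-12)
  expect_error(rdc_from_ipap(mk(120), mk(119), mk(120), list(residue = 3)),
               "missing member")
  ## synthetic tensor forward model round-trips through the quartets
  gt <- get_bundle()$gt
  fr <- forward_rdc(gt, da = 8, rhombicity = 0.3, noise = NULL)
  q <- fr$quartets
  for (rn in fr$truth$residue[c(2, 10, 25)]) {
    pick <- function(cond) q[q$residue == rn & q$condition == cond, ]
    got <- rdc_from_ipap(pick("para_inphase"), pick("para_antiphase"),
                         pick("dia_inphase"), pick("dia_antiphase"))
    expect_equal(got$d_hz, fr$truth$d_hz[fr$truth$residue == rn],
                 tolerance = 1e-9)
  }
})

test_that("NOE classes map to the flat-bottom bound table", {
  rs <- noes_to_restraints(data.frame(residue_i = 10, residue_j = 14,
                                      class = "strong"))
  expect_equal(rs$upper, 3.5)
  expect_equal(rs$lower, 1.8)
  expect_identical(rs$potential, "flat-bottom")
  expect_equal(nrow(noes_to_restraints(
    data.frame(residue_i = integer(0), residue_j = integer(0),
               class = character(0)))), 0)
  expect_error(noes_to_restraints(data.frame(residue_i = 1, residue_j = 2,
                                             class = "huge")), "unknown")
  ## contacts generated from a structure are satisfied by that structure
  gt <- get_bundle()$gt
  noe <- forward_temp_and_noe(gt)$noe_peaks
  rs2 <- noes_to_restraints(noe)
  d <- restraint_distances(gt$structure, rs2)
  expect_true(all(d <= rs2$upper + 1e-9 & d >= rs2$lower - 1e-9))
})
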