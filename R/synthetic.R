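## Synthetic study system: a toy C5 pentamer with two long helices and one
## anchored flexible loop per subunit, plus forward models of every
## observable the pipeline consumes.  All noise is seeded; at zero noise
## every forward/inverse pair in the pipeline closes numerically.

#' Noise model for forward-simulated observables
#'
#' @param intensity_cv multiplicative coefficient of variation of peak
#'   intensities.
#' @param shift_jitter_ppm additive Gaussian jitter on chemical shifts (ppm).
#' @param seed RNG seed recorded with the model.
#' @return list of class `ff_noise`.
#' @export
noise_model <- function(intensity_cv = 0.02, shift_jitter_ppm = 0.002,
                        seed = 1) {
  stopifnot(intensity_cv >= 0, shift_jitter_ppm >= 0)
  structure(list(intensity_cv = intensity_cv,
                 shift_jitter_ppm = shift_jitter_ppm, seed = as.integer(seed)),
            class = "ff_noise")
}

#' Default segment plan of the toy subunit
#'
#' Two 20-residue helices (a transmembrane-like anchor and a long
#' membrane-associated-like helix) joined by a 20-residue flexible loop whose
#' middle residue is anchored near the long helix, echoing the
#' helix-loop-helix architecture of a receptor intracellular domain.
#'
#' Label placement mirrors the study design: single-cysteine nitroxide
#' labels spread along the sequence (about one per seven residues) for
#' intra-subunit PRE, and four of them additionally probed by inter-subunit
#' DEER to supply the quaternary restraints that orient the subunit in the
#' ring.
#'
#' @return list with `helix_a`, `loop`, `helix_b` residue index vectors,
#'   PRE `label_sites` and DEER-labeled residues `deer_labels`.
#' @export
toy_segment_plan <- function() {
  list(helix_a = 1:20, loop = 21:40, helix_b = 41:60,
       label_sites = c(5, 12, 18, 25, 30, 35, 45, 52, 58),
       deer_labels = c(5, 30, 45, 58),
       anchor_residue = 30)
}

#' Build the toy ground-truth pentamer
#'
#' Ideal CA helices placed on a ring about the z axis; the loop is a seeded
#' guided self-avoiding walk routed through a waypoint near the long helix
#' (so the anchor residue sits within 8 A of it), then the subunit is
#' replicated to exact C5.  Order parameters are 0.85 in helices and 0.3 in
#' the loop.
#'
#' @param plan segment plan (see [toy_segment_plan]).
#' @param seed RNG seed; the structure is deterministic given it.
#' @return list of class `ff_groundtruth`: `structure` (pentamer),
#'   `subunit` (CA matrix), `ss`, `dynamics` (residue, s2, tau_e),
#'   `hbond_map`, `label_sites`, `deer_label`, `frame`, `plan`.
#' @export
build_toy_pentamer <- function(plan = toy_segment_plan(), seed = 42) {
  n <- max(plan$helix_b)
  if (n < 40 || n > 120) stop("segment plan must total 40-120 residues/subunit")
  ss <- rep("C", n)
  ss[plan$helix_a] <- "H"
  ss[plan$helix_b] <- "H"
  xyz <- with_seed(seed, {
    out <- matrix(NA_real_, n, 3)
    ## helix A: descending, axis on the ring at radius 15
    out[plan$helix_a, ] <- ideal_ca_helix(length(plan$helix_a),
                                          origin = c(15, 0, 28),
                                          direction = c(0, 0, -1))
    ## helix B: ascending, nearer the axis, rotated off helix A
    axis_b <- 11 * c(cos(-0.5), sin(-0.5))
    out[plan$helix_b, ] <- ideal_ca_helix(length(plan$helix_b),
                                          origin = c(axis_b, -33),
                                          direction = c(0, 0, 1),
                                          phase = pi / 3)
    ## waypoint 6 A outside the helix-B axis at mid-height anchors the loop
    way <- c(axis_b * (1 + 6 / 11), -18)
    start <- out[plan$helix_a[length(plan$helix_a)], ]
    target <- out[plan$helix_b[1], ]
    ## approach standoff: one bond out from the helix-B start, radially away
    ## from the helix-B axis, so the closure does not thread into the helix
    standoff <- target + 4.2 * unit(target - c(axis_b, target[3]))
    nl <- length(plan$loop)
    n1 <- floor(nl / 2)
    avoid <- rbind(out[plan$helix_a, ], out[plan$helix_b, ])
    avoid <- rbind(avoid,
                   avoid %*% t(C5_ROTS[[2]]), avoid %*% t(C5_ROTS[[5]]))
    ## rejection-sample loop conformations: keep the first attempt whose C5
    ## assembly is essentially strain-free, or the best of 60 attempts
    best_loop <- NULL; best_e <- Inf
    for (attempt in 1:60) {
      loop_xyz <- guided_walk(start,
                              legs = list(
                                list(n = n1, target = way, arrive = 3.0),
                                list(n = nl - n1 - 1, target = standoff,
                                     arrive = 2.5),
                                list(n = 1, target = target,
                                     arrive = 3.8, close = TRUE)),
                              avoid = avoid,
                              prev = out[plan$helix_a[length(plan$helix_a) - 1], ])
      cand <- out
      cand[plan$loop, ] <- loop_xyz
      pent <- replicate_c5_xyz(cand)
      cfg <- score_config()
      e <- cpp_cg_energy(pent, rep(1:5, each = n), rep(as.integer(ss == "H"), 5),
                         cfg$k_bond, cfg$bond_length,
                         cfg$k_angle, cfg$angle_lo * pi / 180,
                         cfg$angle_hi * pi / 180,
                         cfg$k_rep, cfg$rep_onset,
                         cfg$k_dihedral, cfg$helix_tau * pi / 180)[1]
      ## also require the loop anchor to sit near the long helix
      anchor_ok <- min(sqrt(rowSums(sweep(out[plan$helix_b, ], 2,
                                          loop_xyz[plan$anchor_residue -
                                                   plan$loop[1] + 1, ])^2))) < 8
      if (anchor_ok && e < best_e) { best_e <- e; best_loop <- loop_xyz }
      if (anchor_ok && e < 5) break
    }
    out[plan$loop, ] <- best_loop
    out
  })
  dyn <- data.frame(residue = 1:n,
                    s2 = ifelse(ss == "H", 0.85, 0.30),
                    tau_e = ifelse(ss == "H", 500e-12, 50e-12))
  structure(list(structure = symmetrize_c5(subunit_from_xyz(xyz, 1:n)),
                 subunit = xyz, ss = ss, dynamics = dyn,
                 hbond_map = ss == "H",
                 label_sites = plan$label_sites,
                 deer_labels = plan$deer_labels,
                 frame = symmetry_frame(), plan = plan),
            class = "ff_groundtruth")
}

## multiplicative intensity noise helper (uses current RNG stream)
jitter_intensity <- function(x, cv) x * (1 + rnorm(length(x), 0, cv))

#' Forward-model a PRE experiment from the ground truth
#'
#' For each residue the label-to-amide distance (CA proxies) is pushed
#' through the Solomon-Bloembergen relation and the two-condition intensity
#' model, emitting paired paramagnetic/diamagnetic peak records.
#'
#' @param gt [build_toy_pentamer] output.
#' @param label_residue labeled residue.
#' @param p [pre_params].
#' @param noise [noise_model]; `NULL` for noiseless.
#' @param i0 diamagnetic reference intensity.
#' @param linewidth_dia diamagnetic linewidth (Hz).
#' @return Peak table (see [read_peak_table] for the columns).
#' @export
forward_pre <- function(gt, label_residue, p = pre_params(), noise = NULL,
                        i0 = 100, linewidth_dia = 20) {
  xyz <- gt$subunit
  if (!label_residue %in% seq_len(nrow(xyz))) stop("no such label site")
  r <- sqrt(rowSums(sweep(xyz, 2, xyz[label_residue, ])^2))
  r[label_residue] <- NA
  ratio <- rep(NA_real_, length(r))
  ok <- !is.na(r) & r > 0
  ratio[ok] <- pre_ratio(sb_rate(pmax(r[ok], 1e-6), p), pi * linewidth_dia,
                         p$t_evol)
  resn <- which(ok)
  cv <- if (is.null(noise)) 0 else noise$intensity_cv
  tab <- with_seed(if (is.null(noise)) NULL else noise$seed, {
    rbind(
      data.frame(residue = resn, condition = "paramagnetic",
                 intensity = jitter_intensity(i0 * ratio[resn], cv),
                 linewidth_hz = NA_real_, shift_h_ppm = NA_real_,
                 shift_n_ppm = NA_real_, noise = cv * i0),
      data.frame(residue = resn, condition = "diamagnetic",
                 intensity = jitter_intensity(rep(i0, length(resn)), cv),
                 linewidth_hz = linewidth_dia, shift_h_ppm = NA_real_,
                 shift_n_ppm = NA_real_, noise = cv * i0))
  })
  tab[order(tab$residue, tab$condition), ]
}

#' Forward-model a DEER distance distribution
#'
#' Equal-weight mixture of two Gaussians at the adjacent and diagonal
#' inter-label distances of the C5 ring (5 adjacent and 5 diagonal pairs).
#'
#' @param gt ground truth.
#' @param label_residue spin-labeled residue.
#' @param width Gaussian width (Angstrom) of both modes.
#' @param noise [noise_model]; adds multiplicative density noise.
#' @param r_grid distance grid (Angstrom).
#' @return `ff_deer_dist`.
#' @export
forward_deer <- function(gt, label_residue, width = 2.5, noise = NULL,
                         r_grid = seq(5, 60, by = 0.25)) {
  site <- gt$subunit[label_residue, ]
  d_adj <- vnorm(site - as.numeric(site %*% t(C5_ROTS[[2]])))
  d_diag <- vnorm(site - as.numeric(site %*% t(C5_ROTS[[3]])))
  p <- 0.5 * dnorm(r_grid, d_adj, width) + 0.5 * dnorm(r_grid, d_diag, width)
  if (!is.null(noise))
    p <- with_seed(noise$seed + 1L,
                   pmax(0, jitter_intensity(p, noise$intensity_cv)))
  p <- p / (sum(p) * (r_grid[2] - r_grid[1]))
  structure(list(r = r_grid, p = p), class = "ff_deer_dist")
}

## ---- relaxation forward model (model-free spectral density) --------------

GAMMA_H <- 2.6752218744e8   # rad/s/T
GAMMA_N <- -2.7126e7        # rad/s/T (15N, negative)
R_NH <- 1.02e-10            # m
CSA_N <- -160e-6            # 15N chemical-shift anisotropy

jw <- function(omega, s2, tau_m, tau_e) {
  taup <- 1 / (1 / tau_m + 1 / tau_e)
  0.4 * (s2 * tau_m / (1 + (omega * tau_m)^2) +
         (1 - s2) * taup / (1 + (omega * taup)^2))
}

#' Model-free 15N relaxation parameters
#'
#' Lipari-Szabo spectral density with overall tumbling `tau_m` and
#' per-residue (S2, tau_e); standard dipolar + CSA expressions for 15N R1,
#' R2 and the 15N-(1H) steady-state NOE.
#'
#' @param s2 order parameter in `[0, 1]`.
#' @param tau_e internal correlation time (s).
#' @param tau_m overall correlation time (s).
#' @param field_mhz 1H frequency (MHz).
#' @return list with `r1`, `r2`, `noe` (rates in s^-1, NOE unitless).
#' @export
model_free_rates <- function(s2, tau_e, tau_m = 15e-9, field_mhz = 700) {
  wh <- 2 * pi * field_mhz * 1e6
  wn <- wh * abs(GAMMA_N) / GAMMA_H
  d <- 1e-7 * 1.054571817e-34 * GAMMA_H * abs(GAMMA_N) / R_NH^3
  cc <- wn * abs(CSA_N) / sqrt(3)
  J <- function(w) jw(w, s2, tau_m, tau_e)
  r1 <- (d^2 / 4) * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + cc^2 * J(wn)
  r2 <- (d^2 / 8) * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                     6 * J(wh + wn)) +
        (cc^2 / 6) * (4 * J(0) + 3 * J(wn))
  noe <- 1 + (d^2 / 4) * (GAMMA_H / GAMMA_N) *
    (6 * J(wh + wn) - J(wh - wn)) / r1
  list(r1 = r1, r2 = r2, noe = noe)
}

#' Forward-model relaxation decay series and saturation pairs
#'
#' Exports per-residue R1 and R2 decay series on the standard delay grids
#' (20-1500 ms and 16-640 ms) and saturated/unsaturated intensity pairs
#' whose ratio is the model-free heteronuclear NOE.
#'
#' @param gt ground truth (supplies per-residue S2 and tau_e).
#' @param tau_m overall correlation time (s).
#' @param field_mhz 1H frequency (MHz).
#' @param noise [noise_model] or `NULL`.
#' @param i0 reference intensity.
#' @return list with `r1_series`, `r2_series` (long data.frames: residue,
#'   delay_s, intensity, noise), `hetnoe` (peak table with
#'   saturated/unsaturated rows) and `truth` (residue, r1, r2, noe).
#' @export
forward_relaxation <- function(gt, tau_m = 15e-9, field_mhz = 700,
                               noise = NULL, i0 = 100) {
  delays_r1 <- c(20, 100, 200, 400, 600, 800, 1100, 1500) / 1000
  delays_r2 <- c(16, 48, 96, 160, 240, 320, 480, 640) / 1000
  dyn <- gt$dynamics
  rates <- lapply(seq_len(nrow(dyn)), function(i)
    model_free_rates(dyn$s2[i], dyn$tau_e[i], tau_m, field_mhz))
  truth <- data.frame(residue = dyn$residue,
                      r1 = vapply(rates, `[[`, numeric(1), "r1"),
                      r2 = vapply(rates, `[[`, numeric(1), "r2"),
                      noe = vapply(rates, `[[`, numeric(1), "noe"))
  cv <- if (is.null(noise)) 0 else noise$intensity_cv
  with_seed(if (is.null(noise)) NULL else noise$seed + 2L, {
    series <- function(delays, rate_col) {
      do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
        data.frame(residue = truth$residue[i], delay_s = delays,
                   intensity = jitter_intensity(
                     i0 * exp(-truth[[rate_col]][i] * delays), cv),
                   noise = cv * i0)))
    }
    r1s <- series(delays_r1, "r1")
    r2s <- series(delays_r2, "r2")
    het <- rbind(
      data.frame(residue = truth$residue, condition = "saturated",
                 intensity = jitter_intensity(i0 * truth$noe, cv),
                 linewidth_hz = NA_real_, shift_h_ppm = NA_real_,
                 shift_n_ppm = NA_real_, noise = cv * i0),
      data.frame(residue = truth$residue, condition = "unsaturated",
                 intensity = jitter_intensity(rep(i0, nrow(truth)), cv),
                 linewidth_hz = NA_real_, shift_h_ppm = NA_real_,
                 shift_n_ppm = NA_real_, noise = cv * i0))
    list(r1_series = r1s, r2_series = r2s, hetnoe = het, truth = truth)
  })
}

#' Forward-model RDCs and IPAP quartets
#'
#' NH orientations are taken as the local backbone direction
#' (CA(i-1) -> CA(i+1)); couplings follow
#' `D = Da * ((3 cos^2 theta - 1) + 1.5 R sin^2 theta cos 2 phi)` in the
#' alignment-tensor frame, and quartets carry 15N splittings `J + D`
#' (aligned) and `J` (isotropic) around 120 ppm.
#'
#' @param gt ground truth.
#' @param da axial alignment magnitude (Hz).
#' @param rhombicity tensor rhombicity in `[0, 2/3]`.
#' @param orientation 3x3 rotation into the tensor frame.
#' @param j_hz scalar coupling (Hz).
#' @param field_mhz 1H frequency (MHz).
#' @param noise [noise_model] (shift jitter) or `NULL`.
#' @return list with `truth` (residue, d_hz) and `quartets` (peak table with
#'   inphase/antiphase rows per paramagnetic/diamagnetic arm, conditions
#'   `para_inphase` etc.).
#' @export
forward_rdc <- function(gt, da = 8, rhombicity = 0.3, orientation = diag(3),
                        j_hz = 93, field_mhz = 700, noise = NULL) {
  stopifnot(rhombicity >= 0, rhombicity <= 2 / 3)
  xyz <- gt$subunit
  n <- nrow(xyz)
  res <- 2:(n - 1)
  nh <- t(vapply(res, function(i) unit(xyz[i + 1, ] - xyz[i - 1, ]),
                 numeric(3))) %*% t(orientation)
  ct <- nh[, 3]
  st2 <- pmax(0, 1 - ct^2)
  phi <- atan2(nh[, 2], nh[, 1])
  d_hz <- da * ((3 * ct^2 - 1) + 1.5 * rhombicity * st2 * cos(2 * phi))
  n_mhz <- field_mhz * GAMMA_N_OVER_H
  jit <- if (is.null(noise)) 0 else noise$shift_jitter_ppm
  quart <- with_seed(if (is.null(noise)) NULL else noise$seed + 3L, {
    base <- 120 + 0.02 * res
    mk <- function(cond, split_hz) {
      sgn <- if (grepl("inphase", cond)) 0.5 else -0.5
      data.frame(residue = res, condition = cond,
                 intensity = 100, linewidth_hz = NA_real_,
                 shift_h_ppm = NA_real_,
                 shift_n_ppm = base + sgn * split_hz / n_mhz +
                   rnorm(length(res), 0, jit),
                 noise = 0)
    }
    rbind(mk("para_inphase", j_hz + d_hz), mk("para_antiphase", j_hz + d_hz),
          mk("dia_inphase", j_hz), mk("dia_antiphase", j_hz))
  })
  list(truth = data.frame(residue = res, d_hz = d_hz), quartets = quart)
}

#' Forward-model amide temperature series and a NOE contact list
#'
#' Hydrogen-bonded residues draw temperature coefficients in (-4.4, -0.5)
#' ppb/K, others in (-9, -4.6); the NOE list contains all residue pairs
#' (|i - j| >= 2) with CA distance below 5.5 A, classed by distance.
#'
#' @param gt ground truth.
#' @param temps_k temperatures (K).
#' @param noise [noise_model] or `NULL`.
#' @return list with `temp_series` (residue, temperature, shift_h_ppm),
#'   `noe_peaks` (residue_i, residue_j, class), `coefficients` (truth,
#'   ppb/K).
#' @export
forward_temp_and_noe <- function(gt, temps_k = 273.15 + c(25, 30, 35, 40, 45),
                                 noise = NULL) {
  n <- length(gt$hbond_map)
  jit <- if (is.null(noise)) 0 else noise$shift_jitter_ppm
  out <- with_seed(if (is.null(noise)) 42L else noise$seed + 4L, {
    slope <- ifelse(gt$hbond_map, runif(n, -4.4, -0.5), runif(n, -9, -4.6))
    ts <- do.call(rbind, lapply(1:n, function(i)
      data.frame(residue = i, temperature = temps_k,
                 shift_h_ppm = 8.2 + 0.001 * i +
                   slope[i] * (temps_k - temps_k[1]) / 1000 +
                   rnorm(length(temps_k), 0, jit))))
    list(slope = slope, ts = ts)
  })
  xyz <- gt$subunit
  dm <- as.matrix(dist(xyz))
  pairs <- which(upper.tri(dm) & dm < 5.5, arr.ind = TRUE)
  pairs <- pairs[abs(pairs[, 1] - pairs[, 2]) >= 2, , drop = FALSE]
  d <- dm[pairs]
  noe <- data.frame(residue_i = pmin(pairs[, 1], pairs[, 2]),
                    residue_j = pmax(pairs[, 1], pairs[, 2]),
                    class = ifelse(d < 3.5, "strong",
                                   ifelse(d < 4.5, "medium", "weak")))
  noe <- noe[order(noe$residue_i, noe$residue_j), ]
  list(temp_series = out$ts, noe_peaks = noe,
       coefficients = data.frame(residue = 1:n, slope_ppb_k = out$slope))
}

#' Forward-model CA/CB shifts carrying the secondary structure
#'
#' Helical residues get +3 ppm CA secondary shifts (0 on CB), coil residues
#' random-coil values, plus jitter.
#'
#' @param gt ground truth.
#' @param noise [noise_model] or `NULL`.
#' @return data.frame (residue, resname, ca_ppm, cb_ppm).
#' @export
forward_shifts <- function(gt, noise = NULL) {
  n <- length(gt$ss)
  jit <- if (is.null(noise)) 0 else noise$shift_jitter_ppm * 50 # 13C scale
  with_seed(if (is.null(noise)) NULL else noise$seed + 5L, {
    data.frame(residue = 1:n, resname = "ALA",
               ca_ppm = RANDOM_COIL_CA[["ALA"]] +
                 ifelse(gt$ss == "H", 3, 0) + rnorm(n, 0, jit),
               cb_ppm = RANDOM_COIL_CB[["ALA"]] + rnorm(n, 0, jit))
  })
}

#' Write a complete synthetic bundle to disk
#'
#' Generates the toy ground truth and every forward-modeled observable and
#' writes them in the same plain-text dialects the pipeline reads, plus a
#' manifest with checksums.
#'
#' @param dir output directory (created).
#' @param master_seed master RNG seed; the bundle is reproducible given it.
#' @param noise [noise_model]; its seed is overridden from `master_seed`.
#' @return list of class `ff_bundle`: `dir`, `gt`, `files` (named paths),
#'   `manifest` (file, md5).
#' @export
make_bundle <- function(dir = tempfile("bundle"), master_seed = 1,
                        noise = noise_model()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  noise$seed <- derive_seed(master_seed, 17)
  gt <- build_toy_pentamer(seed = derive_seed(master_seed, 1))
  files <- list()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files$truth_pdb <- file.path(dir, "truth.pdb")
  write_structure(gt$structure, files$truth_pdb)
  for (ls in gt$label_sites) {
    files[[paste0("pre_", ls)]] <-
      wr(forward_pre(gt, ls, noise = noise), sprintf("pre_%03d.tsv", ls))
  }
  for (dl in gt$deer_labels) {
    deer <- forward_deer(gt, dl, noise = noise)
    files[[paste0("deer_", dl)]] <- file.path(dir, sprintf("deer_%03d.dat", dl))
    write_distribution(deer, files[[paste0("deer_", dl)]])
  }
  relax <- forward_relaxation(gt, noise = noise)
  files$r1 <- wr(relax$r1_series, "r1_series.tsv")
  files$r2 <- wr(relax$r2_series, "r2_series.tsv")
  files$hetnoe <- wr(relax$hetnoe, "hetnoe.tsv")
  tn <- forward_temp_and_noe(gt, noise = noise)
  files$temp <- wr(tn$temp_series, "temp_series.tsv")
  files$noe <- wr(tn$noe_peaks, "noe_peaks.tsv")
  files$shifts <- wr(forward_shifts(gt, noise = noise), "shifts.tsv")
  truth_d <- do.call(rbind, lapply(gt$label_sites, function(ls) {
    r <- sqrt(rowSums(sweep(gt$subunit, 2, gt$subunit[ls, ])^2))
    data.frame(label = ls, residue = seq_along(r), distance = r)
  }))
  files$truth_distances <- wr(truth_d[truth_d$label != truth_d$residue, ],
                              "truth_distances.tsv")
  manifest <- data.frame(file = basename(unlist(files)),
                         md5 = vapply(unlist(files), function(p)
                           as.character(tools::md5sum(p)), character(1)))
  jsonlite::write_json(list(master_seed = master_seed,
                            noise = unclass(noise),
                            files = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$manifest <- file.path(dir, "manifest.json")
  structure(list(dir = dir, gt = gt, files = files, manifest = manifest),
            class = "ff_bundle")
}

#' Derive the working restraint set from a bundle directory
#'
#' Reads the PRE tables, DEER distribution and NOE list written by
#' [make_bundle] and converts them with the standard pipeline operations.
#'
#' @param bundle `ff_bundle` or a bundle directory path.
#' @param p [pre_params].
#' @return `ff_restraints` combining PRE, DEER and NOE restraints.
#' @export
derive_restraints <- function(bundle, p = pre_params()) {
  dir <- if (inherits(bundle, "ff_bundle")) bundle$dir else bundle
  pre_files <- list.files(dir, pattern = "^pre_[0-9]+\\.tsv$",
                          full.names = TRUE)
  pre <- lapply(pre_files, function(f) {
    lab <- as.integer(sub("^pre_0*([0-9]+)\\.tsv$", "\\1", basename(f)))
    pre_table_to_restraints(read_peak_table(f), lab, p)
  })
  deer_files <- list.files(dir, pattern = "^deer_[0-9]+\\.dat$",
                           full.names = TRUE)
  deer <- lapply(deer_files, function(f) {
    lab <- as.integer(sub("^deer_0*([0-9]+)\\.dat$", "\\1", basename(f)))
    deer_to_restraints(split_pentamer_modes(load_distribution(f)), lab)
  })
  noe <- noes_to_restraints(read.table(file.path(dir, "noe_peaks.tsv"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
  do.call(bind_restraints, c(pre, deer, list(noe)))
}

#' Deterministic architecture template for the toy system
#'
#' Encodes only the generic architecture of the study system (two
#' near-vertical helices on the C5 ring, the connecting loop a deterministic
#' strain-screened self-avoiding path with exact 3.8 A virtual bonds) and
#' none of a particular ground truth's loop conformation.  Used as the first-round
#' template of the iterative protocol, playing the role of the homolog
#' templates of comparative modeling; it also fixes the hand of the fold,
#' which pure distance restraints cannot (all restraint and coarse-grained
#' energies are invariant under mirror inversion of the subunit).
#'
#' @param plan segment plan (see [toy_segment_plan]).
#' @return Single-chain CA-level [ff_structure].
#' @export
toy_template <- function(plan = toy_segment_plan()) {
  n <- max(plan$helix_b)
  xyz <- matrix(NA_real_, n, 3)
  xyz[plan$helix_a, ] <- ideal_ca_helix(length(plan$helix_a),
                                        origin = c(15, 0, 28),
                                        direction = c(0, 0, -1))
  axis_b <- 11 * c(cos(-0.5), sin(-0.5))
  xyz[plan$helix_b, ] <- ideal_ca_helix(length(plan$helix_b),
                                        origin = c(axis_b, -33),
                                        direction = c(0, 0, 1), phase = pi / 3)
  A <- xyz[plan$loop[1] - 1, ]
  B <- xyz[max(plan$loop) + 1, ]
  nl <- length(plan$loop)
  standoff <- B + 4.2 * unit(B - c(axis_b, B[3]))
  avoid <- rbind(xyz[plan$helix_a, ], xyz[plan$helix_b, ])
  avoid <- rbind(avoid, avoid %*% t(C5_ROTS[[2]]), avoid %*% t(C5_ROTS[[5]]))
  ss <- rep("C", n); ss[plan$helix_a] <- "H"; ss[plan$helix_b] <- "H"
  ## deterministic (fixed internal seed), strain-screened loop without the
  ## ground truth's anchor waypoint
  xyz[plan$loop, ] <- with_seed(73L, {
    cfg <- score_config()
    best_loop <- NULL; best_e <- Inf
    for (attempt in 1:40) {
      loop_xyz <- guided_walk(A,
                              legs = list(
                                list(n = nl - 1, target = standoff,
                                     arrive = 2.5),
                                list(n = 1, target = B, arrive = 3.8,
                                     close = TRUE)),
                              avoid = avoid,
                              prev = xyz[plan$loop[1] - 2, ])
      cand <- xyz
      cand[plan$loop, ] <- loop_xyz
      pent <- replicate_c5_xyz(cand)
      e <- cpp_cg_energy(pent, rep(1:5, each = n),
                         rep(as.integer(ss == "H"), 5),
                         cfg$k_bond, cfg$bond_length,
                         cfg$k_angle, cfg$angle_lo * pi / 180,
                         cfg$angle_hi * pi / 180,
                         cfg$k_rep, cfg$rep_onset,
                         cfg$k_dihedral, cfg$helix_tau * pi / 180)[1]
      if (e < best_e) { best_e <- e; best_loop <- loop_xyz }
      if (e < 5) break
    }
    best_loop
  })
  subunit_from_xyz(xyz, seq_len(n))
}
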