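## Coarse-grained, C5-symmetric, restraint-guided conformational sampling.
##
## The asymmetric unit (one subunit, CA level) is sampled with pivot and
## crankshaft moves on loop/coil residues and rigid-body moves of the whole
## subunit; helical segments move as rigid bodies.  Every step the subunit is
## replicated about the fixed symmetry frame (z axis through the origin) and
## the full pentamer is scored, so emitted models are exactly C5-symmetric.

## random-coil 13C chemical shifts (ppm) used for secondary-shift scoring
RANDOM_COIL_CA <- c(ALA = 52.5, ARG = 56.0, ASN = 53.1, ASP = 54.2,
                    CYS = 58.2, GLN = 55.7, GLU = 56.6, GLY = 45.1,
                    HIS = 55.0, ILE = 61.1, LEU = 55.1, LYS = 56.2,
                    MET = 55.4, PHE = 57.7, PRO = 63.3, SER = 58.3,
                    THR = 61.8, TRP = 57.5, TYR = 57.9, VAL = 62.2)
RANDOM_COIL_CB <- c(ALA = 19.1, ARG = 30.9, ASN = 38.9, ASP = 41.1,
                    CYS = 28.0, GLN = 29.4, GLU = 29.9, GLY = NA,
                    HIS = 29.0, ILE = 38.8, LEU = 42.4, LYS = 33.1,
                    MET = 32.9, PHE = 39.6, PRO = 32.1, SER = 63.8,
                    THR = 69.8, TRP = 29.6, TYR = 38.8, VAL = 32.9)

#' Secondary structure from CA/CB secondary chemical shifts
#'
#' The per-residue secondary-shift score Delta-delta(CA) - Delta-delta(CB)
#' (observed minus random coil) is smoothed over a 3-residue window; runs of
#' at least 4 consecutive residues with smoothed score >= +1.4 ppm are called
#' helix (H), <= -1.4 ppm extended (E), everything else (and unassigned
#' residues) coil (C).
#'
#' @param shifts data.frame with columns `residue`, `resname`, `ca_ppm`,
#'   `cb_ppm` (`cb_ppm` may be `NA` for glycine).
#' @param n_res total residue count (residues absent from `shifts` are C).
#' @param threshold score threshold in ppm (default 1.4).
#' @param min_run minimum run length (default 4).
#' @return Character vector of length `n_res` over H/E/C, with attribute
#'   `source = "shift-derived"`.
#' @export
ss_from_shifts <- function(shifts, n_res = max(shifts$residue),
                           threshold = 1.4, min_run = 4) {
  if (nrow(shifts) < 0.7 * n_res)
    stop("need CA/CB shifts for at least 70% of residues")
  bad <- setdiff(unique(shifts$resname), names(RANDOM_COIL_CA))
  if (length(bad)) stop("no random-coil reference for: ", paste(bad, collapse = ", "))
  score <- rep(NA_real_, n_res)
  dca <- shifts$ca_ppm - RANDOM_COIL_CA[shifts$resname]
  dcb <- shifts$cb_ppm - RANDOM_COIL_CB[shifts$resname]
  dcb[is.na(dcb)] <- 0
  score[shifts$residue] <- dca - dcb
  sm <- score
  for (i in seq_len(n_res)) {
    w <- score[max(1, i - 1):min(n_res, i + 1)]
    sm[i] <- if (all(is.na(w))) NA else mean(w, na.rm = TRUE)
  }
  lab <- rep("C", n_res)
  for (sgn in c(1, -1)) {
    hit <- !is.na(sm) & sgn * sm >= threshold
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= min_run)
        lab[(ends[k] - r$lengths[k] + 1):ends[k]] <- if (sgn > 0) "H" else "E"
    }
  }
  attr(lab, "source") <- "shift-derived"
  lab
}

## contiguous runs of H in an annotation -> list of index vectors
helix_segments <- function(ss) {
  r <- rle(ss == "H")
  ends <- cumsum(r$lengths)
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) out[[length(out) + 1]] <- (ends[k] - r$lengths[k] + 1):ends[k]
  }
  out
}

#' Initial subunit conformation
#'
#' Helical segments are built as ideal CA helices in randomized orientations;
#' loop/coil stretches as seeded self-avoiding walks.  With a template, the
#' template is perturbed by a burst of random internal moves (pivot,
#' crankshaft, rigid-body) scaled by `perturb_sigma`; moves preserve virtual
#' bond lengths, so the perturbed start carries no bond strain.
#'
#' @param n_res number of residues (ignored with a template).
#' @param ss secondary-structure annotation (length `n_res`).
#' @param template optional [ff_structure] (single chain) to start from.
#' @param perturb_sigma template perturbation scale (Angstrom-equivalent;
#'   0 returns the template unchanged).
#' @param rebuild_loops with a template: resample interior flexible segments
#'   as fresh guided self-avoiding walks between the template's helix
#'   endpoints before perturbing.
#' @param seed RNG seed.
#' @param resno residue numbers (default `1:n_res`).
#' @return Single-chain CA-level [ff_structure].
#' @export
init_conformation <- function(n_res = NULL, ss, template = NULL,
                              perturb_sigma = 1.0, seed = 1,
                              resno = NULL, rebuild_loops = FALSE) {
  if (!is.null(template)) {
    xyz <- ca_coords(template)
    if (nrow(xyz) != length(ss)) stop("template length does not match annotation")
    flex <- which(ss != "H")
    xyz <- with_seed(seed, {
      if (rebuild_loops) {
        ## resample interior flexible segments as fresh self-avoiding walks
        ## between the template's anchor points (the fragment-insertion
        ## analog: pool diversity concentrates where the data must decide)
        for (sg in ss_runs(ss)) {
          idx <- sg$idx
          if (sg$helix || idx[1] == 1 || idx[length(idx)] == nrow(xyz)) next
          helix_xyz <- xyz[-idx, , drop = FALSE]
          avoid <- rbind(helix_xyz,
                         helix_xyz %*% t(C5_ROTS[[2]]),
                         helix_xyz %*% t(C5_ROTS[[5]]))
          xyz[idx, ] <- guided_walk(xyz[idx[1] - 1, ],
                                    legs = list(list(n = length(idx),
                                                     target = xyz[idx[length(idx)] + 1, ],
                                                     arrive = 3.8, close = TRUE)),
                                    avoid = avoid,
                                    prev = xyz[max(1, idx[1] - 2), ])
        }
      }
      for (k in seq_len(12)) {
        xyz <- propose_move(xyz, flex, sigma_rot = 0.08 * perturb_sigma,
                            sigma_tr = 0.4 * perturb_sigma)
      }
      xyz
    })
    return(subunit_from_xyz(xyz, resno %||% unique(template$atoms$resno)))
  }
  if (is.null(n_res)) n_res <- length(ss)
  if (n_res != length(ss)) stop("sequence length does not match annotation")
  xyz <- with_seed(seed, {
    out <- matrix(NA_real_, n_res, 3)
    segs <- ss_runs(ss)
    cur <- c(12, 0, 0) # start on the ring, off the symmetry axis
    prev_end <- NULL
    for (sg in segs) {
      idx <- sg$idx
      if (sg$helix) {
        dirn <- if (is.null(prev_end)) c(0, 0, -1) else random_unit_vector()
        start <- if (is.null(prev_end)) cur else prev_end + 3.8 * dirn
        h <- ideal_ca_helix(length(idx), origin = start, direction = dirn,
                            phase = runif(1, 0, 2 * pi))
        out[idx, ] <- h
      } else {
        start <- if (is.null(prev_end)) cur else prev_end
        walk <- matrix(NA_real_, length(idx), 3)
        p <- start
        for (j in seq_along(idx)) {
          p <- p + 3.8 * random_unit_vector()
          walk[j, ] <- p
        }
        out[idx, ] <- walk
      }
      prev_end <- out[idx[length(idx)], ]
    }
    out
  })
  subunit_from_xyz(xyz, resno %||% seq_len(n_res))
}

ss_runs <- function(ss) {
  r <- rle(ss == "H")
  ends <- cumsum(r$lengths)
  lapply(seq_along(r$values), function(k)
    list(helix = r$values[k], idx = (ends[k] - r$lengths[k] + 1):ends[k]))
}

subunit_from_xyz <- function(xyz, resno, chain = "A", resname = "ALA") {
  ff_structure(data.frame(chain = chain, resno = resno,
                          resname = rep(resname, length.out = nrow(xyz)),
                          atom = "CA", elem = "C",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE), resolution = "calpha")
}

#' Annealing schedule
#'
#' @param temps strictly decreasing temperature ladder (score units).
#' @param moves_per_temp Monte Carlo moves at each temperature.
#' @param sigma_rot,sigma_tr move sizes: pivot/rotation sigma (radians) and
#'   rigid-translation sigma (Angstrom).
#' @param rep_ramp per-temperature scale of the soft-sphere repulsion
#'   (soft-core annealing: restraints establish the topology before sterics
#'   harden); defaults to a 0 -> 1 ramp reaching full strength on the final
#'   rungs.  The best model is tracked over full-repulsion rungs only.
#' @param seed RNG seed recorded with the schedule.
#' @return list of class `ff_schedule`.
#' @export
anneal_schedule <- function(temps = c(2.5, 1.2, 0.6, 0.3, 0.15, 0.08),
                            moves_per_temp = 700, sigma_rot = 0.35,
                            sigma_tr = 1.2, rep_ramp = NULL, seed = 1) {
  if (!length(temps)) stop("empty schedule")
  if (any(diff(temps) >= 0)) stop("temperatures must be strictly decreasing")
  if (is.null(rep_ramp)) {
    ## soft-core ramp: weak repulsion on the first rungs so restraints can
    ## establish the topology, rising to full strength by the last two rungs
    k <- length(temps)
    rep_ramp <- pmin(1, 0.3 + 0.7 * (seq_len(k) - 1) / max(1, k - 2))
  }
  if (length(rep_ramp) != length(temps)) stop("rep_ramp length mismatch")
  structure(list(temps = temps, moves_per_temp = moves_per_temp,
                 sigma_rot = sigma_rot, sigma_tr = sigma_tr,
                 rep_ramp = rep_ramp, seed = as.integer(seed)), class = "ff_schedule")
}

## precomputed 72-degree rotations for pentamer replication about +z
C5_ROTS <- lapply(0:4, function(k) rotation_matrix(c(0, 0, 1), k * 2 * pi / 5))

replicate_c5_xyz <- function(xyz) {
  do.call(rbind, lapply(C5_ROTS, function(R) xyz %*% t(R)))
}

## one proposal move on the subunit coordinates; flex = flexible residue
## indices, segs = helix runs.  Returns the new coordinate matrix.
propose_move <- function(xyz, flex, sigma_rot = 0.35, sigma_tr = 1.2) {
  n <- nrow(xyz)
  kind <- sample.int(4, 1, prob = c(0.4, 0.25, 0.175, 0.175))
  if (kind == 1 && length(flex)) { # pivot
    p <- flex[sample.int(length(flex), 1)]
    side <- if (runif(1) < 0.5 && p > 1) 1:(p - 1)
            else if (p < n) (p + 1):n else 1:max(1, p - 1)
    xyz[side, ] <- rotate_about(xyz[side, , drop = FALSE], xyz[p, ],
                                random_unit_vector(), rnorm(1, 0, sigma_rot))
  } else if (kind == 2 && length(flex) > 3) { # crankshaft
    for (try in 1:10) {
      i <- flex[sample.int(length(flex), 1)]
      j <- i + sample(3:6, 1)
      if (j <= n && all((i:j) %in% flex)) {
        axis <- xyz[j, ] - xyz[i, ]
        if (vnorm(axis) > 1e-6) {
          xyz[(i + 1):(j - 1), ] <- rotate_about(xyz[(i + 1):(j - 1), , drop = FALSE],
                                                 xyz[i, ], axis,
                                                 rnorm(1, 0, 2 * sigma_rot))
          break
        }
      }
    }
  } else if (kind == 3) { # rigid translation
    xyz <- sweep(xyz, 2, rnorm(3, 0, sigma_tr), "+")
  } else { # rigid rotation about the subunit centroid
    xyz <- rotate_about(xyz, colMeans(xyz), random_unit_vector(),
                        rnorm(1, 0, sigma_rot))
  }
  xyz
}

fold_energy <- function(xyz, chain_id, helix5, ridx, config) {
  pent <- replicate_c5_xyz(xyz)
  cg <- cpp_cg_energy(pent, chain_id, helix5,
                      config$k_bond, config$bond_length,
                      config$k_angle, config$angle_lo * pi / 180,
                      config$angle_hi * pi / 180,
                      config$k_rep, config$rep_onset,
                      config$k_dihedral, config$helix_tau * pi / 180)
  re <- restraint_class_energy(pent, ridx, config$sigmoid_m)
  total <- config$w_physics * cg[1] + config$w_knowledge * cg[2] +
    config$w_deer * re$deer + config$w_pre * re$pre + config$w_noe * re$noe
  list(total = total, physics = cg[1], knowledge = cg[2],
       deer = re$deer, pre = re$pre, noe = re$noe)
}

#' Restraint-guided simulated-annealing fold of one subunit
#'
#' Metropolis annealing over the subunit's internal coordinates; the total
#' score of the C5-replicated pentamer is evaluated at every step and the
#' best-scoring symmetrized pentamer is returned.  Bitwise reproducible for a
#' fixed schedule seed.
#'
#' @param start single-chain CA-level [ff_structure].
#' @param ss per-residue annotation over H/E/T/C.
#' @param restraints `ff_restraints`.
#' @param schedule [anneal_schedule].
#' @param config [score_config].
#' @return list of class `ff_fold`: `model` (pentamer [ff_structure]),
#'   `subunit` (coordinate matrix), `score` (breakdown, equal to
#'   `total_score(model, ...)`), `trace` (accepted total per step),
#'   `acceptance` (per-temperature acceptance rates), `seed`.
#' @export
mc_fold <- function(start, ss, restraints, schedule = anneal_schedule(),
                    config = score_config()) {
  xyz <- ca_coords(start)
  n <- nrow(xyz)
  if (n != length(ss)) stop("annotation length mismatch")
  resno <- unique(start$atoms$resno)
  ridx <- restraint_index(restraints, resno)
  cgpar <- c(config$k_bond, config$bond_length, config$k_angle,
             config$angle_lo * pi / 180, config$angle_hi * pi / 180,
             config$k_rep, config$rep_onset, config$k_dihedral,
             config$helix_tau * pi / 180, config$w_physics,
             config$w_knowledge, config$w_deer, config$w_pre, config$w_noe,
             config$sigmoid_m)
  ## move sizes shrink with the temperature rung so low-T rungs relax
  ## residual strain instead of rejecting every proposal
  scale <- pmax(0.2, sqrt(schedule$temps / schedule$temps[1]))
  res <- with_seed(schedule$seed,
    cpp_mc_fold(xyz, as.integer(ss == "H"), which(ss != "H") - 1L,
                ridx$ia, ridx$ib, ridx$d0, ridx$lower, ridx$upper, ridx$pot,
                ridx$weight, ridx$kind, cgpar, schedule$temps,
                schedule$moves_per_temp, schedule$sigma_rot * scale,
                schedule$sigma_tr * scale, schedule$rep_ramp))
  model <- symmetrize_c5(subunit_from_xyz(res$xyz, resno))
  structure(list(model = model, subunit = res$xyz,
                 score = total_score(model, restraints, ss, config),
                 trace = res$trace, acceptance = res$acceptance,
                 seed = schedule$seed), class = "ff_fold")
}

#' Greedy local score descent
#'
#' Seeded small-move hill descent on the subunit; only score-improving moves
#' are accepted, so the total score never increases.
#'
#' @param fold `ff_fold` (or a single-chain structure via `start`).
#' @param ss,restraints,config as in [mc_fold].
#' @param n_steps number of proposals.
#' @param seed RNG seed.
#' @return An `ff_fold` with `score$s_total <=` the input's.
#' @export
minimize_fold <- function(fold, ss, restraints, config = score_config(),
                          n_steps = 200, seed = 1) {
  xyz <- fold$subunit
  n <- nrow(xyz)
  resno <- unique(fold$model$atoms$resno)
  flex <- which(ss != "H")
  chain_id <- rep(1:5, each = n)
  helix5 <- rep(as.integer(ss == "H"), 5)
  ridx <- restraint_index(restraints, resno)
  with_seed(seed, {
    e <- fold_energy(xyz, chain_id, helix5, ridx, config)
    for (s in seq_len(n_steps)) {
      cand <- propose_move(xyz, flex, sigma_rot = 0.06, sigma_tr = 0.25)
      ec <- fold_energy(cand, chain_id, helix5, ridx, config)
      if (ec$total < e$total) { xyz <- cand; e <- ec }
    }
    model <- symmetrize_c5(subunit_from_xyz(xyz, resno))
    structure(list(model = model, subunit = xyz,
                   score = total_score(model, restraints, ss, config),
                   trace = fold$trace, acceptance = fold$acceptance,
                   seed = seed), class = "ff_fold")
  })
}
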