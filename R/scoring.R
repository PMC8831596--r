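## Restraint potentials, the coarse-grained stand-in energy, combined model
## ranking, and Q-factor validation statistics.

#' Scoring configuration
#'
#' Class weights of the total score and shape parameters of the potentials.
#' Energy units are arbitrary score units, consistent within a run; only the
#' ranking of models matters.
#'
#' @param w_physics,w_knowledge,w_deer,w_pre,w_noe class weights.
#' @param sigmoid_m steepness of the sigmoid PRE potential (1/Angstrom).
#' @param k_bond,bond_length virtual CA-CA bond term (score/A^2, Angstrom).
#' @param k_angle,angle_lo,angle_hi flat-bottom pseudo-angle band (degrees).
#' @param k_rep,rep_onset soft-sphere CA repulsion (score/A^2, onset in
#'   Angstrom between nonbonded CA).
#' @param k_dihedral,helix_tau helix pseudo-dihedral bias (score, degrees).
#' @return list of class `ff_score_config`.
#' @export
score_config <- function(w_physics = 1, w_knowledge = 1, w_deer = 1,
                         w_pre = 1, w_noe = 1, sigmoid_m = 1,
                         k_bond = 10, bond_length = 3.8,
                         k_angle = 20, angle_lo = 75, angle_hi = 150,
                         k_rep = 10, rep_onset = 4.0,
                         k_dihedral = 5, helix_tau = ideal_helix_tau()) {
  structure(list(w_physics = w_physics, w_knowledge = w_knowledge,
                 w_deer = w_deer, w_pre = w_pre, w_noe = w_noe,
                 sigmoid_m = sigmoid_m, k_bond = k_bond,
                 bond_length = bond_length, k_angle = k_angle,
                 angle_lo = angle_lo, angle_hi = angle_hi, k_rep = k_rep,
                 rep_onset = rep_onset, k_dihedral = k_dihedral,
                 helix_tau = helix_tau), class = "ff_score_config")
}

#' Harmonic restraint potential
#' @param d,d0 distance and target (Angstrom).
#' @param k spring weight (>= 0).
#' @return `k * (d - d0)^2`.
#' @export
harmonic_energy <- function(d, d0, k = 1) {
  stopifnot(all(k >= 0))
  k * (d - d0)^2
}

#' Sigmoid restraint potential
#'
#' Value 0.5 at `d = d0`, monotone in `d`, bounded in `[0, 1]`.  `sense =
#' "upper"` penalizes distances above `d0`, `"lower"` mirrors it.
#'
#' @param d,d0 distance and midpoint (Angstrom).
#' @param m steepness (1/Angstrom), > 0.
#' @param sense `"upper"` or `"lower"`.
#' @export
sigmoid_energy <- function(d, d0, m = 1, sense = c("upper", "lower")) {
  sense <- match.arg(sense)
  stopifnot(m > 0)
  s <- if (sense == "upper") 1 else -1
  1 / (1 + exp(-s * m * (d - d0)))
}

#' Flat-bottom restraint potential
#'
#' Zero inside `[lower, upper]`, harmonic in the violation outside; continuous
#' with zero slope at the band edges.
#'
#' @param d distance (Angstrom).
#' @param lower,upper band (Angstrom), `lower <= upper`.
#' @param k spring weight.
#' @export
flat_bottom_energy <- function(d, lower, upper, k = 1) {
  stopifnot(all(lower <= upper))
  k * (pmax(0, lower - d)^2 + pmax(0, d - upper)^2)
}

## ---- internal plumbing shared with the sampler ---------------------------

POT_CODE <- c(harmonic = 0L, sigmoid = 1L, `flat-bottom` = 2L)
KIND_CODE <- c(NOE = 0L, PRE = 1L, DEER = 2L)

## Map each restraint site to a row of the pentamer CA matrix.  `resno` is
## the per-chain residue vector of the CA matrix (chains concatenated in ring
## order).  On reduced models LABEL/H sites resolve to the CA of the residue.
restraint_index <- function(restraints, resno_per_chain, n_chains = 5L) {
  nres <- length(resno_per_chain)
  row_of <- function(res, off) {
    i <- match(res, resno_per_chain)
    if (any(is.na(i))) stop("restraint references residue absent from model: ",
                            paste(res[is.na(i)], collapse = ", "))
    (off %% n_chains) * nres + i
  }
  list(ia = row_of(restraints$res_a, restraints$off_a) - 1L,
       ib = row_of(restraints$res_b, restraints$off_b) - 1L,
       d0 = ifelse(is.na(restraints$d0), 0, restraints$d0),
       lower = restraints$lower, upper = restraints$upper,
       pot = unname(POT_CODE[restraints$potential]),
       weight = restraints$weight,
       kind = unname(KIND_CODE[restraints$kind]))
}

restraint_class_energy <- function(xyz, ridx, sigmoid_m) {
  cpp_restraint_energy(xyz, ridx$ia, ridx$ib, ridx$d0, ridx$lower, ridx$upper,
                       ridx$pot, ridx$weight, ridx$kind, sigmoid_m)
}

## Pentamer CA matrix + per-chain resno + chain ids from an ff_structure.
pentamer_ca <- function(model) {
  ch <- unique(model$atoms$chain)
  resno <- model$atoms$resno[model$atoms$chain == ch[1] & model$atoms$atom == "CA"]
  xyz <- do.call(rbind, lapply(ch, function(c) ca_coords(model, chain = c)))
  list(xyz = xyz, resno = resno,
       chain = rep(seq_along(ch), each = length(resno)), n_chains = length(ch))
}

#' Coarse-grained stand-in energy of a CA-level model
#'
#' A virtual-bond term (target 3.8 A), a flat-bottom pseudo-angle band, a
#' pairwise soft-sphere repulsion between nonbonded CA (the physics part),
#' and a helix pseudo-dihedral bias over annotated helical residues (the
#' knowledge part).
#'
#' @param model [ff_structure] (CA level; any number of chains).
#' @param ss per-residue annotation (one chain's worth), characters in
#'   `H/E/T/C`; `NULL` skips the bias term.
#' @param config [score_config].
#' @return list with `s_physics` and `s_knowledge`.
#' @export
cg_energy <- function(model, ss = NULL, config = score_config()) {
  pc <- pentamer_ca(model)
  if (is.null(ss)) {
    helix <- integer(length(pc$resno))
  } else {
    if (length(ss) != length(pc$resno))
      stop("ss annotation length does not match residues per chain")
    helix <- as.integer(ss == "H")
  }
  e <- cpp_cg_energy(pc$xyz, pc$chain, rep(helix, pc$n_chains),
                     config$k_bond, config$bond_length,
                     config$k_angle, config$angle_lo * pi / 180,
                     config$angle_hi * pi / 180,
                     config$k_rep, config$rep_onset,
                     config$k_dihedral, config$helix_tau * pi / 180)
  list(s_physics = e[1], s_knowledge = e[2])
}

#' Distances realized by each restraint in a model
#'
#' @param model [ff_structure] pentamer (or single chain for purely
#'   intra-subunit restraints).
#' @param restraints `ff_restraints`.
#' @return numeric vector of distances (Angstrom), one per restraint.
#' @export
restraint_distances <- function(model, restraints) {
  pc <- pentamer_ca(model)
  ridx <- restraint_index(restraints, pc$resno, pc$n_chains)
  restraint_class_energy(pc$xyz, ridx, 1)$dist
}

#' Total score of a model
#'
#' `s_total` is the weighted sum of the coarse-grained physics and knowledge
#' terms and the per-class restraint energies (harmonic DEER, sigmoid PRE,
#' flat-bottom NOE).  Lower is better.
#'
#' @param model [ff_structure].
#' @param restraints `ff_restraints`.
#' @param ss per-residue secondary-structure annotation or `NULL`.
#' @param config [score_config].
#' @return One-row data.frame: `s_physics`, `s_knowledge`, `s_deer`, `s_pre`,
#'   `s_noe`, `s_total`.
#' @export
total_score <- function(model, restraints = NULL, ss = NULL,
                        config = score_config()) {
  cg <- cg_energy(model, ss, config)
  if (is.null(restraints) || !nrow(restraints)) {
    re <- list(noe = 0, pre = 0, deer = 0)
  } else {
    pc <- pentamer_ca(model)
    ridx <- restraint_index(restraints, pc$resno, pc$n_chains)
    re <- restraint_class_energy(pc$xyz, ridx, config$sigmoid_m)
  }
  s <- data.frame(s_physics = cg$s_physics, s_knowledge = cg$s_knowledge,
                  s_deer = re$deer, s_pre = re$pre, s_noe = re$noe)
  s$s_total <- config$w_physics * s$s_physics +
    config$w_knowledge * s$s_knowledge + config$w_deer * s$s_deer +
    config$w_pre * s$s_pre + config$w_noe * s$s_noe
  s
}

#' Restraint Q-factor
#'
#' Normalized RMS discrepancy between experimental and back-calculated
#' restraint distances,
#' \eqn{Q = \sqrt{\sum_i (r_{exp,i} - r_{calc,i})^2 / \sum_i r_{exp,i}^2}}.
#'
#' @param r_exp experimental restraint distances (Angstrom).
#' @param r_calc distances observed in the calculated structure(s).
#' @return Unitless Q >= 0; 0 iff all pairs agree.
#' @export
q_factor <- function(r_exp, r_calc) {
  if (!length(r_exp)) stop("empty restraint list")
  if (length(r_exp) != length(r_calc)) stop("length mismatch")
  den <- sum(r_exp^2)
  if (den == 0) stop("all experimental distances zero")
  sqrt(sum((r_exp - r_calc)^2) / den)
}
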