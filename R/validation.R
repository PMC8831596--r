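## Validation: held-out-restraint Q-factors and the downstream structural
## analytics (secondary structure and disorder, pore-radius profile, lateral
## portals, salt bridges, dimensions).

#' Split restraints into working and held-out (free) sets
#'
#' Seeded uniform sample without replacement of size `round(fraction * N)`;
#' the two sets are disjoint and their union is the input.
#'
#' @param restraints `ff_restraints`.
#' @param fraction fraction held out, in (0, 1).
#' @param seed RNG seed.
#' @return list with `working` and `free` restraint tables.
#' @export
holdout_split <- function(restraints, fraction = 0.1, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(restraints)
  k <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, k))
  list(working = validate_restraints(restraints[setdiff(seq_len(n), idx), ]),
       free = validate_restraints(restraints[sort(idx), ]))
}

## per-restraint (r_exp, r_calc) pairs under the documented convention:
## two-sided restraints compare d0 with the ensemble-mean distance; bound-only
## restraints enter through their violated bound (r_exp := bound, r_calc :=
## bound + violation), so a satisfied bound contributes zero discrepancy but
## still counts in the normalization.
q_pairs <- function(ensemble, restraints) {
  dmat <- vapply(ensemble$models, restraint_distances,
                 numeric(nrow(restraints)), restraints = restraints)
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = nrow(restraints))
  d <- rowMeans(dmat)
  two <- !is.na(restraints$d0)
  upperish <- is.finite(restraints$upper)
  r_exp <- ifelse(two, restraints$d0,
                  ifelse(upperish, restraints$upper, restraints$lower))
  r_calc <- ifelse(two, d,
                   ifelse(upperish, pmax(d, restraints$upper),
                          pmin(d, restraints$lower)))
  data.frame(kind = restraints$kind, r_exp = r_exp, r_calc = r_calc)
}

#' Q-factor report for an ensemble
#'
#' Computes the restraint Q-factor (see [q_factor]) per restraint class, with
#' `r_calc` the ensemble-mean distance, plus the free-set Q over held-out
#' restraints.
#'
#' @param ensemble [ff_ensemble].
#' @param restraints working `ff_restraints` (all classes).
#' @param free optional held-out restraints (the `free` part of
#'   [holdout_split]).
#' @return list of class `ff_qreport`: `q_noe`, `q_pre`, `q_deer`,
#'   `q_pre_free` (present when `free` given) and per-class counts `n`.
#' @export
q_report <- function(ensemble, restraints, free = NULL) {
  pr <- q_pairs(ensemble, restraints)
  qs <- list()
  ns <- list()
  for (k in c("NOE", "PRE", "DEER")) {
    sub <- pr[pr$kind == k, ]
    key <- paste0("q_", tolower(k))
    ns[[tolower(k)]] <- nrow(sub)
    qs[[key]] <- if (nrow(sub)) q_factor(sub$r_exp, sub$r_calc) else NA_real_
  }
  if (!is.null(free) && nrow(free)) {
    prf <- q_pairs(ensemble, free)
    qs$q_pre_free <- q_factor(prf$r_exp, prf$r_calc)
    ns$pre_free <- nrow(prf)
  }
  structure(c(qs, list(n = ns)), class = "ff_qreport")
}

#' @export
print.ff_qreport <- function(x, ...) {
  cat("Q-factor report\n")
  for (nm in setdiff(names(x), "n")) {
    if (!is.na(x[[nm]]))
      cat(sprintf("  %-10s %.4f  (n = %d)\n", nm, x[[nm]],
                  x$n[[sub("^q_", "", nm)]]))
  }
  invisible(x)
}

## ---- secondary structure -------------------------------------------------

## Kabsch-Sander style electrostatic hydrogen-bond energy (kcal/mol) between
## donor amide (N, H) and acceptor carbonyl (C, O).
hbond_energy <- function(N, H, C, O) {
  0.084 * 332 * (1 / vnorm(O - N) + 1 / vnorm(C - H) -
                 1 / vnorm(O - H) - 1 / vnorm(C - N))
}

backbone_arrays <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain, ]
  resn <- unique(a$resno)
  get <- function(nm) {
    m <- matrix(NA_real_, length(resn), 3)
    sub <- a[a$atom == nm, ]
    m[match(sub$resno, resn), ] <- as.matrix(sub[, c("x", "y", "z")])
    m
  }
  N <- get("N"); CA <- get("CA"); C <- get("C"); O <- get("O"); H <- get("H")
  if (any(is.na(N)) || any(is.na(C)) || any(is.na(O)))
    stop("backbone N/C/O atoms required for secondary-structure assignment")
  ## geometric amide-H placement (1.01 A along the N-centred bisector) when
  ## the file carries no hydrogens
  for (i in seq_along(resn)) {
    if (any(is.na(H[i, ])) && i > 1) {
      dirh <- unit(unit(N[i, ] - C[i - 1, ]) + unit(N[i, ] - CA[i, ]))
      H[i, ] <- N[i, ] + 1.01 * dirh
    }
  }
  list(resno = resn, N = N, CA = CA, C = C, O = O, H = H)
}

#' Hydrogen-bond based secondary-structure assignment
#'
#' Backbone amide-carbonyl hydrogen bonds are scored with the
#' electrostatic energy
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol and
#' accepted below -0.5 kcal/mol.  Acceptor(i) -> donor(i+4) patterns label
#' alpha helix (H), i -> i+3 3_10 helix (G); residues touched by isolated
#' turns are T and everything else C.
#'
#' @param model full-atom [ff_structure] (amide H placed geometrically when
#'   absent).
#' @param e_cut hydrogen-bond energy cutoff (kcal/mol).
#' @return data.frame with `chain`, `resno`, `label` in H/G/T/C.
#' @export
assign_secondary_structure <- function(model, e_cut = -0.5) {
  out <- lapply(unique(model$atoms$chain), function(ch) {
    bb <- backbone_arrays(model, ch)
    n <- length(bb$resno)
    turn4 <- rep(FALSE, n); turn3 <- rep(FALSE, n)
    for (i in seq_len(n)) {
      for (k in c(3, 4)) {
        j <- i + k
        if (j <= n && !any(is.na(bb$H[j, ]))) {
          e <- hbond_energy(bb$N[j, ], bb$H[j, ], bb$C[i, ], bb$O[i, ])
          if (e < e_cut) {
            if (k == 4) turn4[i] <- TRUE else turn3[i] <- TRUE
          }
        }
      }
    }
    lab <- rep("C", n)
    for (i in which(turn4)) lab[i:min(n, i + 4)] <- "T"
    for (i in which(turn3)) lab[i:min(n, i + 3)] <- "T"
    for (i in which(turn3)) {
      span <- (i + 1):min(n, i + 3)
      lab[span] <- "G"
    }
    for (i in which(turn4)) {
      span <- (i + 1):min(n, i + 4)
      lab[span] <- "H"
    }
    data.frame(chain = ch, resno = bb$resno, label = lab,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Disordered fraction of a residue span
#'
#' Turn and coil labels (T, C) count as disordered; helices (H, G) as
#' ordered.
#'
#' @param assignment data.frame from [assign_secondary_structure] (one model)
#'   or a list of them (ensemble mode: mean over models).
#' @param span `c(first, last)` residue numbers, inclusive.
#' @return Fraction in `[0, 1]`.
#' @export
disorder_fraction <- function(assignment, span) {
  if (is.data.frame(assignment)) assignment <- list(assignment)
  fr <- vapply(assignment, function(a) {
    sub <- a[a$resno >= span[1] & a$resno <= span[2], ]
    if (!nrow(sub)) stop("empty span")
    mean(sub$label %in% c("T", "C"))
  }, numeric(1))
  mean(fr)
}

## ---- pore and portals ----------------------------------------------------

## transform atom coordinates into a frame whose z axis is the symmetry axis
frame_coords <- function(model, frame) {
  d <- frame$axis_direction
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(ref - sum(ref * d) * d)
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  M <- rbind(u, v, d)
  xyz <- sweep(as.matrix(model$atoms[, c("x", "y", "z")]), 2, frame$axis_point)
  list(xyz = xyz %*% t(M), M = M)
}

## largest sphere radius centred at p (3-vector, frame coords) not
## overlapping any atom
clearance <- function(p, xyz, radii, clamp) {
  min(clamp, sqrt(rowSums(sweep(xyz, 2, p)^2)) - radii)
}

#' Pore-radius profile along the symmetry axis
#'
#' At each height z the in-plane centre maximizing the clearance radius
#' `min_atoms(|c - atom| - vdw)` is found by multi-start local search (the
#' axis point plus 8 seeded perturbed starts); the radius is clamped at
#' `clamp`.
#'
#' @param model [ff_structure] with element symbols (radii from
#'   [vdw_radii]).
#' @param frame [symmetry_frame]; estimated from the model when `NULL`.
#' @param z_range `c(lo, hi)` along the axis (frame coordinates, Angstrom);
#'   defaults to the model's CA extent.
#' @param step sampling step (Angstrom).
#' @param clamp maximum reported radius (Angstrom).
#' @param seed seed of the multi-start perturbations.
#' @return data.frame of class `ff_pore_profile`: `z`, `x`, `y` (centre, in
#'   frame coordinates), `radius` (Angstrom).
#' @export
pore_profile <- function(model, frame = NULL, z_range = NULL, step = 0.5,
                         clamp = 15, seed = 1) {
  frame <- frame %||% estimate_symmetry_axis(model)
  fc <- frame_coords(model, frame)
  radii <- vdw_radii(model$atoms$elem)
  if (is.null(z_range)) z_range <- range(fc$xyz[, 3])
  if (z_range[2] < z_range[1]) stop("empty z range")
  zs <- seq(z_range[1], z_range[2], by = step)
  starts <- with_seed(seed, cbind(c(0, rnorm(8, 0, 2)), c(0, rnorm(8, 0, 2))))
  res <- t(vapply(zs, function(z) {
    near <- abs(fc$xyz[, 3] - z) < clamp + 2
    xyz <- fc$xyz[near, , drop = FALSE]
    rr <- radii[near]
    if (!nrow(xyz)) return(c(0, 0, clamp))
    obj <- function(c2) -clearance(c(c2, z), xyz, rr, clamp)
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- optim(starts[s, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-8))
      if (is.null(best) || o$value < best$value) best <- o
    }
    c(best$par, max(0, -best$value))
  }, numeric(3)))
  out <- data.frame(z = zs, x = res[, 1], y = res[, 2], radius = res[, 3])
  class(out) <- c("ff_pore_profile", "data.frame")
  out
}

#' Lateral portal bottleneck radius
#'
#' Largest sphere that can travel from a point on the pore axis (in the
#' vestibule, above the girdle) outward along the ray through the midpoint of
#' an adjacent-chain interface.  At each ray sample the sphere centre is
#' locally optimized perpendicular to the ray; the bottleneck is the minimum
#' clearance along the ray.
#'
#' @param model [ff_structure].
#' @param interface chain pair, e.g. `c("A", "B")`; must be ring-adjacent.
#' @param girdle_z frame-z of the girdle; interface atoms above it define the
#'   ray, and the start point sits `vestibule_dz` above it on the axis.
#' @param frame [symmetry_frame] (estimated when `NULL`).
#' @param vestibule_dz axial offset of the start point (Angstrom).
#' @param step ray sampling step (Angstrom).
#' @param offset_max perpendicular optimization bound (Angstrom).
#' @param clamp maximum radius considered (Angstrom).
#' @return Bottleneck radius (Angstrom, >= 0).
#' @export
lateral_portal_radius <- function(model, interface, girdle_z, frame = NULL,
                                  vestibule_dz = 5, step = 0.5,
                                  offset_max = 4, clamp = 15) {
  frame <- frame %||% estimate_symmetry_axis(model)
  ch <- unique(model$atoms$chain)
  i1 <- match(interface[1], ch); i2 <- match(interface[2], ch)
  if (is.na(i1) || is.na(i2) || !(abs(i1 - i2) %in% c(1, length(ch) - 1)))
    stop("interface chains must be ring-adjacent")
  fc <- frame_coords(model, frame)
  radii <- vdw_radii(model$atoms$elem)
  above <- fc$xyz[, 3] >= girdle_z
  cen <- function(c0) colMeans(fc$xyz[above & model$atoms$chain == c0, , drop = FALSE])
  mid <- (cen(interface[1]) + cen(interface[2])) / 2
  p0 <- c(0, 0, girdle_z + vestibule_dz)
  dirn <- unit(mid - p0)
  ## perpendicular frame
  ref <- if (abs(dirn[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(ref - sum(ref * dirn) * dirn)
  v <- c(dirn[2] * u[3] - dirn[3] * u[2], dirn[3] * u[1] - dirn[1] * u[3],
         dirn[1] * u[2] - dirn[2] * u[1])
  t_max <- max(sqrt(rowSums(fc$xyz[, 1:2]^2))) + 4
  ts <- seq(2, t_max, by = step)
  bottleneck <- clamp
  for (t in ts) {
    p <- p0 + t * dirn
    obj <- function(o2) {
      if (max(abs(o2)) > offset_max) return(1e6)
      -clearance(p + o2[1] * u + o2[2] * v, fc$xyz, radii, clamp)
    }
    o <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 150, reltol = 1e-8))
    bottleneck <- min(bottleneck, max(0, -o$value))
  }
  bottleneck
}

#' Salt-bridge side-chain distances
#'
#' Minimum distance between the basic side-chain nitrogens (Arg NH1/NH2/NE,
#' Lys NZ, His ND1/NE2) of one residue and the carboxylate oxygens (Glu
#' OE1/OE2, Asp OD1/OD2) of the other.  No thresholding is applied.
#'
#' @param model [ff_structure] with side chains.
#' @param pairs data.frame with columns `res_a`, `res_b`, `relation` in
#'   `"intra"` / `"adjacent"` (minimum over the 5 symmetric chain pairs).
#' @return `pairs` with an added `distance` column (Angstrom; `NA` with a
#'   warning when side-chain atoms are missing).
#' @export
salt_bridge_distances <- function(model, pairs) {
  basic <- c("NH1", "NH2", "NE", "NZ", "ND1", "NE2")
  acidic <- c("OE1", "OE2", "OD1", "OD2")
  ch <- unique(model$atoms$chain)
  a <- model$atoms
  get_atoms <- function(resno, chain, names) {
    as.matrix(a[a$resno == resno & a$chain == chain & a$atom %in% names,
                c("x", "y", "z"), drop = FALSE])
  }
  pair_min <- function(resno_a, chain_a, resno_b, chain_b) {
    combos <- list(c("b", "a"), c("a", "b"))
    best <- Inf
    for (cb in combos) {
      P <- get_atoms(if (cb[1] == "a") resno_a else resno_b,
                     if (cb[1] == "a") chain_a else chain_b, basic)
      Q <- get_atoms(if (cb[2] == "a") resno_a else resno_b,
                     if (cb[2] == "a") chain_a else chain_b, acidic)
      if (nrow(P) && nrow(Q))
        best <- min(best, min(as.matrix(dist(rbind(P, Q)))[seq_len(nrow(P)),
                                                           nrow(P) + seq_len(nrow(Q))]))
    }
    best
  }
  pairs$distance <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    d <- if (pairs$relation[i] == "intra") {
      min(vapply(ch, function(c0) pair_min(pairs$res_a[i], c0,
                                           pairs$res_b[i], c0), numeric(1)))
    } else {
      vals <- vapply(seq_along(ch), function(k) {
        k2 <- k %% length(ch) + 1
        min(pair_min(pairs$res_a[i], ch[k], pairs$res_b[i], ch[k2]),
            pair_min(pairs$res_a[i], ch[k2], pairs$res_b[i], ch[k]))
      }, numeric(1))
      min(vals)
    }
    if (!is.finite(d)) {
      warning("missing side-chain atoms for pair ", pairs$res_a[i], "-",
              pairs$res_b[i])
    } else pairs$distance[i] <- d
  }
  pairs
}

#' Deposited-ensemble measurement report
#'
#' One-call reproduction of the standard structural measurements on a
#' multi-model coordinate file of the pentameric receptor: domain height and
#' maximum radius from CA positions, pore-profile constrictions, the
#' vestibule maximum, lateral portal bottleneck, disorder fraction of the
#' intracellular span and salt-bridge distances.  Residue numbers follow the
#' author numbering of the deposited file; the defaults target the receptor
#' construct this pipeline models (measurements on ensembles report the mean
#' over models, bound-type salt-bridge checks the minimum).
#'
#' @param x path to a (multi-model) PDB file, or an [ff_ensemble].
#' @param height_pair CA pair measured vertically across the domain.
#' @param radius_residue residue whose CA-to-axis distance is the maximum
#'   domain radius.
#' @param icd_span residue span for the disorder fraction (requires full
#'   backbone; skipped with a message on CA-only models).
#' @param portal_interface adjacent chain pair for the lateral portal.
#' @param girdle_z frame-z of the hydrophobic girdle for the portal ray;
#'   when `NULL` the portal measurement is skipped.
#' @param salt_bridges data.frame of `res_a`, `res_b`, `relation` pairs, or
#'   `NULL`.
#' @param pore_step pore profile sampling step (Angstrom).
#' @return list with `height`, `max_radius`, `pore` (profile data.frame),
#'   `pore_min_radius`, `vestibule_max_radius`, `portal_radius`,
#'   `disorder_fraction`, `salt_bridges`.
#' @export
pdb_report <- function(x, height_pair = c(296, 402), radius_residue = 336,
                       icd_span = c(296, 443),
                       portal_interface = c("A", "B"), girdle_z = NULL,
                       salt_bridges = data.frame(
                         res_a = c(368, 417, 424),
                         res_b = c(430, 419, 429),
                         relation = c("intra", "adjacent", "adjacent")),
                       pore_step = 0.5) {
  ens <- if (inherits(x, "ff_ensemble")) x else read_structure(x)
  ch1 <- unique(ens$models[[1]]$atoms$chain)[1]
  per_model <- function(f) vapply(ens$models, f, numeric(1))
  ## height as the 3D CA-CA distance (the published dimension)
  height <- per_model(function(m)
    measure_distance(m, list(chain = ch1, resno = height_pair[1], atom = "CA"),
                     list(chain = ch1, resno = height_pair[2], atom = "CA")))
  radius <- per_model(function(m) {
    fr <- estimate_symmetry_axis(m)
    p <- site_xyz(m, list(chain = ch1, resno = radius_residue, atom = "CA"))
    v <- p - fr$axis_point
    vnorm(v - sum(v * fr$axis_direction) * fr$axis_direction)
  })
  model1 <- ens$models[[1]]
  frame <- estimate_symmetry_axis(model1)
  pp <- pore_profile(model1, frame = frame, step = pore_step)
  portal <- if (is.null(girdle_z)) NA_real_ else
    lateral_portal_radius(model1, portal_interface, girdle_z, frame = frame)
  dis <- tryCatch(
    disorder_fraction(lapply(ens$models, assign_secondary_structure),
                      icd_span),
    error = function(e) { message("disorder fraction skipped: ",
                                  conditionMessage(e)); NA_real_ })
  sb <- if (is.null(salt_bridges)) NULL else {
    d <- vapply(ens$models, function(m)
      salt_bridge_distances(m, salt_bridges)$distance,
      numeric(nrow(salt_bridges)))
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(salt_bridges))
    cbind(salt_bridges, min_distance = apply(d, 1, min))
  }
  list(height = mean(height), height_per_model = height,
       max_radius = mean(radius), radius_per_model = radius,
       pore = pp, pore_min_radius = min(pp$radius),
       vestibule_max_radius = max(pp$radius[pp$radius < 15 - 1e-6]),
       portal_radius = portal, disorder_fraction = dis, salt_bridges = sb)
}
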