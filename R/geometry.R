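## Deterministic peptide geometry: ideal CA helices, full-backbone chains
## from internal coordinates, and guided self-avoiding walks for loops.

## CA helix parameters: 1.5 A rise and 100 deg twist per residue; the radius
## is chosen so consecutive CA are exactly 3.8 A apart.
HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180
HELIX_RADIUS <- sqrt(3.8^2 - HELIX_RISE^2) / (2 * sin(HELIX_TWIST / 2))

#' Ideal CA helix coordinates
#'
#' Right-handed CA-level alpha helix along `direction`, with exact 3.8 A
#' consecutive CA spacing.
#'
#' @param n number of residues.
#' @param origin position of the helix axis at the first residue's level.
#' @param direction helix axis direction (from residue 1 to residue n).
#' @param phase azimuthal phase of the first residue (radians).
#' @return `n x 3` coordinate matrix.
#' @export
ideal_ca_helix <- function(n, origin = c(0, 0, 0), direction = c(0, 0, 1),
                           phase = 0) {
  d <- unit(direction)
  ## orthonormal frame (u, v, d), right-handed
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unit(ref - sum(ref * d) * d)
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  k <- seq_len(n) - 1
  ang <- phase + k * HELIX_TWIST
  t(vapply(seq_len(n), function(i)
    origin + HELIX_RADIUS * (cos(ang[i]) * u + sin(ang[i]) * v) +
      k[i] * HELIX_RISE * d, numeric(3)))
}

## CA pseudo-dihedral of the ideal helix above (used as the knowledge-term
## target); evaluated once at load time.
ideal_helix_tau <- function() {
  x <- ideal_ca_helix(5)
  dihedral_angle(x[1, ], x[2, ], x[3, ], x[4, ]) * 180 / pi
}

dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- unit(b2)
  x <- sum(n1 * n2)
  y <- sum((c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
              n1[1] * n2[2] - n1[2] * n2[1])) * m1)
  atan2(y, x)
}

## NeRF atom placement: position D such that |CD| = bond, angle(BCD) = angle,
## torsion(ABCD) = torsion (radians).
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unit(c - b)
  n <- unit(c(
    (b - a)[2] * bc[3] - (b - a)[3] * bc[2],
    (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
    (b - a)[1] * bc[2] - (b - a)[2] * bc[1]))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a full-backbone peptide from dihedral angles
#'
#' Places N, CA, C, O (and amide H) for `n` residues with the given phi/psi
#' (omega fixed trans) using standard bond geometry.  `phi = -57, psi = -47`
#' gives an ideal alpha helix; `phi = psi = 180` a fully extended chain.
#'
#' @param n number of residues.
#' @param phi,psi backbone dihedrals in degrees (recycled).
#' @param resname residue name(s) for the atom table.
#' @param chain chain label.
#' @return Full-atom [ff_structure] with N, CA, C, O, H per residue.
#' @export
build_peptide <- function(n, phi = -57, psi = -47, resname = "ALA",
                          chain = "A") {
  phi <- rep(phi * pi / 180, length.out = n)
  psi <- rep(psi * pi / 180, length.out = n)
  omega <- pi
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329; b_co <- 1.231; b_nh <- 1.01
  a_ncac <- 111.2 * pi / 180; a_cacn <- 116.2 * pi / 180
  a_cnca <- 121.7 * pi / 180; a_caco <- 120.5 * pi / 180
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_nca, 0, 0)
  C[1, ] <- CA[1, ] + b_cac * c(-cos(a_ncac), sin(a_ncac), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], b_cn, a_cacn, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], b_nca, a_cnca, omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], b_cac, a_ncac, phi[i])
  }
  O <- matrix(0, n, 3); H <- matrix(NA_real_, n, 3)
  for (i in 1:n) {
    if (i < n) {
      O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], b_co, a_caco, pi)
    } else {
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_co, a_caco, pi)
    }
    if (i > 1) {
      ## amide H along the in-plane bisector opposite the C(i-1) and CA bonds
      dirh <- unit(unit(N[i, ] - C[i - 1, ]) + unit(N[i, ] - CA[i, ]))
      H[i, ] <- N[i, ] + b_nh * dirh
    }
  }
  rows <- list()
  for (i in 1:n) {
    at <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    if (i > 1) { at <- rbind(at, H = H[i, ]); nm <- c(nm, "H"); el <- c(el, "H") }
    rows[[i]] <- data.frame(chain = chain, resno = i,
                            resname = rep(resname, length.out = n)[i],
                            atom = nm, elem = el,
                            x = at[, 1], y = at[, 2], z = at[, 3],
                            stringsAsFactors = FALSE)
  }
  ff_structure(do.call(rbind, rows), resolution = "full")
}

## Guided self-avoiding walk with fixed step length.  `legs` is a list of
## list(n = steps, target = point, arrive = acceptable final distance,
## close = bond-closure flag).  A minimum pseudo-angle keeps the chain from
## kinking (which also keeps i, i+2 pairs outside the repulsion onset), and
## closure legs end with an exact two-sphere projection so the bond to the
## target has exactly `step` length.  `avoid` is a matrix of positions to
## keep >= min_sep away (symmetry copies included by the caller).  Uses the
## current RNG stream.
guided_walk <- function(start, legs, step = 3.8, avoid = NULL,
                        min_sep = 4.0, prev = NULL, min_angle = 85,
                        max_try = 120) {
  cos_max <- cos(min_angle * pi / 180)
  cur <- start
  placed <- matrix(numeric(0), 0, 3)
  for (leg in legs) {
    m <- leg$n
    for (j in seq_len(leg$n)) {
      remain <- m - j # steps left in this leg after this one
      ok <- FALSE
      for (attempt in seq_len(max_try)) {
        w <- min(1, 0.3 + 0.7 * attempt / max_try)
        to_t <- leg$target - cur
        dirn <- unit(w * unit(to_t) + (1 - w) * random_unit_vector())
        cand <- cur + step * dirn
        ## pseudo-angle at `cur` between the previous point and the candidate
        if (!is.null(prev) &&
            sum(unit(prev - cur) * unit(cand - cur)) > cos_max) next
        dt <- vnorm(cand - leg$target)
        reach_hi <- remain * step * 0.95 + leg$arrive
        reach_lo <- if (remain == 0) max(0, leg$arrive - 0.8) else 0
        if (dt > reach_hi || dt < reach_lo) next
        clear <- TRUE
        if (!is.null(avoid) && nrow(avoid))
          clear <- min(sqrt(rowSums(sweep(avoid, 2, cand)^2))) >= min_sep
        if (clear && nrow(placed) > 2) {
          dp <- sqrt(rowSums(sweep(placed[seq_len(nrow(placed) - 2), , drop = FALSE],
                                   2, cand)^2))
          clear <- min(dp) >= min_sep
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) cand <- cur + step * unit(leg$target - cur) # deterministic fallback
      placed <- rbind(placed, cand)
      prev <- cur
      cur <- cand
    }
    if (isTRUE(leg$close) && nrow(placed) >= 2) {
      ## move the final point onto the circle where both bonds (to the
      ## penultimate point and to the target) have exactly `step` length,
      ## picking the circle point with the largest clearance
      A <- placed[nrow(placed) - 1, ]
      B <- leg$target
      d <- vnorm(B - A)
      if (d < 2 * step) {
        mid <- (A + B) / 2
        rho <- sqrt(step^2 - (d / 2)^2)
        nrm <- unit(B - A)
        ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        u <- unit(ref - sum(ref * nrm) * nrm)
        v <- c(nrm[2] * u[3] - nrm[3] * u[2], nrm[3] * u[1] - nrm[1] * u[3],
               nrm[1] * u[2] - nrm[2] * u[1])
        obst <- rbind(avoid,
                      placed[seq_len(max(0, nrow(placed) - 2)), , drop = FALSE])
        best <- NULL; best_clear <- -Inf
        for (ang in seq(0, 2 * pi, length.out = 73)[-73]) {
          cand <- mid + rho * (cos(ang) * u + sin(ang) * v)
          cl <- if (is.null(obst) || !nrow(obst)) 1e6
                else min(sqrt(rowSums(sweep(obst, 2, cand)^2)))
          if (cl > best_clear) { best_clear <- cl; best <- cand }
        }
        placed[nrow(placed), ] <- best
        cur <- best
      }
    }
  }
  placed
}
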