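## Coordinate containers, PDB I/O, superposition and five-fold symmetry.
##
## A structure is a plain atom table plus a resolution flag; an ensemble is an
## ordered list of structures sharing one chain/residue topology.  File I/O is
## delegated to bio3d; everything downstream works on the atom table.

#' Construct a structure object
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `elem`, `x`, `y`, `z`.  One row per atom; residue numbers must be strictly
#'   increasing within each chain.
#' @param resolution `"calpha"` for reduced models or `"full"` for all-atom.
#' @return An object of class `ff_structure`.
#' @export
ff_structure <- function(atoms, resolution = c("calpha", "full")) {
  resolution <- match.arg(resolution)
  need <- c("chain", "resno", "resname", "atom", "elem", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  atoms <- atoms[, need]
  atoms$chain <- as.character(atoms$chain)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  for (ch in unique(atoms$chain)) {
    rn <- unique(atoms$resno[atoms$chain == ch])
    if (any(diff(rn) <= 0))
      stop("residue numbers not strictly increasing in chain ", ch)
    ca <- atoms$atom[atoms$chain == ch] == "CA"
    if (!all(rn %in% atoms$resno[atoms$chain == ch][ca]))
      stop("missing CA for one or more residues in chain ", ch)
  }
  structure(list(atoms = atoms, resolution = resolution), class = "ff_structure")
}

#' @export
print.ff_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("ff_structure: %d atoms, %d chain(s) [%s], %d residues/chain, %s resolution\n",
              nrow(x$atoms), length(ch), paste(ch, collapse = ""),
              length(unique(x$atoms$resno[x$atoms$chain == ch[1]])), x$resolution))
  invisible(x)
}

#' Construct an ensemble of structures
#'
#' @param models list of [ff_structure] objects sharing topology.
#' @param scores optional data.frame of per-model score breakdowns.
#' @return An object of class `ff_ensemble`.
#' @export
ff_ensemble <- function(models, scores = NULL) {
  if (!length(models)) stop("empty ensemble")
  ref <- topology_key(models[[1]])
  for (i in seq_along(models)) {
    if (!identical(topology_key(models[[i]]), ref))
      stop("model ", i, " does not share the ensemble topology")
  }
  structure(list(models = models, scores = scores), class = "ff_ensemble")
}

#' @export
print.ff_ensemble <- function(x, ...) {
  cat(sprintf("ff_ensemble: %d model(s)\n", length(x$models)))
  print(x$models[[1]])
  invisible(x)
}

#' @export
length.ff_ensemble <- function(x) length(x$models)

topology_key <- function(s) {
  a <- s$atoms
  paste(a$chain, a$resno, a$atom, sep = ":")
}

#' Van der Waals radii
#'
#' Fixed Bondi-style radii (Angstrom) used for pore and portal profiling.
#' Pore radii depend directly on this table, so it is exported rather than
#' hidden.
#'
#' @param elem optional character vector of element symbols; if omitted the
#'   whole table is returned.  Unknown elements fall back to 1.70 A (carbon).
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(elem = NULL) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
           P = 1.80, F = 1.47, SE = 1.90)
  if (is.null(elem)) return(tab)
  r <- tab[toupper(elem)]
  r[is.na(r)] <- 1.70
  unname(r)
}

## Infer an element symbol from a PDB atom name when the element column is
## absent (e.g. "CA" -> C is wrong for calcium, but within protein chains the
## first letter convention holds for H/C/N/O/S).
elem_from_name <- function(name) {
  first <- toupper(substr(gsub("[0-9]", "", trimws(name)), 1, 1))
  ifelse(first %in% c("H", "C", "N", "O", "S", "P"), first, "C")
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' Honors ATOM/HETATM/MODEL/ENDMDL/TER records.  For alternate locations the
#' highest-occupancy copy is kept; insertion codes are rejected.  Residue
#' numbering is taken verbatim from the file (author numbering).
#'
#' @param path PDB file path.
#' @param model `"all"` or an integer model index.
#' @return An [ff_ensemble] with one [ff_structure] per model.
#' @export
read_structure <- function(path, model = "all") {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported")
  keep <- rep(TRUE, nrow(at))
  alt <- !is.na(at$alt) & nzchar(at$alt)
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    for (k in unique(key[alt])) {
      idx <- which(key == k)
      if (length(idx) > 1) keep[idx[-which.max(occ[idx])]] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  sel <- seq_len(nmod)
  if (!identical(model, "all")) {
    model <- as.integer(model)
    if (any(model < 1 | model > nmod)) stop("model index out of range 1..", nmod)
    sel <- model
  }
  elem <- if (!is.null(at$elesy) && any(!is.na(at$elesy) & nzchar(at$elesy))) {
    ifelse(is.na(at$elesy) | !nzchar(at$elesy), elem_from_name(at$elety), toupper(at$elesy))
  } else elem_from_name(at$elety)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  xyz <- xyz[, rep((which(keep) - 1) * 3, each = 3) + 1:3, drop = FALSE]
  full <- any(at$elety != "CA")
  models <- lapply(sel, function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    ff_structure(data.frame(chain = at$chain, resno = at$resno,
                            resname = at$resid, atom = at$elety, elem = elem,
                            x = co[, 1], y = co[, 2], z = co[, 3],
                            stringsAsFactors = FALSE),
                 resolution = if (full) "full" else "calpha")
  })
  ff_ensemble(models)
}

#' Write a structure or ensemble to a PDB file
#'
#' @param x [ff_structure] or [ff_ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "ff_structure")) x <- ff_ensemble(list(x))
  a <- x$models[[1]]$atoms
  xyz <- do.call(rbind, lapply(x$models, function(s)
    as.numeric(t(as.matrix(s$atoms[, c("x", "y", "z")])))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, chain = a$chain,
                   resid = a$resname, elety = a$atom)
  invisible(path)
}

## n x 3 coordinate matrix of selected atoms.
atom_coords <- function(s, atom = NULL, chain = NULL, resno = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(atom)) keep <- keep & a$atom %in% atom
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  as.matrix(a[keep, c("x", "y", "z")])
}

ca_coords <- function(s, chain = NULL, resno = NULL) {
  atom_coords(s, atom = "CA", chain = chain, resno = resno)
}

set_coords <- function(s, xyz, atom = NULL, chain = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(atom)) keep <- keep & a$atom %in% atom
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  s$atoms[keep, c("x", "y", "z")] <- xyz
  s
}

## Optimal rigid superposition of two point sets (rows of n x 3 matrices)
## by SVD of the covariance; proper rotation enforced.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(sweep(P, 2, cp) %*% t(R), 2, cq, "+")
  list(rotation = R, translation = as.numeric(cq - R %*% cp),
       rmsd = sqrt(mean(rowSums((moved - Q)^2))), coords = moved)
}

#' Least-squares superposition of one structure onto another
#'
#' @param mobile,reference [ff_structure] objects sharing topology over
#'   `selection`.
#' @param selection residue numbers used for the fit; default all shared.
#' @return list with `rotation` (3x3), `translation` (length 3; the transform
#'   is `x' = R x + t`), `rmsd` (post-fit CA RMSD over the selection, Angstrom)
#'   and `mobile` (the transformed structure).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection))
    selection <- intersect(unique(mobile$atoms$resno), unique(reference$atoms$resno))
  P <- ca_coords(mobile, resno = selection)
  Q <- ca_coords(reference, resno = selection)
  if (nrow(P) != nrow(Q)) stop("selection does not match between structures")
  if (nrow(P) < 3) stop("degenerate selection: need at least 3 CA atoms")
  fit <- kabsch_fit(P, Q)
  all_xyz <- as.matrix(mobile$atoms[, c("x", "y", "z")])
  moved <- sweep(all_xyz %*% t(fit$rotation), 2, fit$translation, "+")
  out <- mobile
  out$atoms[, c("x", "y", "z")] <- moved
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, mobile = out)
}

#' CA root-mean-square deviation between two structures
#'
#' @param a,b [ff_structure] objects with identical topology.
#' @param superpose superpose `b` onto `a` first (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b, superpose = TRUE) {
  if (!identical(topology_key(a), topology_key(b))) stop("topology mismatch")
  P <- ca_coords(a); Q <- ca_coords(b)
  if (superpose) kabsch_fit(Q, P)$rmsd else sqrt(mean(rowSums((P - Q)^2)))
}

#' Five-fold symmetry frame
#'
#' @param axis_point point on the symmetry axis (Angstrom).
#' @param axis_direction axis direction (normalized internally).
#' @param order rotational order (5 for a pentamer).
#' @return list of class `ff_symframe`.
#' @export
symmetry_frame <- function(axis_point = c(0, 0, 0),
                           axis_direction = c(0, 0, 1), order = 5L) {
  if (order < 2) stop("symmetry order must be >= 2")
  structure(list(axis_point = as.numeric(axis_point),
                 axis_direction = unit(as.numeric(axis_direction)),
                 order = as.integer(order)), class = "ff_symframe")
}

#' Replicate a single subunit into a C5 pentamer
#'
#' Chains are labeled `A`..`E` in ring order; chain k is the subunit rotated
#' by (k-1) * 72 degrees about the frame axis.
#'
#' @param subunit single-chain [ff_structure].
#' @param frame [symmetry_frame] with `order = 5`.
#' @return Pentameric [ff_structure].
#' @export
symmetrize_c5 <- function(subunit, frame = symmetry_frame()) {
  if (frame$order != 5L) stop("symmetrize_c5 requires a frame of order 5")
  if (length(unique(subunit$atoms$chain)) != 1)
    stop("subunit must have exactly one chain")
  xyz <- as.matrix(subunit$atoms[, c("x", "y", "z")])
  out <- vector("list", 5)
  for (k in 0:4) {
    a <- subunit$atoms
    a$chain <- LETTERS[k + 1]
    a[, c("x", "y", "z")] <- rotate_about(xyz, frame$axis_point,
                                          frame$axis_direction, k * 2 * pi / 5)
    out[[k + 1]] <- a
  }
  ff_structure(do.call(rbind, out), resolution = subunit$resolution)
}

#' Distance between two atoms in a structure
#'
#' @param s [ff_structure].
#' @param site_a,site_b lists `list(chain=, resno=, atom=)`.
#' @return Euclidean distance in Angstrom.
#' @export
measure_distance <- function(s, site_a, site_b) {
  p <- site_xyz(s, site_a)
  q <- site_xyz(s, site_b)
  vnorm(p - q)
}

site_xyz <- function(s, site) {
  a <- s$atoms
  hit <- a$chain == site$chain & a$resno == site$resno & a$atom == site$atom
  if (!any(hit)) stop(sprintf("no atom %s in chain %s residue %d",
                              site$atom, site$chain, site$resno))
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}

#' Estimate the five-fold symmetry axis of a pentamer
#'
#' The axis point is the centroid of all CA atoms; the direction is the normal
#' of the plane through the five per-chain CA centroids (smallest principal
#' component of their scatter), signed to have a positive z component (or
#' positive x, then y, if the z component vanishes).
#'
#' @param pentamer [ff_structure] with 5 chains of identical topology.
#' @return An `ff_symframe`.
#' @export
estimate_symmetry_axis <- function(pentamer) {
  ch <- unique(pentamer$atoms$chain)
  if (length(ch) != 5) stop("expected 5 chains, found ", length(ch))
  cen <- t(vapply(ch, function(c) colMeans(ca_coords(pentamer, chain = c)),
                  numeric(3)))
  sc <- sweep(cen, 2, colMeans(cen))
  ev <- eigen(crossprod(sc), symmetric = TRUE)
  if (ev$values[2] < 1e-9) stop("degenerate geometry: chain centroids collinear")
  dir <- ev$vectors[, 3]
  for (i in 3:1) {
    if (abs(dir[i]) > 1e-9) { if (dir[i] < 0) dir <- -dir; break }
  }
  symmetry_frame(axis_point = colMeans(ca_coords(pentamer)),
                 axis_direction = dir, order = 5L)
}
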