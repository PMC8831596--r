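## Distance-restraint table: one row per restraint, shared by the NMR, ESR,
## scoring and validation modules.
##
## A site is (residue, atom-or-label, chain offset).  Chain offsets are 0..4
## around the C5 ring: 0 = same subunit, 1 = adjacent, 2 = diagonal.  The
## pseudo-label atom name "LABEL" and the amide proxy "H" both resolve to CA
## on reduced models (see `resolve_site_atom`).

#' Build a distance-restraint table
#'
#' @param res_a,res_b residue numbers of the two sites.
#' @param atom_a,atom_b atom (or pseudo-label) names; `"LABEL"` and `"H"`
#'   resolve to `CA` on reduced models.
#' @param off_a,off_b chain offsets 0..4 around the ring.
#' @param d0 target distance (Angstrom); `NA` for bound-only restraints.
#' @param lower,upper bounds (Angstrom); use `0` / `Inf` for one-sided.
#' @param kind `"NOE"`, `"PRE"` or `"DEER"`.
#' @param weight nonnegative weight.
#' @param potential `"harmonic"`, `"sigmoid"` or `"flat-bottom"`.
#' @return data.frame of class `ff_restraints`.
#' @export
distance_restraints <- function(res_a, atom_a = "CA", off_a = 0L,
                                res_b = res_a, atom_b = "CA", off_b = 0L,
                                d0 = NA_real_, lower = 0, upper = Inf,
                                kind = "PRE", weight = 1,
                                potential = "harmonic") {
  if (!length(res_a)) return(empty_restraints())
  df <- data.frame(res_a = as.integer(res_a), atom_a = atom_a,
                   off_a = as.integer(off_a), res_b = as.integer(res_b),
                   atom_b = atom_b, off_b = as.integer(off_b),
                   d0 = as.numeric(d0), lower = as.numeric(lower),
                   upper = as.numeric(upper), kind = kind,
                   weight = as.numeric(weight), potential = potential,
                   stringsAsFactors = FALSE)
  validate_restraints(df)
}

#' An empty restraint table
#' @return `ff_restraints` with zero rows.
#' @export
empty_restraints <- function() {
  validate_restraints(data.frame(
    res_a = integer(0), atom_a = character(0), off_a = integer(0),
    res_b = integer(0), atom_b = character(0), off_b = integer(0),
    d0 = numeric(0), lower = numeric(0), upper = numeric(0),
    kind = character(0), weight = numeric(0), potential = character(0),
    stringsAsFactors = FALSE))
}

validate_restraints <- function(df) {
  stopifnot(all(df$kind %in% c("NOE", "PRE", "DEER")),
            all(df$potential %in% c("harmonic", "sigmoid", "flat-bottom")),
            all(df$weight >= 0), all(df$off_a %in% 0:4), all(df$off_b %in% 0:4))
  two <- !is.na(df$d0)
  if (any(two & (df$lower > df$d0 | df$d0 > df$upper)))
    stop("restraint with d0 outside [lower, upper]")
  if (any(df$lower > df$upper)) stop("restraint with lower > upper")
  class(df) <- c("ff_restraints", "data.frame")
  df
}

#' Combine restraint tables
#' @param ... `ff_restraints` tables.
#' @return A single `ff_restraints` table.
#' @export
bind_restraints <- function(...) {
  validate_restraints(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' Write / read a restraint table as TSV
#'
#' One restraint per line, columns matching the [distance_restraints] fields;
#' infinities serialized as `Inf`.
#'
#' @param restraints `ff_restraints` table.
#' @param path file path.
#' @return `path` (write) or the restraint table (read).
#' @export
write_restraints <- function(restraints, path) {
  write.table(as.data.frame(restraints), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  validate_restraints(read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
}
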