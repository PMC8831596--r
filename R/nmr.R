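## NMR observables -> restraints and dynamics parameters.
##
## Peak tables are plain data.frames with columns
##   residue, condition, intensity, linewidth_hz, shift_h_ppm, shift_n_ppm, noise
## where `condition` tags the experiment arm: "paramagnetic", "diamagnetic",
## "saturated", "unsaturated", "temperature:<K>", "inphase", "antiphase".

## gyromagnetic ratio of 15N relative to 1H; converts spectrometer field (1H
## MHz) to the 15N frequency used for ppm <-> Hz conversion of splittings.
GAMMA_N_OVER_H <- 0.10136767

#' Read a peak table from TSV
#'
#' @param path TSV with header columns `residue`, `condition`, `intensity`
#'   and optionally `linewidth_hz`, `shift_h_ppm`, `shift_n_ppm`, `noise`.
#' @return data.frame.
#' @export
read_peak_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("residue", "condition", "intensity") %in% names(df)))
    stop("peak table must have residue/condition/intensity columns")
  df
}

#' Parameters of the PRE distance conversion
#'
#' Constants of the Solomon-Bloembergen relation between the paramagnetic
#' transverse-rate enhancement of a nitroxide label and the electron-proton
#' distance, plus the bound rules used when intensity ratios leave the
#' quantifiable window.
#'
#' @param tau_c rotational correlation time (s).
#' @param field_mhz 1H spectrometer frequency (MHz); sets the proton Larmor
#'   frequency.
#' @param K nitroxide interaction constant (cm^6 s^-2); default the standard
#'   value 1.23e-32.
#' @param t_evol transverse evolution period of the experiment (s).
#' @param ratio_floor,ratio_ceiling I/I0 window limits; ratios at or below
#'   the floor are "vanished" peaks, at or above the ceiling unbroadened.
#' @param r_min_bound,r_max_bound bound distances (Angstrom) assigned outside
#'   the window; `NA` (the default) derives them per residue by inverting the
#'   window-edge ratios at the residue's diamagnetic linewidth, so bounds
#'   coincide with the quantifiable-window edges.
#' @param tol half-width of the two-sided restraint band (Angstrom).
#' @return list of class `ff_pre_params`.
#' @export
pre_params <- function(tau_c = 10e-9, field_mhz = 700, K = 1.23e-32,
                       t_evol = 0.010, ratio_floor = 0.10,
                       ratio_ceiling = 0.85, r_min_bound = NA,
                       r_max_bound = NA, tol = 4) {
  stopifnot(tau_c > 0, t_evol > 0, K > 0,
            ratio_floor > 0, ratio_floor < ratio_ceiling, ratio_ceiling < 1,
            is.na(r_min_bound) || is.na(r_max_bound) ||
              r_min_bound < r_max_bound)
  structure(list(tau_c = tau_c, omega_h = 2 * pi * field_mhz * 1e6, K = K,
                 t_evol = t_evol, ratio_floor = ratio_floor,
                 ratio_ceiling = ratio_ceiling, r_min_bound = r_min_bound,
                 r_max_bound = r_max_bound, tol = tol),
            class = "ff_pre_params")
}

## Spectral prefactor K * (4 tau_c + 3 tau_c / (1 + (wH tau_c)^2)) in
## Angstrom^6 / s  (K converted from cm^6 s^-2: 1 cm^6 = 1e48 A^6).
sb_prefactor <- function(p) {
  tau <- p$tau_c
  (p$K * 1e48) * (4 * tau + 3 * tau / (1 + (p$omega_h * tau)^2))
}

#' Forward Solomon-Bloembergen rate from a distance
#'
#' @param r electron-proton distance (Angstrom).
#' @param p [pre_params].
#' @return Paramagnetic transverse rate enhancement R2sp (s^-1).
#' @export
sb_rate <- function(r, p = pre_params()) {
  stopifnot(all(r > 0))
  sb_prefactor(p) / r^6
}

#' Distance from a paramagnetic rate enhancement
#'
#' Inverts the Solomon-Bloembergen relation
#' \eqn{R_2^{sp} = (K/r^6)(4\tau_c + 3\tau_c/(1+\omega_H^2\tau_c^2))}.
#'
#' @param r2sp paramagnetic transverse rate enhancement (s^-1), > 0.
#' @param p [pre_params].
#' @return Distance in Angstrom; strictly decreasing in `r2sp`.
#' @export
pre_distance <- function(r2sp, p = pre_params()) {
  if (any(r2sp <= 0)) stop("r2sp must be positive")
  (sb_prefactor(p) / r2sp)^(1 / 6)
}

## Forward two-condition intensity model: the paramagnetic arm relaxes at
## R2dia + R2sp during the evolution period and is broadened in the ratio of
## linewidths, giving  I/I0 = R2dia exp(-R2sp t) / (R2dia + R2sp).
pre_ratio <- function(r2sp, r2dia, t_evol) {
  r2dia * exp(-r2sp * t_evol) / (r2dia + r2sp)
}

#' Rate enhancement from an intensity ratio
#'
#' Solves `ratio = R2dia exp(-R2sp t) / (R2dia + R2sp)` for `R2sp` by
#' bracketed root finding, with `R2dia = pi * linewidth_dia`.
#'
#' @param ratio paramagnetic/diamagnetic intensity ratio I/I0 in (0, 1].
#' @param linewidth_dia diamagnetic linewidth (Hz), > 0.
#' @param t_evol transverse evolution period (s).
#' @return R2sp in s^-1 (0 when `ratio == 1`).
#' @export
r2sp_from_ratio <- function(ratio, linewidth_dia, t_evol = 0.010) {
  if (linewidth_dia <= 0) stop("diamagnetic linewidth must be positive")
  if (ratio > 1) stop("intensity ratio > 1: inconsistent data")
  if (ratio <= 0) stop("peak vanished (ratio <= 0): assign an upper-bound restraint")
  if (ratio == 1) return(0)
  r2dia <- pi * linewidth_dia
  f <- function(x) pre_ratio(x, r2dia, t_evol) - ratio
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = 1e-12)$root
}

#' Fit a single-exponential relaxation decay
#'
#' Nonlinear least squares of `I(tau) = A exp(-R tau)`; the initializer is a
#' log-linear fit so the result is deterministic.
#'
#' @param series list or data.frame with `delays` (s, strictly increasing,
#'   >= 4 points), `intensities`, and optionally `residue`.
#' @return list with `residue`, `rate` (s^-1), `rate_sigma`, `amplitude`,
#'   `ok` (FALSE on fit failure, with rate `NA`).
#' @export
fit_relaxation_rate <- function(series) {
  tau <- series$delays
  y <- series$intensities
  if (length(tau) < 4) stop("need at least 4 delay points")
  if (any(diff(tau) <= 0)) stop("delays must be strictly increasing")
  if (length(y) != length(tau)) stop("delays/intensities length mismatch")
  res <- series$residue %||% NA_integer_
  fail <- list(residue = res, rate = NA_real_, rate_sigma = NA_real_,
               amplitude = NA_real_, ok = FALSE)
  if (diff(range(y)) == 0) return(fail)
  pos <- y > 0
  if (sum(pos) >= 2) {
    init <- unname(coef(lm(log(y[pos]) ~ tau[pos])))
    a0 <- exp(init[1]); r0 <- max(-init[2], 1e-3)
  } else {
    a0 <- max(abs(y)); r0 <- 1
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-R * tau),
                      start = list(A = a0, R = r0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- coef(fit)
  if (!is.finite(cf["R"]) || cf["R"] <= 0) return(fail)
  se <- tryCatch(sqrt(diag(vcov(fit)))["R"], error = function(e) NA_real_)
  list(residue = res, rate = unname(cf["R"]), rate_sigma = unname(se),
       amplitude = unname(cf["A"]), ok = TRUE)
}

#' Heteronuclear NOE from a saturation pair
#'
#' @param sat,unsat peak records (rows with `intensity` and `noise`) with and
#'   without proton saturation.
#' @return list with `residue`, `noe` = I_sat / I_unsat and its propagated
#'   `sigma`.
#' @export
compute_hetnoe <- function(sat, unsat) {
  if (unsat$intensity == 0) stop("zero unsaturated intensity")
  noe <- sat$intensity / unsat$intensity
  ss <- sat$noise %||% 0
  su <- unsat$noise %||% 0
  sigma <- if (sat$intensity == 0) su / abs(unsat$intensity)
           else abs(noe) * sqrt((ss / sat$intensity)^2 + (su / unsat$intensity)^2)
  list(residue = sat$residue %||% NA_integer_, noe = noe, sigma = abs(sigma))
}

#' Amide-proton temperature coefficient and hydrogen-bond flag
#'
#' Ordinary least-squares slope of the amide 1H shift (in ppb) against
#' temperature (K).  Helical amides with coefficients of magnitude below the
#' threshold are flagged as hydrogen bonded; the magnitude criterion is used
#' because amide coefficients are conventionally negative.
#'
#' @param series data.frame with columns `temperature` (K) and `shift_h_ppm`,
#'   and optionally `residue`; >= 3 temperatures spanning >= 10 K.
#' @param threshold flag threshold in ppb/K (default 4.5).
#' @return list with `residue`, `coefficient` (ppb/K), `hbond_flag`.
#' @export
temperature_coefficient <- function(series, threshold = 4.5) {
  t <- series$temperature
  if (length(unique(t)) < 3) stop("need at least 3 temperatures")
  if (diff(range(t)) < 10) stop("temperature range must span at least 10 K")
  slope <- unname(coef(lm(I(series$shift_h_ppm * 1000) ~ t))[2])
  list(residue = series$residue[1] %||% NA_integer_,
       coefficient = slope, hbond_flag = abs(slope) < threshold)
}

#' PRE peak table to distance restraints
#'
#' Pairs paramagnetic/diamagnetic records per residue and applies the window
#' rules: ratios at or above the ceiling give a lower-bound-only restraint at
#' `r_max_bound`; vanished peaks (ratio at or below the floor) an
#' upper-bound-only restraint at `r_min_bound`; quantifiable ratios a
#' two-sided sigmoid restraint centered on the Solomon-Bloembergen distance
#' with a `+/- tol` band.
#'
#' @param peaks peak table with paired `paramagnetic` / `diamagnetic` rows
#'   per residue (`linewidth_hz` required on the diamagnetic rows).
#' @param label_residue residue carrying the nitroxide label.
#' @param p [pre_params].
#' @return `ff_restraints` table with site A = (label_residue, `"LABEL"`) and
#'   site B = (residue, `"H"`); unmatched residues are skipped with a warning.
#' @export
pre_table_to_restraints <- function(peaks, label_residue, p = pre_params()) {
  para <- peaks[peaks$condition == "paramagnetic", ]
  dia <- peaks[peaks$condition == "diamagnetic", ]
  resn <- sort(intersect(para$residue, dia$residue))
  orphan <- setdiff(union(para$residue, dia$residue), resn)
  if (length(orphan))
    warning("unmatched PRE records skipped for residues: ",
            paste(orphan, collapse = ", "))
  if (!length(resn)) return(empty_restraints())
  rows <- lapply(resn, function(rn) {
    ip <- para$intensity[match(rn, para$residue)]
    id <- dia$intensity[match(rn, dia$residue)]
    lw <- dia$linewidth_hz[match(rn, dia$residue)]
    ratio <- ip / id
    r_max <- if (is.na(p$r_max_bound))
      pre_distance(r2sp_from_ratio(p$ratio_ceiling, lw, p$t_evol), p)
      else p$r_max_bound
    r_min <- if (is.na(p$r_min_bound))
      pre_distance(r2sp_from_ratio(p$ratio_floor, lw, p$t_evol), p)
      else p$r_min_bound
    if (ratio >= p$ratio_ceiling) {
      distance_restraints(res_a = label_residue, atom_a = "LABEL",
                          res_b = rn, atom_b = "H", d0 = NA,
                          lower = r_max, upper = Inf,
                          kind = "PRE", potential = "sigmoid")
    } else if (ratio <= p$ratio_floor) {
      distance_restraints(res_a = label_residue, atom_a = "LABEL",
                          res_b = rn, atom_b = "H", d0 = NA,
                          lower = 0, upper = r_min,
                          kind = "PRE", potential = "sigmoid")
    } else {
      d0 <- pre_distance(r2sp_from_ratio(ratio, lw, p$t_evol), p)
      distance_restraints(res_a = label_residue, atom_a = "LABEL",
                          res_b = rn, atom_b = "H", d0 = d0,
                          lower = d0 - p$tol, upper = d0 + p$tol,
                          kind = "PRE", potential = "sigmoid")
    }
  })
  do.call(bind_restraints, rows)
}

#' Residual dipolar coupling from an IPAP quartet
#'
#' The 15N splitting of each arm is the in-phase / anti-phase 15N shift
#' difference converted from ppm to Hz at the 15N frequency; the RDC is the
#' aligned (paramagnetic) minus isotropic (diamagnetic) splitting.
#'
#' @param para_inphase,para_antiphase,dia_inphase,dia_antiphase peak records
#'   (rows with `shift_n_ppm`) for the same residue.
#' @param field_mhz 1H spectrometer frequency (MHz).
#' @return list with `residue`, `d_hz`, `sigma_hz`.
#' @export
rdc_from_ipap <- function(para_inphase, para_antiphase, dia_inphase,
                          dia_antiphase, field_mhz = 700) {
  quartet <- list(para_inphase, para_antiphase, dia_inphase, dia_antiphase)
  if (any(vapply(quartet, function(r) is.null(r$shift_n_ppm) ||
                 is.na(r$shift_n_ppm), logical(1))))
    stop("missing member of IPAP quartet")
  n_mhz <- field_mhz * GAMMA_N_OVER_H
  split_para <- abs(para_inphase$shift_n_ppm - para_antiphase$shift_n_ppm) * n_mhz
  split_dia <- abs(dia_inphase$shift_n_ppm - dia_antiphase$shift_n_ppm) * n_mhz
  sig <- vapply(quartet, function(r) r$noise %||% 0, numeric(1))
  list(residue = para_inphase$residue %||% NA_integer_,
       d_hz = split_para - split_dia,
       sigma_hz = sqrt(sum(sig^2)) * n_mhz)
}

#' NOE contact list to flat-bottom restraints
#'
#' @param noe_peaks data.frame with columns `residue_i`, `residue_j`,
#'   `class` in strong/medium/weak.
#' @param bounds named upper bounds (Angstrom) per class.
#' @param lower common lower bound (Angstrom).
#' @return `ff_restraints` table (CA-CA flat-bottom bounds).
#' @export
noes_to_restraints <- function(noe_peaks,
                               bounds = c(strong = 3.5, medium = 4.5, weak = 6.0),
                               lower = 1.8) {
  if (!nrow(noe_peaks)) return(empty_restraints())
  bad <- setdiff(unique(noe_peaks$class), names(bounds))
  if (length(bad)) stop("unknown NOE class: ", paste(bad, collapse = ", "))
  distance_restraints(res_a = noe_peaks$residue_i, atom_a = "CA",
                      res_b = noe_peaks$residue_j, atom_b = "CA",
                      d0 = NA, lower = lower,
                      upper = unname(bounds[noe_peaks$class]),
                      kind = "NOE", potential = "flat-bottom")
}
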