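## Iterative folding protocol: generate a pool of restraint-guided folds,
## rank by total score, cluster the top models, reseed the next round from
## cluster representatives, iterate to a score plateau, then refine.

#' Protocol configuration
#'
#' Defaults are desk-scale (pool of 40, top 10); the published-scale values
#' (pool of 1000, top 100, 3 A cutoff) are ordinary arguments.
#'
#' @param n_pool structures generated per iteration.
#' @param top_m structures kept for clustering.
#' @param rmsd_cutoff clustering cutoff (Angstrom CA RMSD).
#' @param max_iterations iteration cap.
#' @param window,tol convergence: declared when the best total score improves
#'   by less than `max(tol, tol_rel * |best|)` over the last `window`
#'   iterations and the top representative moves less than `rmsd_cutoff / 2`
#'   between iterations (the motion test is vacuous when `tol` is infinite).
#' @param tol_rel relative component of the plateau tolerance.
#' @param master_seed master RNG seed; every per-fold seed derives from it.
#' @param perturb_sigma Gaussian noise (Angstrom) applied to templates.
#' @param elitism carry the incumbent best model into the next pool, making
#'   the best score non-increasing across iterations.
#' @param schedule [anneal_schedule] prototype for the first, exploratory
#'   round (its seed is overridden per fold).
#' @param refine_schedule schedule for later rounds, which resample within
#'   the basins reseeded by the cluster representatives; defaults to the
#'   round-1 ladder with temperatures scaled by 0.3.
#' @param refine_perturb template perturbation in later rounds.
#' @return list of class `ff_protocol_config`.
#' @export
protocol_config <- function(n_pool = 40, top_m = 10, rmsd_cutoff = 3,
                            max_iterations = 6, window = 2, tol = 1.0,
                            tol_rel = 0.02, master_seed = 1,
                            perturb_sigma = 1.0, elitism = TRUE,
                            schedule = anneal_schedule(),
                            refine_schedule = NULL, refine_perturb = 0.5) {
  stopifnot(top_m <= n_pool, rmsd_cutoff > 0, n_pool >= 1)
  if (is.null(refine_schedule)) {
    refine_schedule <- schedule
    refine_schedule$temps <- schedule$temps * 0.2
    refine_schedule$rep_ramp <- rep(1, length(schedule$temps))
  }
  structure(list(n_pool = n_pool, top_m = top_m, rmsd_cutoff = rmsd_cutoff,
                 max_iterations = max_iterations, window = window, tol = tol,
                 tol_rel = tol_rel, master_seed = as.integer(master_seed),
                 perturb_sigma = perturb_sigma, elitism = elitism,
                 schedule = schedule, refine_schedule = refine_schedule,
                 refine_perturb = refine_perturb),
            class = "ff_protocol_config")
}

#' Generate a pool of independent folds
#'
#' Runs `n` independent [mc_fold] calls with per-run seeds derived from the
#' master seed; templates (if any) are cycled across runs and perturbed.
#'
#' @param templates list of single-chain [ff_structure] templates, or `NULL`
#'   for de novo starts.
#' @param n pool size (>= 1).
#' @param ss,restraints,score_cfg as in [mc_fold].
#' @param master_seed master seed for this pool.
#' @param config [protocol_config] supplying schedule and perturbation.
#' @return list of `ff_fold` objects.
#' @export
generate_pool <- function(templates, n, ss, restraints,
                          score_cfg = score_config(), master_seed = 1,
                          config = protocol_config(), refine = FALSE) {
  if (n < 1) stop("pool size must be >= 1")
  lapply(seq_len(n), function(i) {
    seed_i <- derive_seed(master_seed, i)
    tmpl <- if (is.null(templates) || !length(templates)) NULL
            else templates[[(i - 1) %% length(templates) + 1]]
    start <- init_conformation(n_res = length(ss), ss = ss, template = tmpl,
                               perturb_sigma = if (refine) config$refine_perturb
                                               else config$perturb_sigma,
                               seed = seed_i, rebuild_loops = !refine)
    sch <- if (refine) config$refine_schedule else config$schedule
    sch$seed <- derive_seed(seed_i, 2)
    mc_fold(start, ss, restraints, sch, score_cfg)
  })
}

pool_scores <- function(pool) {
  do.call(rbind, lapply(pool, function(f) f$score))
}

#' Rank a pool by total score and keep the best models
#'
#' @param pool list of `ff_fold`.
#' @param top_m number kept.
#' @return The `top_m` best folds in ascending `s_total`; ties broken by
#'   original pool position (stable).
#' @export
rank_and_select <- function(pool, top_m = length(pool)) {
  s <- vapply(pool, function(f) {
    if (is.null(f$score)) stop("fold without a score")
    f$score$s_total
  }, numeric(1))
  pool[order(s)][seq_len(min(top_m, length(pool)))]
}

#' Greedy leader clustering of a score-ranked ensemble
#'
#' The best-scoring unassigned model founds a cluster; every unassigned model
#' within the cutoff CA RMSD (after superposition) joins it; repeat.  Every
#' member is therefore within the cutoff of its representative, and
#' representatives have the lowest score within their cluster.
#'
#' @param selected list of `ff_fold` in ascending score order (see
#'   [rank_and_select]).
#' @param cutoff RMSD cutoff (Angstrom).
#' @return list with `assignments` (cluster id per model), `representatives`
#'   (indices into `selected`), `populations`.
#' @export
cluster_pool <- function(selected, cutoff = 3) {
  n <- length(selected)
  if (!n) stop("empty selection")
  assign <- rep(NA_integer_, n)
  reps <- integer(0)
  cl <- 0
  for (i in seq_len(n)) {
    if (!is.na(assign[i])) next
    cl <- cl + 1
    assign[i] <- cl
    reps[cl] <- i
    if (i < n) for (j in (i + 1):n) {
      if (is.na(assign[j]) &&
          ca_rmsd(selected[[i]]$model, selected[[j]]$model) <= cutoff)
        assign[j] <- cl
    }
  }
  list(assignments = assign, representatives = reps,
       populations = as.integer(table(factor(assign, levels = seq_len(cl)))))
}

#' Run the iterative fold-rank-cluster-reseed protocol
#'
#' Each iteration generates a pool (templated on the previous iteration's
#' cluster representatives; `templates0` is used only in the first round),
#' ranks it by total score, clusters the top models, and reseeds.  With
#' elitism the incumbent best fold is carried into every pool, so the best
#' score is non-increasing.  Convergence is a pure function of the iteration
#' log (see [protocol_config]).  Final representatives are passed through
#' [minimize_fold].
#'
#' @param config [protocol_config].
#' @param restraints `ff_restraints`.
#' @param ss secondary-structure annotation.
#' @param templates0 optional list of single-chain templates for round 1.
#' @param score_cfg [score_config].
#' @return list with `ensemble` ([ff_ensemble] of minimized representatives,
#'   best first, with scores), `folds` (the corresponding `ff_fold`s),
#'   `records` (per-iteration log), `converged` flag.
#' @export
run_protocol <- function(config = protocol_config(), restraints, ss,
                         templates0 = NULL, score_cfg = score_config()) {
  templates <- templates0
  incumbent <- NULL
  prev_rep <- NULL
  records <- data.frame()
  converged <- FALSE
  final_sel <- NULL
  for (it in seq_len(config$max_iterations)) {
    pool <- generate_pool(templates, config$n_pool, ss, restraints, score_cfg,
                          master_seed = derive_seed(config$master_seed, it),
                          config = config, refine = it > 1)
    if (config$elitism && !is.null(incumbent)) pool <- c(pool, list(incumbent))
    sel <- rank_and_select(pool, config$top_m)
    cl <- cluster_pool(sel, config$rmsd_cutoff)
    incumbent <- sel[[1]]
    rep_move <- if (is.null(prev_rep)) NA_real_
                else ca_rmsd(sel[[1]]$model, prev_rep)
    prev_rep <- sel[[1]]$model
    records <- rbind(records, data.frame(
      iteration = it, best_total = sel[[1]]$score$s_total,
      n_clusters = length(cl$representatives),
      top_population = cl$populations[1], rep_move = rep_move))
    final_sel <- sel
    templates <- lapply(cl$representatives, function(i)
      subunit_from_xyz(sel[[i]]$subunit, unique(sel[[i]]$model$atoms$resno)))
    if (protocol_converged(records, config)) { converged <- TRUE; break }
  }
  reps_idx <- cluster_pool(final_sel, config$rmsd_cutoff)$representatives
  folds <- lapply(reps_idx, function(i)
    minimize_fold(final_sel[[i]], ss, restraints, score_cfg, n_steps = 600,
                  seed = derive_seed(config$master_seed, 999 + i)))
  folds <- folds[order(vapply(folds, function(f) f$score$s_total, numeric(1)))]
  ens <- ff_ensemble(lapply(folds, `[[`, "model"),
                     scores = do.call(rbind, lapply(folds, `[[`, "score")))
  list(ensemble = ens, folds = folds, records = records, converged = converged)
}

#' Convergence decision from the iteration log
#'
#' @param records iteration log as produced by [run_protocol].
#' @param config [protocol_config].
#' @return TRUE when the plateau criterion holds at the last logged iteration.
#' @export
protocol_converged <- function(records, config) {
  it <- nrow(records)
  if (it < config$window) return(FALSE)
  drop <- records$best_total[it - config$window + 1] - records$best_total[it]
  tol <- max(config$tol, config$tol_rel * abs(records$best_total[it]))
  if (!(drop < tol)) return(FALSE)
  if (!is.finite(config$tol)) return(TRUE) # vacuous plateau: motion test bypassed
  rm <- records$rep_move[it]
  !is.na(rm) && rm < config$rmsd_cutoff / 2
}
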