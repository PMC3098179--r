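# The Lamarckian genetic algorithm -- the unit of work parallelized across
# threads -- plus Solis-Wets local search and deterministic per-run seeding.
# The hot loop lives in compiled code; this file owns seeding, the search
# control block, and the buffered per-run log.

#' Derive a run seed
#'
#' `base_seed + run_index`: injective in the run index for a fixed base, so
#' every concurrent run draws from its own independent stream, and the
#' result of a run does not depend on which thread or worker executed it.
#' When the configured base seed is `"time"`, the base is sampled once per
#' docking and then fixed.
#'
#' @param base_seed integer base.
#' @param run_index 1-based run number.
#' @return the run's seed.
#' @export
make_seed <- function(base_seed, run_index) {
  if (run_index < 1) stop("run_index must be >= 1")
  base_seed + run_index
}

.resolve_base_seed <- function(seed) {
  if (identical(seed, "time")) as.numeric(Sys.time()) %% 2^31 else as.numeric(seed)
}

#' Search control settings
#'
#' Tunables of the genetic search and local minimizer, with the engine
#' defaults: crossover rate 0.8 (two-point, at gene boundaries), per-gene
#' Cauchy mutation rate 0.02 with scales 2.0 Angstrom (translation genes),
#' 0.2 rad (orientation perturbation angle) and 30 degrees (torsions),
#' elitism of 1, and Solis-Wets with initial step 1.0, termination step
#' 0.01, expansion/contraction after 4 consecutive successes/failures, at
#' most 300 iterations per invocation, and per-gene scales of 1.0 Angstrom
#' (translation), 0.3 rad (orientation) and 30 degrees (torsion).
#'
#' @param ... named overrides.
#' @return a named list.
#' @export
search_control <- function(...) {
  ctl <- list(
    crossover_rate = 0.8,
    mutation_rate = 0.02,
    mutation_scale_translation = 2.0,
    mutation_scale_orientation = 0.2,
    mutation_scale_torsion = 30,
    sw_max_its = 300L,
    sw_rho0 = 1.0,
    sw_rho_min = 0.01,
    sw_max_consec = 4L,
    sw_scale_translation = 1.0,
    sw_scale_orientation = 0.3,
    sw_scale_torsion = 30
  )
  over <- list(...)
  bad <- setdiff(names(over), names(ctl))
  if (length(bad)) stop("unknown control(s): ", paste(bad, collapse = ", "))
  ctl[names(over)] <- over
  ctl
}

#' Solis-Wets local search
#'
#' Adaptive random-walk minimization of `score_fn` over a real vector:
#' propose `x + bias + rho * scales * N(0, 1)`, accept on strict energy
#' decrease; on success `bias <- 0.2 bias + 0.4 dx`, on failure
#' `bias <- 0.5 bias`; `rho` doubles after 4 consecutive successes and
#' halves after 4 consecutive failures; stops when `rho < rho_min`
#' (default 0.01) or the evaluation budget is exhausted. The returned
#' energy never exceeds the starting energy.
#'
#' @param start numeric start vector.
#' @param score_fn function of one numeric vector returning a single energy.
#' @param budget maximum number of score evaluations (>= 0); the start is
#'   scored once before the walk and not counted against the budget.
#' @param seed stream seed (the walk uses the package's portable generator).
#' @param scales per-gene step scales (recycled if length 1).
#' @param rho0,rho_min,max_consec step-size schedule.
#' @return list with `x`, `energy` and `evals` (evaluations spent).
#' @export
solis_wets <- function(start, score_fn, budget, seed, scales = 1,
                       rho0 = 1.0, rho_min = 0.01, max_consec = 4L) {
  if (budget < 0) stop("budget must be >= 0")
  start <- as.numeric(start)
  if (budget == 0) {
    return(list(x = start, energy = score_fn(start), evals = 0L))
  }
  res <- cpp_solis_wets_vec(start, function(x) as.numeric(score_fn(x)),
                            as.numeric(scales), as.integer(budget),
                            as.numeric(seed), rho0, rho_min,
                            as.integer(max_consec))
  res$evals <- as.integer(res$evals)
  res
}

# assemble the C++ control block for one run
.lga_control <- function(params, control, emap_blob) {
  n <- emap_blob$n
  lo <- emap_blob$origin
  hi <- emap_blob$origin + (n - 1) * emap_blob$spacing
  c(list(ga_popsize = as.integer(params$ga_popsize),
         ga_num_evals = as.numeric(params$ga_num_evals),
         ga_num_generations = as.numeric(params$ga_num_generations),
         ls_frequency = params$ls_frequency,
         box_lo = lo, box_hi = hi),
    control)
}

#' Run one Lamarckian GA docking run
#'
#' One independent LGA execution: a population of `ga_popsize` random
#' genomes (translation uniform in the grid box, orientation uniform on the
#' quaternion sphere, torsions uniform in (-180, 180]) evolved by
#' rank-proportional selection, two-point crossover at gene boundaries,
#' per-gene Cauchy mutation and elitism of 1, with Solis-Wets applied to
#' each individual with probability `ls_frequency` and improved genomes
#' written back (Lamarckian inheritance). The run terminates when the
#' evaluation budget (`ga_num_evals`, with at most one generation of
#' overshoot) or the generation budget (`ga_num_generations`) is met.
#'
#' The run is a pure function of (ligand, parameters, map contents, seed):
#' repeated execution, on any thread or worker, returns a bit-identical
#' result. All log lines are accumulated in `log_buffer` (one line per
#' generation: generation, evaluations, best and mean energy) and none are
#' emitted during execution.
#'
#' @param ligand a `ligand`.
#' @param params a `docking_parameters` object.
#' @param cache a `map_cache` with the ligand's maps resident or loadable.
#' @param seed this run's stream seed (see [make_seed()]).
#' @param run_index 1-based run number within its docking.
#' @param sources optional named map-path vector for lazy loading.
#' @param control a [search_control()] list.
#' @param pairs optional precomputed [eligible_pairs()].
#' @return an object of class `lga_run`: `run_index`, `seed`, `best_state`
#'   (a `genome_state`), `best_energy`, `best_coords`, `generations_done`,
#'   `evals_used`, `log_buffer`.
#' @export
run_lga <- function(ligand, params, cache, seed, run_index = 1L,
                    sources = NULL, control = search_control(),
                    pairs = NULL) {
  if (params$ga_popsize < 1) stop("ga_popsize must be >= 1")
  if (is.null(pairs)) pairs <- eligible_pairs(ligand)
  ms <- .map_set(ligand, cache, sources)
  coords <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  ctl <- .lga_control(params, control, ms$emap)
  res <- cpp_run_lga(coords, ligand$atoms$charge, ms$type_idx, ligand$root,
                     ligand$edges, pairs, ms$aff, ms$emap, ms$dmap, ctl,
                     as.numeric(seed))
  gl <- res$genlog
  log_buffer <- sprintf("gen %d evals %d best %.6f mean %.6f",
                        as.integer(gl[, "generation"]),
                        as.integer(gl[, "evals"]),
                        gl[, "best"], gl[, "mean"])
  structure(list(
    run_index = as.integer(run_index),
    seed = as.numeric(seed),
    best_state = genome_state(res$best_translation, res$best_quaternion,
                              res$best_torsions),
    best_energy = res$best_energy,
    best_coords = res$best_coords,
    generations_done = as.integer(res$generations_done),
    evals_used = as.integer(res$evals_used),
    genlog = gl,
    log_buffer = log_buffer
  ), class = "lga_run")
}

#' @export
print.lga_run <- function(x, ...) {
  cat(sprintf("LGA run %d (seed %.0f): best %.4f kcal/mol after %d generations, %d evals\n",
              x$run_index, x$seed, x$best_energy, x$generations_done,
              x$evals_used))
  invisible(x)
}
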