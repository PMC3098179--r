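# One docking: ga_runs independent LGA runs executed serially or
# concurrently, collected in run-index order, then clustered (greedy leader
# clustering on best poses) and ranked; plus the serial-vs-parallel output
# comparison used to certify that concurrency leaves results unchanged.

#' Dock one ligand
#'
#' Executes `params$ga_runs` independent LGA runs, run `k` seeded with
#' `make_seed(base, k)`. With `concurrency > 1` the runs execute on forked
#' processes, but results are collected and ordered by run index, so the
#' result -- energies, poses, logs, clustering, ranking -- is bit-identical
#' for any concurrency level. Runs are then clustered with
#' [cluster_runs()] at `params$cluster_tolerance`.
#'
#' @param ligand a `ligand`.
#' @param params a `docking_parameters`.
#' @param cache a `map_cache`; the ligand's maps are made resident before
#'   any run starts.
#' @param concurrency number of concurrent run executors (>= 1).
#' @param sources optional named map-path vector for lazy loading.
#' @param control a [search_control()] list.
#' @param job_id label recorded in the result and its log.
#' @return an object of class `docking_result`: `job_id`, `runs`,
#'   `clusters` (ordered list of run-index vectors), `status`
#'   (`"success"`/`"failure"`), `failure_reason`, `cluster_tolerance`,
#'   `base_seed`.
#' @export
dock <- function(ligand, params, cache, concurrency = 1L, sources = NULL,
                 control = search_control(), job_id = ligand$source_id) {
  if (concurrency < 1) stop("concurrency must be >= 1")
  base <- .resolve_base_seed(params$seed)
  cache_begin_docking(cache, unique(ligand$atoms$type), sources)
  pairs <- eligible_pairs(ligand)
  one <- function(k) {
    run_lga(ligand, params, cache, seed = make_seed(base, k), run_index = k,
            sources = sources, control = control, pairs = pairs)
  }
  idx <- seq_len(params$ga_runs)
  runs <- if (concurrency == 1L) {
    lapply(idx, one)
  } else {
    out <- parallel::mclapply(idx, one, mc.cores = concurrency,
                              mc.preschedule = TRUE)
    bad <- vapply(out, inherits, TRUE, "try-error")
    if (any(bad)) {
      reason <- as.character(out[[which(bad)[1]]])
      return(structure(list(job_id = job_id, runs = out[!bad],
                            clusters = list(), status = "failure",
                            failure_reason = reason,
                            cluster_tolerance = params$cluster_tolerance,
                            base_seed = base),
                       class = "docking_result"))
    }
    out
  }
  cache_end_docking(cache)
  res <- structure(list(
    job_id = job_id,
    runs = runs,
    clusters = cluster_runs(runs, params$cluster_tolerance),
    status = "success",
    failure_reason = "",
    cluster_tolerance = params$cluster_tolerance,
    base_seed = base
  ), class = "docking_result")
  res
}

#' Cluster docking runs by pose RMSD
#'
#' Greedy leader clustering on the runs' best poses: the lowest-energy
#' unassigned pose seeds a cluster; every unassigned pose within `tol`
#' Angstrom RMSD of the seed pose joins it; repeat until all runs are
#' assigned. Within a cluster, members are ordered by energy ascending;
#' clusters are ordered by their lowest member energy ascending. Energy
#' ties are broken by lower run index, making the partition fully
#' deterministic.
#'
#' @param runs list of `lga_run` objects sharing one ligand.
#' @param tol clustering tolerance in Angstrom (> 0).
#' @return ordered list of integer vectors of run indices (positions in
#'   `runs`); empty list for an empty run list.
#' @export
cluster_runs <- function(runs, tol) {
  if (tol <= 0) stop("tol must be > 0")
  n <- length(runs)
  if (n == 0) return(list())
  energies <- vapply(runs, `[[`, 0, "best_energy")
  ord <- order(energies, seq_len(n))  # energy ascending, run index tie-break
  assigned <- logical(n)
  clusters <- list()
  for (s in ord) {
    if (assigned[s]) next
    seed_pose <- runs[[s]]$best_coords
    members <- s
    assigned[s] <- TRUE
    for (m in ord) {
      if (assigned[m]) next
      if (rmsd(runs[[m]]$best_coords, seed_pose) <= tol) {
        members <- c(members, m)
        assigned[m] <- TRUE
      }
    }
    clusters[[length(clusters) + 1L]] <- members  # already energy-ordered
  }
  clusters
}

# largest cluster; size ties broken by lower cluster rank (lower energy)
.largest_cluster <- function(result) {
  sizes <- lengths(result$clusters)
  which.max(sizes)  # first maximum = lowest-rank among ties
}

# pose selections of the output-comparison procedure
.lowest_energy_run <- function(result) {
  energies <- vapply(result$runs, `[[`, 0, "best_energy")
  order(energies, seq_along(energies))[1]
}

#' Compare two docking results
#'
#' The serial-vs-parallel comparison: the RMSD between the two results'
#' overall lowest-energy poses, and between their lowest-energy members of
#' the largest cluster. When a result's lowest-energy pose is not in its
#' largest cluster the two selections differ and the lesser of the two
#' RMSD values is returned; when they coincide the values are equal.
#'
#' @param a,b `docking_result` objects for the same ligand and job.
#' @return RMSD in Angstrom.
#' @export
compare_results <- function(a, b) {
  na <- nrow(a$runs[[1]]$best_coords)
  nb <- nrow(b$runs[[1]]$best_coords)
  if (na != nb) stop("results come from incompatible ligands")
  low_a <- .lowest_energy_run(a)
  low_b <- .lowest_energy_run(b)
  v_low <- rmsd(a$runs[[low_a]]$best_coords, b$runs[[low_b]]$best_coords)
  big_a <- a$clusters[[.largest_cluster(a)]][1]
  big_b <- b$clusters[[.largest_cluster(b)]][1]
  v_big <- rmsd(a$runs[[big_a]]$best_coords, b$runs[[big_b]]$best_coords)
  separated <- !(low_a %in% a$clusters[[.largest_cluster(a)]]) ||
    !(low_b %in% b$clusters[[.largest_cluster(b)]])
  if (separated) min(v_low, v_big) else v_low
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("docking '%s': %s, %d runs, %d clusters",
              x$job_id, x$status, length(x$runs), length(x$clusters)))
  if (x$status == "success" && length(x$runs)) {
    best <- min(vapply(x$runs, `[[`, 0, "best_energy"))
    cat(sprintf(", best %.4f kcal/mol", best))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.docking_result <- function(object, ...) {
  energies <- vapply(object$runs, `[[`, 0, "best_energy")
  data.frame(
    cluster = seq_along(object$clusters),
    size = lengths(object$clusters),
    best_energy = vapply(object$clusters, function(m) energies[m[1]], 0),
    lead_run = vapply(object$clusters, `[[`, 0L, 1)
  )
}
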