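# The screen driver: master-worker job dispatch with per-worker map caches,
# the three progress logs (submitted / successful / failed), optional
# torsion-sorted dispatch, and per-docking phase profiling. The coordinator
# never docks; workers are either simulated in-process (default) or real
# forked processes, and jobs are assigned to workers cyclically in dispatch
# order, which keeps the assignment -- and therefore per-worker map-read
# accounting -- deterministic.

#' Screen configuration
#'
#' @param joblist_path path to the job-list file (one docking directory per
#'   line), or `NULL` when `jobs` is given directly to [run_screen()].
#' @param worker_count number of workers (>= 1).
#' @param threads_per_docking concurrent LGA runs within each docking (>= 1).
#' @param map_policy `"reuse"` (maps persist per worker for the screen) or
#'   `"reload"` (re-read every docking).
#' @param sort_by_torsions dispatch ligands in descending torsion count.
#' @param profiling record per-docking phase timings.
#' @param base_seed integer, or `"time"` (sampled once per docking).
#' @param output_root directory for progress logs, profile and docking logs;
#'   `NULL` disables file output (the report still carries everything).
#' @param transport `"inprocess"` (simulated workers, default) or `"fork"`
#'   (one forked process per worker).
#' @param job_timeout per-job wall-clock limit in seconds (guards liveness).
#' @param control a [search_control()] list passed to every docking.
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(joblist_path = NULL, worker_count = 1L,
                          threads_per_docking = 1L,
                          map_policy = c("reuse", "reload"),
                          sort_by_torsions = FALSE, profiling = TRUE,
                          base_seed = "time", output_root = NULL,
                          transport = c("inprocess", "fork"),
                          job_timeout = 600, control = search_control()) {
  map_policy <- match.arg(map_policy)
  transport <- match.arg(transport)
  if (worker_count < 1) stop("worker_count must be >= 1")
  if (threads_per_docking < 1) stop("threads_per_docking must be >= 1")
  structure(list(
    joblist_path = joblist_path,
    worker_count = as.integer(worker_count),
    threads_per_docking = as.integer(threads_per_docking),
    map_policy = map_policy,
    sort_by_torsions = isTRUE(sort_by_torsions),
    profiling = isTRUE(profiling),
    base_seed = base_seed,
    output_root = output_root,
    transport = transport,
    job_timeout = job_timeout,
    control = control
  ), class = "screen_config")
}

#' Read a job-list file
#'
#' One docking directory per line; blank lines are skipped; order is
#' preserved. Each directory is expected to contain `job.dpf`,
#' `ligand.pdbqt` and `maps.fld`.
#'
#' @param path job-list file.
#' @return character vector of job directories (possibly empty).
#' @export
read_joblist <- function(path) {
  if (!file.exists(path)) stop("cannot read job list '", path, "'")
  lines <- trimws(readLines(path, warn = FALSE))
  jobs <- lines[nzchar(lines)]
  if (length(jobs) == 0) warning("empty screen: job list has no entries",
                                 call. = FALSE)
  jobs
}

#' Order jobs for dispatch
#'
#' With `sort_by_torsions` off, the input order; on, a stable sort by the
#' ligand's torsion count descending (ties keep input order), so complex
#' ligands are dispatched first and workers run out of work together. Jobs
#' whose ligand cannot be parsed are routed directly to the failed set.
#'
#' @param jobs character vector of job directories.
#' @param sort_by_torsions logical flag.
#' @return list with `jobs` (ordered dispatchable jobs) and `failed`
#'   (data.frame `job`, `reason` for unparseable ligands).
#' @export
order_jobs <- function(jobs, sort_by_torsions = FALSE) {
  failed <- data.frame(job = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  if (!sort_by_torsions || length(jobs) == 0) {
    return(list(jobs = jobs, failed = failed))
  }
  ntor <- rep(NA_integer_, length(jobs))
  for (k in seq_along(jobs)) {
    lig <- tryCatch(read_pdbqt(file.path(jobs[k], "ligand.pdbqt")),
                    error = function(e) e)
    if (inherits(lig, "error")) {
      failed <- rbind(failed, data.frame(job = jobs[k],
                                         reason = conditionMessage(lig),
                                         stringsAsFactors = FALSE))
    } else {
      ntor[k] <- lig$n_torsions
    }
  }
  keep <- !is.na(ntor)
  ord <- order(-ntor[keep], seq_len(sum(keep)))  # stable descending
  list(jobs = jobs[keep][ord], failed = failed)
}

.phase_names <- c("fld", "map", "lig", "compute", "log")

# run one job on a worker: load phases, docking, log write; returns the
# docking result plus a profile row; errors inside become status "failure"
.run_job <- function(job, cache, cfg) {
  t_dispatch <- as.numeric(Sys.time())
  phases <- stats::setNames(rep(0, length(.phase_names)), .phase_names)
  result <- NULL
  status <- "success"
  reason <- ""
  timed <- function(name, expr) {
    t0 <- as.numeric(Sys.time())
    on.exit(phases[name] <<- phases[name] + (as.numeric(Sys.time()) - t0))
    expr
  }
  out <- tryCatch({
    if (is.finite(cfg$job_timeout)) {
      setTimeLimit(elapsed = cfg$job_timeout, transient = TRUE)
      on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
    }
    params <- parse_parameters(file.path(job, "job.dpf"), quiet = TRUE)
    # a numeric seed in the job's parameter file is authoritative; the
    # screen-level base seed only replaces time-sampled ones, so results
    # stay a function of the job alone, not of worker assignment
    if (!identical(cfg$base_seed, "time") && identical(params$seed, "time")) {
      params$seed <- cfg$base_seed
    }
    sources <- timed("fld", read_fld(file.path(job, "maps.fld")))
    ligand <- timed("lig", read_pdbqt(file.path(job, "ligand.pdbqt")))
    timed("map", cache_begin_docking(cache, unique(ligand$atoms$type), sources))
    res <- timed("compute",
                 dock(ligand, params, cache,
                      concurrency = cfg$threads_per_docking,
                      sources = sources, control = cfg$control,
                      job_id = job))
    timed("log", {
      dlg <- write_dlg(res)
      if (!is.null(cfg$output_root)) {
        writeLines(dlg, file.path(cfg$output_root,
                                  paste0(gsub("[/\\\\]", "_", job), ".dlg")))
      }
    })
    res
  }, error = function(e) e)
  cache_end_docking(cache)  # even after a failure: reload must not leak maps
  if (inherits(out, "error")) {
    status <- "failure"
    reason <- conditionMessage(out)
  } else if (out$status == "failure") {
    result <- out
    status <- "failure"
    reason <- out$failure_reason
  } else {
    result <- out
  }
  t_done <- as.numeric(Sys.time())
  profile <- data.frame(
    job_id = job,
    dispatch_time = t_dispatch, completion_time = t_done,
    fld_s = phases[["fld"]], map_s = phases[["map"]], lig_s = phases[["lig"]],
    compute_s = phases[["compute"]], log_s = phases[["log"]],
    total_s = t_done - t_dispatch,
    status = status,
    stringsAsFactors = FALSE)
  list(result = result, status = status, reason = reason, profile = profile)
}

# one worker's whole queue; returns results, profile rows, and the worker's
# map-read counters -- the worker's completion message to the master
.run_worker <- function(wjobs, cfg, worker_id) {
  cache <- map_cache(cfg$map_policy)
  results <- vector("list", length(wjobs))
  statuses <- character(length(wjobs))
  reasons <- character(length(wjobs))
  profiles <- list()
  for (k in seq_along(wjobs)) {
    r <- .run_job(wjobs[k], cache, cfg)
    results[k] <- list(r$result)  # keep NULL slots for failed jobs
    statuses[k] <- r$status
    reasons[k] <- r$reason
    r$profile$worker <- worker_id
    profiles[[k]] <- r$profile
  }
  list(jobs = wjobs, results = results, statuses = statuses,
       reasons = reasons,
       profile = do.call(rbind, c(profiles,
                                  list(make.row.names = FALSE))),
       load_counts = cache_load_counts(cache))
}

#' Run a virtual screen
#'
#' The coordinator reads the job list, optionally reorders it by torsion
#' count, appends every dispatched job to the submitted log, assigns jobs
#' to `worker_count` workers cyclically in dispatch order, and records each
#' worker's completion messages in the successful or failed log. Each
#' worker holds a private [map_cache()] for its lifetime under the
#' configured policy, and each docking runs its LGA runs with
#' `threads_per_docking`-way concurrency. A failing job (e.g. a grid index
#' naming a missing map) is recorded with its reason and the screen
#' continues; a crashed or timed-out worker fails its remaining jobs rather
#' than hanging the screen. Given a fixed `base_seed`, the per-job docking
#' results are bit-identical for any `worker_count` and
#' `threads_per_docking`.
#'
#' @param config a [screen_config()]; alternatively pass `jobs` directly.
#' @param jobs optional character vector of job directories overriding the
#'   job-list file.
#' @return an object of class `screen_report`: `submitted`, `successful`,
#'   `failed` (data.frame `job`, `reason`), `results` (named by job, in
#'   submitted order), `profile` (data.frame, one row per finished
#'   docking), `load_counts` (per-worker list of map-read counters),
#'   `assignment` (worker index per submitted job).
#' @export
run_screen <- function(config, jobs = NULL) {
  cfg <- config
  if (is.null(jobs)) {
    if (is.null(cfg$joblist_path)) stop("no job list configured")
    jobs <- read_joblist(cfg$joblist_path)
  }
  if (!is.null(cfg$output_root) &&
      !dir.exists(cfg$output_root)) {
    dir.create(cfg$output_root, recursive = TRUE)
  }
  if (anyDuplicated(jobs)) stop("duplicate job ids in the screen")

  ordered <- order_jobs(jobs, cfg$sort_by_torsions)
  pre_failed <- ordered$failed
  jobs <- ordered$jobs

  submitted <- c(jobs, pre_failed$job)
  nw <- min(cfg$worker_count, max(1L, length(jobs)))
  assignment <- if (length(jobs)) ((seq_along(jobs) - 1L) %% nw) + 1L else integer(0)

  worker_out <- if (length(jobs) == 0) {
    list()
  } else if (cfg$transport == "fork" && nw > 1L) {
    out <- parallel::mclapply(seq_len(nw), function(w) {
      .run_worker(jobs[assignment == w], cfg, w)
    }, mc.cores = nw, mc.preschedule = FALSE)
    for (w in seq_len(nw)) {
      if (inherits(out[[w]], "try-error")) {
        wjobs <- jobs[assignment == w]
        out[[w]] <- list(jobs = wjobs, results = vector("list", length(wjobs)),
                         statuses = rep("failure", length(wjobs)),
                         reasons = rep("worker crashed", length(wjobs)),
                         profile = NULL, load_counts = integer(0))
      }
    }
    out
  } else {
    lapply(seq_len(nw), function(w) .run_worker(jobs[assignment == w], cfg, w))
  }

  # collate completion messages in submitted order
  status_by_job <- character(0)
  reason_by_job <- character(0)
  results <- stats::setNames(vector("list", length(jobs)), jobs)
  for (w in seq_along(worker_out)) {
    wo <- worker_out[[w]]
    for (k in seq_along(wo$jobs)) {
      status_by_job[wo$jobs[k]] <- wo$statuses[k]
      reason_by_job[wo$jobs[k]] <- wo$reasons[k]
      results[wo$jobs[k]] <- list(wo$results[[k]])
    }
  }
  successful <- jobs[status_by_job[jobs] == "success"]
  failed <- data.frame(
    job = jobs[status_by_job[jobs] == "failure"],
    reason = unname(reason_by_job[jobs[status_by_job[jobs] == "failure"]]),
    stringsAsFactors = FALSE)
  failed <- rbind(failed, pre_failed)

  profile <- do.call(rbind, c(Filter(Negate(is.null),
                                     lapply(worker_out, `[[`, "profile")),
                              list(make.row.names = FALSE)))

  report <- structure(list(
    submitted = submitted,
    successful = successful,
    failed = failed,
    results = results,
    profile = profile,
    load_counts = lapply(worker_out, `[[`, "load_counts"),
    assignment = assignment,
    config = cfg
  ), class = "screen_report")

  if (!is.null(cfg$output_root)) {
    writeLines(submitted, file.path(cfg$output_root, "submitted.log"))
    writeLines(successful, file.path(cfg$output_root, "successful.log"))
    writeLines(if (nrow(failed)) paste(failed$job, failed$reason, sep = "\t")
               else character(0),
               file.path(cfg$output_root, "failed.log"))
    if (cfg$profiling && !is.null(profile)) {
      write_profile(profile, file.path(cfg$output_root, "profile.csv"))
    }
  }
  report
}

#' Write the profiling log
#'
#' One comma-delimited line per finished docking in a fixed column order
#' (job id, worker, dispatch and completion timestamps, per-phase durations
#' for grid-index/map/ligand loading, compute and log writing, total, and
#' status), with the header written once per file.
#'
#' @param profile profiling data.frame from a [run_screen()] report.
#' @param file output path; an existing profile file is appended to without
#'   repeating the header.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, file) {
  cols <- c("job_id", "worker", "dispatch_time", "completion_time",
            "fld_s", "map_s", "lig_s", "compute_s", "log_s", "total_s",
            "status")
  utils::write.table(profile[, cols], file, sep = ",",
                     row.names = FALSE, col.names = !file.exists(file),
                     append = file.exists(file), quote = FALSE)
  invisible(file)
}

#' Per-phase profile statistics
#'
#' Average, root-mean-square, median and maximum of each phase duration
#' across the screen's dockings (the summary a profiling log is read for;
#' wall-clock values are hardware-dependent by nature).
#'
#' @param profile profiling data.frame from a [run_screen()] report.
#' @return data.frame with one row per statistic.
#' @export
profile_summary <- function(profile) {
  ph <- c("fld_s", "map_s", "lig_s", "compute_s", "log_s")
  out <- rbind(
    ave = vapply(profile[ph], mean, 0),
    rms = vapply(profile[ph], function(x) sqrt(mean(x^2)), 0),
    med = vapply(profile[ph], stats::median, 0),
    max = vapply(profile[ph], max, 0))
  as.data.frame(out)
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("screen: %d submitted, %d successful, %d failed (%d worker(s), policy %s)\n",
              length(x$submitted), length(x$successful), nrow(x$failed),
              length(x$load_counts), x$config$map_policy))
  invisible(x)
}

#' @export
summary.screen_report <- function(object, ...) {
  list(accounting = c(submitted = length(object$submitted),
                      successful = length(object$successful),
                      failed = nrow(object$failed)),
       map_reads = vapply(object$load_counts, sum, 0),
       phases = if (!is.null(object$profile)) profile_summary(object$profile))
}
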