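# The screen driver: job list, dispatch ordering, the three progress logs,
# per-worker map accounting and profiling.

test_that("the job list preserves order, skips blanks and may be empty", {
  d <- withr::local_tempdir()
  f <- file.path(d, "joblist.txt")
  writeLines(c("jobs/a", "jobs/b", "jobs/c", ""), f)
  expect_equal(read_joblist(f), c("jobs/a", "jobs/b", "jobs/c"))
  writeLines(character(0), f)
  expect_warning(jobs <- read_joblist(f), "empty screen")
  expect_length(jobs, 0)
  # an empty screen yields a valid empty report
  cfg <- screen_config(worker_count = 2, base_seed = 1, profiling = FALSE)
  rep0 <- suppressWarnings(run_screen(cfg, jobs = character(0)))
  expect_length(rep0$submitted, 0)
  expect_length(rep0$successful, 0)
  expect_equal(nrow(rep0$failed), 0)
})

test_that("torsion sorting is stable, descending and optional", {
  d <- withr::local_tempdir()
  counts <- c(2, 5, 5, 0)
  jobs <- character(4)
  for (k in 1:4) {
    jd <- file.path(d, sprintf("j%d", k))
    dir.create(jd)
    spec <- toy_complex_spec(ligand_atoms = counts[k] + 2L,
                             ligand_torsions = counts[k])
    make_toy_ligand(spec, file.path(jd, "ligand.pdbqt"))
    jobs[k] <- jd
  }
  off <- order_jobs(jobs, sort_by_torsions = FALSE)
  expect_equal(off$jobs, jobs)
  on <- order_jobs(jobs, sort_by_torsions = TRUE)
  expect_equal(on$jobs, jobs[c(2, 3, 1, 4)])  # the two 5s keep input order
  # all-equal counts: identity
  same <- order_jobs(jobs[c(2, 3)], sort_by_torsions = TRUE)
  expect_equal(same$jobs, jobs[c(2, 3)])
  # unparseable ligand routed to the failed set
  bad <- file.path(d, "bad")
  dir.create(bad)
  writeLines(c("ROOT", "garbage"), file.path(bad, "ligand.pdbqt"))
  mixed <- order_jobs(c(jobs[1], bad), sort_by_torsions = TRUE)
  expect_equal(mixed$jobs, jobs[1])
  expect_equal(mixed$failed$job, bad)
})

test_that("a full screen accounts for every job across workers", {
  d <- withr::local_tempdir()
  joblist <- make_screen(6, d, params = fast_params())
  cfg <- screen_config(joblist, worker_count = 2, base_seed = 5,
                       output_root = file.path(d, "out"))
  rep <- run_screen(cfg)
  expect_length(rep$submitted, 6)
  expect_length(rep$successful, 6)
  expect_equal(nrow(rep$failed), 0)
  # progress logs on disk mirror the report
  expect_equal(readLines(file.path(d, "out", "submitted.log")), rep$submitted)
  expect_equal(readLines(file.path(d, "out", "successful.log")), rep$successful)
  expect_length(readLines(file.path(d, "out", "failed.log")), 0)
  # one DLG per job
  expect_length(list.files(file.path(d, "out"), pattern = "\\.dlg$"), 6)
})

test_that("a job with a missing map file fails with the missing-type reason", {
  d <- withr::local_tempdir()
  joblist <- make_screen(1, d, params = fast_params())
  job <- read_joblist(joblist)[1]
  file.remove(file.path(job, "receptor.C.map"))
  rep <- run_screen(screen_config(joblist, base_seed = 1, profiling = FALSE))
  expect_length(rep$successful, 0)
  expect_equal(rep$failed$job, job)
  expect_match(rep$failed$reason, "missing map.*'C'")
  expect_length(rep$submitted, 1)
})

test_that("map reads per worker follow the reuse and reload I/O laws", {
  d <- withr::local_tempdir()
  joblist <- varied_screen(file.path(d, "s"))
  jobs <- read_joblist(joblist)
  # independent set-union oracle over each job's ligand types
  types_of <- function(job)
    unique(read_pdbqt(file.path(job, "ligand.pdbqt"))$atoms$type)
  type_sets <- lapply(jobs, types_of)
  expect_equal(type_sets, list("C", c("C", "N"), c("C", "N", "O")))

  for (wc in c(1, 2)) {
    assignment <- ((seq_along(jobs) - 1) %% wc) + 1
    rep_reuse <- run_screen(screen_config(joblist, worker_count = wc,
                                          map_policy = "reuse",
                                          base_seed = 2, profiling = FALSE))
    rep_reload <- run_screen(screen_config(joblist, worker_count = wc,
                                           map_policy = "reload",
                                           base_seed = 2, profiling = FALSE))
    for (w in seq_len(wc)) {
      mine <- which(assignment == w)
      union_reads <- length(unique(unlist(type_sets[mine]))) + 2
      sum_reads <- sum(lengths(type_sets[mine]) + 2)
      expect_equal(sum(rep_reuse$load_counts[[w]]), union_reads)
      expect_equal(sum(rep_reload$load_counts[[w]]), sum_reads)
    }
    total_reuse <- sum(unlist(rep_reuse$load_counts))
    total_reload <- sum(unlist(rep_reload$load_counts))
    expect_lte(total_reuse, total_reload)
  }
})

test_that("the three-log accounting identity holds under injected failures", {
  d <- withr::local_tempdir()
  set.seed(99)
  for (trial in 1:5) {
    sd <- file.path(d, sprintf("t%d", trial))
    n <- sample(3:6, 1)
    joblist <- make_screen(n, sd, mode = "varied", params = fast_params())
    jobs <- read_joblist(joblist)
    # break a random subset of jobs by deleting one of their map files
    broken <- sample(jobs, sample(0:n, 1))
    for (b in broken) {
      maps <- list.files(b, pattern = "\\.map$", full.names = TRUE)
      file.remove(sample(maps, 1))
    }
    # reload policy so every docking touches its own files: a deleted map
    # then fails exactly the jobs it was deleted from
    rep <- run_screen(screen_config(joblist, worker_count = 2, base_seed = trial,
                                    map_policy = "reload", profiling = FALSE))
    expect_length(rep$submitted, n)
    expect_equal(length(rep$successful) + nrow(rep$failed), n)
    expect_length(intersect(rep$successful, rep$failed$job), 0)
    expect_setequal(c(rep$successful, rep$failed$job), rep$submitted)
    expect_setequal(rep$failed$job, broken)
  }
})

test_that("screen results are identical across worker and thread counts", {
  d <- withr::local_tempdir()
  joblist <- make_screen(4, d, params = fast_params())
  digest <- function(rep) {
    lapply(rep$results, function(r) list(write_dlg(r),
                                         lapply(r$runs, `[[`, "best_state")))
  }
  base <- run_screen(screen_config(joblist, worker_count = 1,
                                   threads_per_docking = 1,
                                   base_seed = 7, profiling = FALSE))
  for (cfg in list(c(2, 2), c(4, 1), c(1, 4))) {
    rep <- run_screen(screen_config(joblist, worker_count = cfg[1],
                                    threads_per_docking = cfg[2],
                                    transport = "fork",
                                    base_seed = 7, profiling = FALSE))
    expect_identical(digest(rep), digest(base))
  }
})

test_that("the profiling log is one CSV line per docking with consistent fields", {
  d <- withr::local_tempdir()
  joblist <- make_screen(2, d, params = fast_params())
  out <- file.path(d, "out")
  rep <- run_screen(screen_config(joblist, base_seed = 3, output_root = out))
  expect_equal(nrow(rep$profile), 2)
  lines <- readLines(file.path(out, "profile.csv"))
  expect_length(lines, 3)  # header + 2 dockings
  header <- strsplit(lines[1], ",")[[1]]
  for (ln in lines[-1]) {
    expect_length(strsplit(ln, ",")[[1]], length(header))
  }
  # durations are non-negative and bounded by the job's total
  expect_true(all(rep$profile$fld_s >= 0))
  expect_true(all(rep$profile$completion_time >= rep$profile$dispatch_time))
  expect_true(all(rep$profile$total_s + 1e-9 >=
                    rep$profile$fld_s + rep$profile$map_s + rep$profile$lig_s))
  s <- profile_summary(rep$profile)
  expect_equal(rownames(s), c("ave", "rms", "med", "max"))
})

test_that("a 20-job screen on 2 workers completes in bounded time", {
  d <- withr::local_tempdir()
  joblist <- make_screen(20, d, params = fast_params(ga_num_evals = 100))
  t0 <- Sys.time()
  rep <- run_screen(screen_config(joblist, worker_count = 2, base_seed = 9,
                                  profiling = FALSE))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_length(rep$successful, 20)
  expect_lt(elapsed, 120)
})
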