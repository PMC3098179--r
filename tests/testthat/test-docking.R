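# Docking-level behavior: run collection, concurrency invariance,
# clustering and the serial-vs-parallel comparison rule.

test_that("a single-run docking wraps exactly one LGA run", {
  tc <- toy_fixture()
  p <- fast_params(ga_runs = 1)
  res <- dock(tc$ligand, p, toy_cache(), job_id = "one")
  expect_equal(length(res$runs), 1)
  expect_equal(res$status, "success")
  direct <- run_lga(tc$ligand, p, toy_cache(),
                    seed = make_seed(p$seed, 1), run_index = 1)
  expect_identical(res$runs[[1]]$best_state, direct$best_state)
  expect_identical(res$runs[[1]]$log_buffer, direct$log_buffer)
})

test_that("docking output is bit-identical across concurrency levels", {
  tc <- toy_fixture()
  p <- fast_params(ga_runs = 6, ga_num_evals = 400)
  r1 <- dock(tc$ligand, p, toy_cache(), concurrency = 1, job_id = "conc")
  r4 <- dock(tc$ligand, p, toy_cache(), concurrency = 4, job_id = "conc")
  expect_identical(write_dlg(r1), write_dlg(r4))
  expect_identical(lapply(r1$runs, `[[`, "best_energy"),
                   lapply(r4$runs, `[[`, "best_energy"))
  expect_identical(r1$clusters, r4$clusters)
  expect_equal(compare_results(r1, r4), 0)
})

test_that("default-style dockings carry ga_runs distinct seeds", {
  tc <- toy_fixture()
  p <- fast_params(ga_runs = 20, ga_num_evals = 100, ga_popsize = 8)
  res <- dock(tc$ligand, p, toy_cache(), job_id = "twenty")
  expect_equal(length(res$runs), 20)
  seeds <- vapply(res$runs, `[[`, 0, "seed")
  expect_equal(length(unique(seeds)), 20)
  expect_equal(seeds, p$seed + 1:20)
})

# hand-built run stubs for clustering geometry tests
stub_run <- function(idx, energy, pos) {
  structure(list(run_index = idx, seed = idx, best_energy = energy,
                 best_coords = matrix(pos, 1, 3),
                 log_buffer = sprintf("stub %d", idx)),
            class = "lga_run")
}

test_that("greedy leader clustering follows the hand-traced assignment", {
  # single-atom poses on a line at 0, 1, 3, 10 A; energies ascend with
  # position; tol 2 -> {0,1}, {3}, {10}
  runs <- list(stub_run(1, -5, c(0, 0, 0)), stub_run(2, -4, c(1, 0, 0)),
               stub_run(3, -3, c(3, 0, 0)), stub_run(4, -2, c(10, 0, 0)))
  cl <- cluster_runs(runs, tol = 2)
  expect_equal(cl, list(c(1L, 2L), 3L, 4L))

  # coincident poses collapse into one cluster
  same <- lapply(1:5, function(k) stub_run(k, -k, c(1, 1, 1)))
  expect_equal(cluster_runs(same, 2), list(c(5L, 4L, 3L, 2L, 1L)))

  # scattered poses give singletons
  apart <- lapply(1:4, function(k) stub_run(k, k, c(10 * k, 0, 0)))
  expect_equal(cluster_runs(apart, 2), list(1L, 2L, 3L, 4L))

  expect_equal(cluster_runs(list(), 2), list())
  expect_error(cluster_runs(runs, 0), "> 0")
})

test_that("clustering is a partition and tightening tol never merges", {
  tc <- toy_fixture()
  res <- dock(tc$ligand, fast_params(ga_runs = 8, ga_num_evals = 300),
              toy_cache(), job_id = "part")
  prev <- 0
  for (tol in c(8, 4, 2, 1, 0.5, 0.1)) {
    cl <- cluster_runs(res$runs, tol)
    expect_setequal(unlist(cl), 1:8)
    expect_equal(sum(lengths(cl)), 8)
    expect_gte(length(cl), prev)
    prev <- length(cl)
  }
})

test_that("result comparison uses the lesser-RMSD rule when selections split", {
  # construct results where the lowest-energy run is a singleton cluster:
  # the overall-lowest comparison gives 1.0, the largest-cluster one 3.0
  mk <- function(shift) {
    runs <- list(
      stub_run(1, -10, c(0, 0, 0) + shift),        # lowest energy, isolated
      stub_run(2, -5, c(20, 0, 0)),                # largest cluster ...
      stub_run(3, -4, c(20.5, 0, 0)),
      stub_run(4, -3, c(20.2, 0, 0)))
    structure(list(job_id = "cmp", runs = runs,
                   clusters = cluster_runs(runs, tol = 2),
                   status = "success", failure_reason = "",
                   cluster_tolerance = 2, base_seed = 0),
              class = "docking_result")
  }
  a <- mk(c(0, 0, 0))
  b <- mk(c(1, 0, 0))         # lowest poses 1.0 A apart
  b$runs[[2]]$best_coords <- matrix(c(23, 0, 0), 1)  # cluster leads 3.0 apart
  # sanity: the two selections disagree
  expect_equal(a$clusters, list(1L, c(2L, 3L, 4L)))
  expect_equal(compare_results(a, b), 1.0)
  # self-comparison is exactly zero
  expect_equal(compare_results(a, a), 0)
  # coincident selections: lowest pose inside the largest cluster
  runs_c <- list(stub_run(1, -10, c(0, 0, 0)), stub_run(2, -9, c(0.5, 0, 0)),
                 stub_run(3, -1, c(30, 0, 0)))
  cc <- structure(list(job_id = "cmp", runs = runs_c,
                       clusters = cluster_runs(runs_c, 2),
                       status = "success", failure_reason = "",
                       cluster_tolerance = 2, base_seed = 0),
                  class = "docking_result")
  expect_equal(compare_results(cc, cc), 0)
})
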