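# Shared fixtures, generated in code. The standard toy complex (broad
# single-well bowl, 2-atom rigid ligand) is built once per test run and
# reused; independent oracles live here so every test file can reach them.

.fixture_env <- new.env(parent = emptyenv())

# standard toy complex with maps on disk and a populated source table
toy_fixture <- function() {
  if (!is.null(.fixture_env$tc)) return(.fixture_env$tc)
  dir <- file.path(tempdir(), "dockscreen-fixture")
  spec <- toy_complex_spec()
  paths <- make_toy_maps(spec, dir = dir)
  lig <- read_pdbqt(text = make_toy_ligand(spec))
  .fixture_env$tc <- list(
    dir = dir, spec = spec, paths = paths,
    sources = read_fld(file.path(dir, "maps.fld")),
    ligand = lig)
  .fixture_env$tc
}

# a cache with the standard complex resident
toy_cache <- function(policy = "reuse") {
  tc <- toy_fixture()
  cache <- map_cache(policy)
  cache_begin_docking(cache, unique(tc$ligand$atoms$type), tc$sources)
  cache
}

# hand-written PDBQT: 6 atoms, 2 nested branches (atoms 5 moved by bond 4-5,
# atom 6 moved by both; nesting traced in test-formats)
nested_pdbqt <- function() {
  c("ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.100 C",
    "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  0.00  0.00    -0.100 C",
    "ATOM      3  C3  LIG A   1       2.200   1.300   0.000  0.00  0.00    +0.050 N",
    "ATOM      4  C4  LIG A   1       3.700   1.300   0.000  0.00  0.00    -0.050 C",
    "ENDROOT",
    "BRANCH 4 5",
    "ATOM      5  C5  LIG A   1       4.400   2.600   0.000  0.00  0.00    +0.200 O",
    "BRANCH 5 6",
    "ATOM      6  C6  LIG A   1       5.900   2.600   0.000  0.00  0.00    -0.200 C",
    "ENDBRANCH 5 6",
    "ENDBRANCH 4 5",
    "TORSDOF 2")
}

# --- independent oracles -------------------------------------------------

# 8-corner weighted-sum trilinear oracle, coded independently of the engine
oracle_trilinear <- function(map, p) {
  h <- map$header
  u <- (p - map$origin) / h$spacing
  i <- pmin(pmax(floor(u), 0), h$npts - 1)
  f <- u - i
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
      (if (dy) f[2] else 1 - f[2]) *
      (if (dz) f[3] else 1 - f[3])
    val <- val + w * map$values[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
  }
  val
}

# per-atom loop oracle for the grid-based intermolecular energy
oracle_inter_energy <- function(coords, charges, types, maps) {
  total <- 0
  for (a in seq_len(nrow(coords))) {
    p <- coords[a, ]
    total <- total + oracle_trilinear(maps[[types[a]]], p) +
      charges[a] * oracle_trilinear(maps[["e"]], p) +
      abs(charges[a]) * oracle_trilinear(maps[["d"]], p)
  }
  total
}

# random small grid map for round-trip and interpolation property tests
random_map <- function(npts = 4, seed = 1) {
  set.seed(seed)
  n <- npts + 1
  grid_map(spacing = runif(1, 0.2, 0.8), npts = npts,
           center = runif(3, -2, 2), atom_type = sample(c("C", "N", "e"), 1),
           values = array(rnorm(n^3), dim = c(n, n, n)))
}

# a screen directory with constructed atom-type sets {C}, {C,N}, {C,N,O}
varied_screen <- function(dir, n_jobs = 3,
                          params = docking_parameters(ga_runs = 2,
                                                      ga_popsize = 10,
                                                      ga_num_evals = 200,
                                                      seed = 11)) {
  make_screen(n_jobs, dir, mode = "varied",
              type_sets = list("C", c("C", "N"), c("C", "N", "O")),
              params = params)
}

# small fast parameter set for scheduler-level tests
fast_params <- function(...) {
  docking_parameters(ga_runs = 2, ga_popsize = 10, ga_num_evals = 200,
                     seed = 42, ...)
}
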