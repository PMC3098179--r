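# Readers and writers of the screen's text formats.

test_that("read_pdbqt handles root-only and single-branch ligands", {
  rootonly <- c(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.100 C",
    "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  0.00  0.00    -0.100 C",
    "ATOM      3  N1  LIG A   1       2.200   1.300   0.000  0.00  0.00    +0.050 N",
    "ENDROOT")
  lig <- read_pdbqt(text = rootonly)
  expect_s3_class(lig, "ligand")
  expect_equal(lig$n_torsions, 0)
  expect_equal(nrow(lig$atoms), 3)
  expect_equal(lig$atoms$charge, c(0.1, -0.1, 0.05))
  expect_equal(lig$atoms$type, c("C", "C", "N"))

  onebranch <- c(rootonly[1:4], "ENDROOT", "BRANCH 2 4",
                 "ATOM      4  O1  LIG A   1       3.000   2.000   0.000  0.00  0.00    +0.300 O",
                 "ENDBRANCH 2 4")
  lig1 <- read_pdbqt(text = onebranch)
  expect_equal(lig1$n_torsions, 1)
  expect_equal(lig1$edges[[1]]$moved, 4L)
  expect_equal(lig1$edges[[1]]$i, 2L)
  expect_equal(lig1$edges[[1]]$j, 4L)
})

test_that("read_pdbqt resolves nested branches to the hand-traced tree", {
  lig <- read_pdbqt(text = nested_pdbqt())
  expect_equal(lig$n_torsions, 2)
  expect_equal(lig$root, 1:4)
  # outer bond 4-5 moves its whole subtree {5, 6}; inner bond 5-6 moves {6}
  expect_equal(lig$edges[[1]]$i, 4L)
  expect_equal(lig$edges[[1]]$j, 5L)
  expect_equal(lig$edges[[1]]$moved, c(5L, 6L))
  expect_equal(lig$edges[[2]]$i, 5L)
  expect_equal(lig$edges[[2]]$j, 6L)
  expect_equal(lig$edges[[2]]$moved, 6L)
  # partition invariant: every atom in exactly one rigid group
  expect_setequal(unlist(lig$groups), 1:6)
  expect_equal(sum(lengths(lig$groups)), 6)
})

test_that("read_pdbqt rejects malformed input with located errors", {
  bad_nest <- c("ROOT",
                "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.100 C",
                "ENDROOT",
                "BRANCH 1 2",
                "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  0.00  0.00    -0.100 C")
  expect_error(read_pdbqt(text = bad_nest), "unbalanced|never closed")
  bad_charge <- c("ROOT",
                  "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    oops C",
                  "ENDROOT")
  expect_error(read_pdbqt(text = bad_charge), "non-numeric partial charge")
})

test_that("torsion count equals BRANCH count and write/read round-trips", {
  for (ntor in 0:4) {
    spec <- toy_complex_spec(ligand_atoms = ntor + 3L, ligand_torsions = ntor,
                             ligand_types = c("C", "N"))
    txt <- make_toy_ligand(spec)
    expect_equal(sum(grepl("^BRANCH", txt)), ntor)
    lig <- read_pdbqt(text = txt)
    expect_equal(lig$n_torsions, ntor)
    # round trip: write -> read reproduces the parsed structure
    lig2 <- read_pdbqt(text = write_pdbqt(lig))
    expect_equal(lig2$atoms, lig$atoms, tolerance = 1e-3)
    expect_equal(lig2$edges, lig$edges)
    expect_equal(lig2$root, lig$root)
  }
  # the hand-written nested fixture round-trips too
  lig <- read_pdbqt(text = nested_pdbqt())
  lig2 <- read_pdbqt(text = write_pdbqt(lig))
  expect_equal(lig2$edges, lig$edges)
})

test_that("parse_parameters applies defaults, overrides and last-wins", {
  p <- parse_parameters(text = "ga_popsize 150")
  expect_equal(p$ga_popsize, 150L)
  # empty stream: all defaults
  p0 <- parse_parameters(text = character(0))
  expect_equal(p0$ga_runs, 20L)
  expect_equal(p0$ga_popsize, 150L)
  expect_equal(p0$ga_num_evals, 250000L)
  expect_equal(p0$ga_num_generations, 27000L)
  # last occurrence wins
  p2 <- parse_parameters(text = c("ga_runs 1", "ga_runs 5"))
  expect_equal(p2$ga_runs, 5L)
  # unknown keys preserved with a warning, ignored otherwise
  expect_warning(p3 <- parse_parameters(text = "torsdof 3"), "unknown")
  expect_equal(attr(p3, "extra")$torsdof, "3")
  expect_equal(p3$ga_runs, 20L)
})

test_that("parse_parameters rejects bad values", {
  expect_error(parse_parameters(text = "ga_runs 2.5"), "integer")
  expect_error(parse_parameters(text = "ga_runs abc"), "integer")
  expect_error(parse_parameters(text = "ga_popsize -3"), "non-negative")
})

test_that("parameter serialization is idempotent", {
  p <- docking_parameters(ga_runs = 7, ls_frequency = 0.1, seed = 99,
                          map_policy = "reload")
  p2 <- parse_parameters(text = write_parameters(p))
  keys <- c("ga_runs", "ga_popsize", "ga_num_evals", "ga_num_generations",
            "ls_frequency", "cluster_tolerance", "map_policy", "seed")
  expect_equal(unclass(p2)[keys], unclass(p)[keys], ignore_attr = TRUE)
  # and a second cycle changes nothing
  expect_identical(write_parameters(p2), write_parameters(p))
})

test_that("read_map decodes x-fastest order and validates the header", {
  # 2x2x2-interval map with values 0..26 in file order
  txt <- c("SPACING 0.5", "NELEMENTS 2 2 2", "CENTER 0 0 0", "TYPE C",
           as.character(0:26))
  m <- read_map(text = txt)
  expect_equal(m$values[2, 1, 1], 1)   # lattice index (1,0,0)
  expect_equal(m$values[1, 1, 2], 9)   # lattice index (0,0,1)
  expect_equal(m$values[1, 2, 1], 3)   # lattice index (0,1,0)
  expect_equal(m$origin, c(-0.5, -0.5, -0.5))

  expect_error(read_map(text = c("SPACING 0.5", "NELEMENTS 3 3 3",
                                 "CENTER 0 0 0", "TYPE C")), "even")
  expect_error(read_map(text = txt[-27]), "expected 27 values, found 26")
})

test_that("map write/read round trip is the identity on numeric content", {
  for (s in 1:5) {
    m <- random_map(npts = sample(c(2, 4), 1), seed = s)
    txt <- write_map(m)
    m2 <- read_map(text = txt)
    expect_identical(m2$values, m$values)
    expect_identical(m2$header, m$header)
    # second write byte-identical to the first
    expect_identical(write_map(m2), txt)
  }
})

test_that("production-scale map header implies 226981 values", {
  # 60 intervals at 0.375 A per point
  n <- 61L
  m <- grid_map(spacing = 0.375, npts = 60, center = c(0, 0, 0),
                atom_type = "C", values = array(0, dim = c(n, n, n)))
  txt <- write_map(m)
  expect_equal(length(txt) - 4L, 226981L)  # 4 header lines
  m2 <- read_map(text = txt)
  expect_equal(dim(m2$values), c(61L, 61L, 61L))
})

test_that("fld index round-trips through the filesystem", {
  d <- withr::local_tempdir()
  write_fld(c(C = "receptor.C.map", e = "receptor.e.map", d = "receptor.d.map"),
            file.path(d, "maps.fld"))
  src <- read_fld(file.path(d, "maps.fld"))
  expect_named(src, c("C", "e", "d"))
  expect_equal(basename(src[["C"]]), "receptor.C.map")
  expect_equal(dirname(src[["e"]]), d)
})

test_that("docking log keeps each run's lines contiguous and in order", {
  tc <- toy_fixture()
  cache <- toy_cache()
  p <- fast_params(ga_runs = 4)
  res <- dock(tc$ligand, p, cache, job_id = "contig")
  dlg <- write_dlg(res)
  starts <- grep("^Run [0-9]+$", dlg)
  ends <- grep("^End Run [0-9]+$", dlg)
  expect_equal(dlg[starts], paste("Run", 1:4))
  expect_equal(dlg[ends], paste("End Run", 1:4))
  # each section's body is exactly that run's buffer (contiguity)
  for (k in 1:4) {
    body <- dlg[(starts[k] + 2):(ends[k] - 2)]
    expect_identical(body, res$runs[[k]]$log_buffer)
  }
  # sections do not interleave
  expect_true(all(ends > starts))
  expect_true(all(starts[-1] > ends[-4]))
})

test_that("a 1-run docking logs a single singleton cluster", {
  tc <- toy_fixture()
  res <- dock(tc$ligand, fast_params(ga_runs = 1), toy_cache(), job_id = "solo")
  dlg <- write_dlg(res)
  expect_equal(sum(grepl("^cluster ", dlg)), 1)
  expect_match(dlg[grepl("^cluster 1:", dlg)], "size 1")
  # a result missing a run buffer is rejected
  broken <- res
  broken$runs[[1]]$log_buffer <- NULL
  expect_error(write_dlg(broken), "incomplete")
})
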