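# Pose scoring: grid intermolecular term, internal term, breakdown.

test_that("intermolecular energy collapses to map values on lattice points", {
  n <- 3
  mk <- function(val, type) grid_map(1, 2, c(0, 0, 0), type,
                                     array(val, dim = c(n, n, n)))
  d <- file.path(tempdir(), "flat-maps")
  dir.create(d, showWarnings = FALSE)
  write_map(mk(-1.25, "C"), file.path(d, "receptor.C.map"))
  write_map(mk(0.5, "e"), file.path(d, "receptor.e.map"))
  write_map(mk(0.75, "d"), file.path(d, "receptor.d.map"))
  write_fld(c(C = "receptor.C.map", e = "receptor.e.map", d = "receptor.d.map"),
            file.path(d, "maps.fld"))
  src <- read_fld(file.path(d, "maps.fld"))
  cache <- map_cache("reuse")
  cache_begin_docking(cache, "C", src)

  lig0 <- function(q) {
    read_pdbqt(text = c(
      "ROOT",
      sprintf("ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    %+7.4f C", q),
      "ENDROOT"))
  }
  # zero charge: affinity only
  expect_equal(intermolecular_energy(matrix(0, 1, 3), lig0(0), cache), -1.25)
  # unit charge: affinity + electrostatic + desolvation
  expect_equal(intermolecular_energy(matrix(0, 1, 3), lig0(1), cache),
               -1.25 + 0.5 + 0.75)
  # negative charge: affinity + q*e + |q|*d
  expect_equal(intermolecular_energy(matrix(0, 1, 3), lig0(-1), cache),
               -1.25 - 0.5 + 0.75)
})

test_that("intermolecular energy matches the per-atom loop oracle", {
  tc <- toy_fixture()
  cache <- toy_cache()
  maps <- list(C = cache_get(cache, "C", NULL),
               e = cache_get(cache, "e", NULL),
               d = cache_get(cache, "d", NULL))
  lig <- tc$ligand
  set.seed(11)
  for (k in 1:10) {
    coords <- matrix(runif(nrow(lig$atoms) * 3, -3, 3), ncol = 3)
    expect_equal(
      intermolecular_energy(coords, lig, cache),
      oracle_inter_energy(coords, lig$atoms$charge, lig$atoms$type, maps),
      tolerance = 1e-12)
  }
})

test_that("a rigid ligand has zero internal energy", {
  tc <- toy_fixture()
  lig <- tc$ligand  # 2 atoms, 0 torsions
  expect_length(eligible_pairs(lig)$i, 0)
  expect_equal(internal_energy(as.matrix(lig$atoms[, c("x", "y", "z")]), lig), 0)
})

test_that("the Lennard-Jones term hits -eps at the potential minimum", {
  # two eligible atoms with zero charge at r = sigma * 2^(1/6)
  pairs <- list(i = 1L, j = 2L, eps = 0.1, sigma = 3.4, qq = 0)
  r_min <- 3.4 * 2^(1 / 6)
  coords <- rbind(c(0, 0, 0), c(r_min, 0, 0))
  e <- sum(dockscreen:::cpp_internal_pairs_energy(coords, pairs))
  expect_equal(e, -0.1, tolerance = 1e-12)
})

test_that("the internal term matches hand arithmetic on a 3-pair case", {
  pairs <- list(i = c(1L, 1L, 2L), j = c(3L, 4L, 4L),
                eps = c(0.1, 0.2, 0.1), sigma = c(3.4, 3.0, 3.4),
                qq = c(0.01, -0.02, 0.0))
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(4, 0, 0), c(0, 3.5, 0))
  hand <- 0
  lj <- function(eps, sig, r) 4 * eps * ((sig / r)^12 - (sig / r)^6)
  coul <- function(qq, r) 332.0636 * qq / (4 * r^2)
  r13 <- 4; r14 <- 3.5; r24 <- sqrt(1.5^2 + 3.5^2)
  hand <- lj(0.1, 3.4, r13) + coul(0.01, r13) +
    lj(0.2, 3.0, r14) + coul(-0.02, r14) +
    lj(0.1, 3.4, r24) + coul(0, r24)
  expect_equal(sum(dockscreen:::cpp_internal_pairs_energy(coords, pairs)), hand,
               tolerance = 1e-9)
})

test_that("eligible pairs require >= 3 bonds separation and distinct groups", {
  # 6-atom chain, torsions on the last two bonds; bond graph is the chain
  spec <- toy_complex_spec(ligand_atoms = 6, ligand_torsions = 2)
  lig <- read_pdbqt(text = make_toy_ligand(spec))
  pr <- eligible_pairs(lig)
  found <- paste(pr$i, pr$j)
  # atoms 1..4 are the root group: pairs inside it are ineligible however
  # far apart; atom 5 (group 2) pairs with 1, 2 (3+ bonds away), atom 6
  # (group 3) with 1, 2, 3
  expect_setequal(found, c("1 5", "2 5", "1 6", "2 6", "3 6"))
})

test_that("score_pose is pure, additive and counts evaluations", {
  tc <- toy_fixture()
  cache <- toy_cache()
  st <- genome_state(c(0.3, -0.2, 0.1), c(0.9, 0.1, 0.2, -0.3))
  b1 <- score_pose(st, tc$ligand, cache)
  b2 <- score_pose(st, tc$ligand, cache)
  expect_identical(b1, b2)
  expect_equal(b1$total, b1$intermolecular + b1$internal)
  expect_equal(b1$eval_count_delta, 1L)
  # counting contract
  ctr <- new_eval_counter()
  for (k in 1:5) score_pose(st, tc$ligand, cache, counter = ctr)
  expect_equal(ctr$n, 5L)
  # breakdown agrees with the separately computed terms
  coords <- apply_state(tc$ligand, st)
  expect_equal(b1$intermolecular,
               intermolecular_energy(coords, tc$ligand, cache),
               tolerance = 1e-12)
  expect_equal(b1$internal, internal_energy(coords, tc$ligand),
               tolerance = 1e-12)
})

test_that("score is minimized at the constructed well on a lattice scan", {
  # single-probe energy over all lattice points: argmin at the well center
  tc <- toy_fixture()
  cache <- toy_cache()
  cmap <- cache_get(cache, "C", NULL)
  h <- cmap$header
  idx <- which(cmap$values == min(cmap$values), arr.ind = TRUE)
  expect_equal(nrow(idx), 1)
  well_idx <- (tc$spec$well_center - cmap$origin) / h$spacing + 1
  expect_equal(as.vector(idx), well_idx)
})
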