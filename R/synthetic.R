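# Synthetic fixture generator: complete toy screens with point-atom
# receptors, analytically computed grid maps carrying a constructed global
# energy minimum, and PDBQT ligands with 0-6 torsions. Everything is
# deterministic given a seed and needs no external input.

.with_seed <- function(seed, expr) {
  # localize R's RNG so fixture generation never perturbs a caller's stream
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a toy receptor-ligand complex
#'
#' Defines the synthetic study system: a point-atom receptor arranged as an
#' octahedral cage of six atoms around `well_center` at the Lennard-Jones
#' minimum distance of a broad map probe (`map_sigma`, wider than the grid
#' box), so the whole box forms one smooth bowl whose minimum -- for a
#' single probe and for the small toy ligands alike -- sits at the well
#' center; by construction every affinity map attains its minimum lattice
#' value at `well_center`. The object also fixes a cubic grid and a ligand
#' recipe (atom count, torsion count, alternating charge pattern). Receptor
#' charges alternate +/- 0.1 e so the electrostatic map is non-trivial but
#' vanishes at the well center by symmetry. The toy grid defaults to 20
#' intervals of 0.4 Angstrom (small enough for fast screens; wider
#' production-style geometries are exercised by the format layer).
#'
#' @param well_center constructed pose optimum, strictly inside the box and
#'   (by default) on a lattice point.
#' @param grid_npts even interval count per axis.
#' @param grid_spacing Angstrom per interval.
#' @param grid_center box center.
#' @param ligand_atoms atoms in the generated ligand (>= 2).
#' @param ligand_torsions rotatable bonds (0-6, and at most
#'   `ligand_atoms - 2`).
#' @param ligand_types atom-type labels to draw ligand atoms from.
#' @param map_sigma Lennard-Jones sigma of the map probe (Angstrom); the
#'   cage radius is `2^(1/6) * map_sigma`.
#' @param seed generation seed; everything downstream is deterministic in it.
#' @return an object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(well_center = c(0, 0, 0), grid_npts = 20L,
                             grid_spacing = 0.4, grid_center = c(0, 0, 0),
                             ligand_atoms = 2L, ligand_torsions = 0L,
                             ligand_types = "C", map_sigma = 5.0,
                             seed = 1L) {
  grid_npts <- as.integer(grid_npts)
  half <- grid_npts * grid_spacing / 2
  if (any(abs(well_center - grid_center) >= half)) {
    stop("well_center must lie strictly inside the grid box")
  }
  if (ligand_atoms < 2) stop("ligand needs at least 2 atoms")
  if (ligand_torsions < 0 || ligand_torsions > 6 ||
      ligand_torsions > ligand_atoms - 2) {
    stop("infeasible torsion count (need 0 <= torsions <= min(6, atoms - 2))")
  }
  r_min <- map_sigma * 2^(1 / 6)
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  receptor <- data.frame(
    x = well_center[1] + r_min * axes[, 1],
    y = well_center[2] + r_min * axes[, 2],
    z = well_center[3] + r_min * axes[, 3],
    charge = rep(c(0.1, -0.1), 3),
    type = "R")
  structure(list(
    receptor_atoms = receptor,
    well_center = as.numeric(well_center),
    grid = list(spacing = grid_spacing, npts = grid_npts,
                center = as.numeric(grid_center)),
    ligand_spec = list(atoms = as.integer(ligand_atoms),
                       torsions = as.integer(ligand_torsions),
                       types = ligand_types),
    map_sigma = map_sigma,
    seed = as.integer(seed)
  ), class = "toy_complex_spec")
}

# lattice point coordinates along one axis
.lattice_axis <- function(grid) {
  grid$center - grid$npts * grid$spacing / 2 + (0:grid$npts) * grid$spacing
}

# per-type LJ well depth: slight spread so different types' maps differ
.type_eps <- function(type) {
  idx <- (utils::head(utf8ToInt(type), 1) %% 7) + 1
  .LJ_EPS_DEFAULT * (1 + 0.05 * idx)
}

#' Generate toy grid maps
#'
#' Computes one affinity map per requested atom type, the electrostatic map
#' and the desolvation map on the spec's lattice, analytically from the
#' point-atom receptor: affinity as the sum over receptor atoms of 12-6
#' Lennard-Jones (clamped at +1e3 kcal/mol near the atoms), electrostatics
#' as the summed receptor-charge potential with distance-dependent
#' dielectric (`332.0636 q / (4 r^2)`), and desolvation as a smooth
#' Gaussian occupancy of the receptor volume. By construction the affinity
#' minimum over lattice points sits at the spec's `well_center`.
#'
#' @param spec a [toy_complex_spec()].
#' @param types atom-type labels to build affinity maps for.
#' @param dir output directory; created if needed. Files are
#'   `receptor.<type>.map`, `receptor.e.map`, `receptor.d.map` plus the
#'   grid index `maps.fld`.
#' @return named character vector of map paths (including `e` and `d`),
#'   invisibly; the `maps.fld` index is written alongside.
#' @export
make_toy_maps <- function(spec, types = spec$ligand_spec$types, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ax <- .lattice_axis(spec$grid)
  n <- length(ax)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))  # x-fastest
  rec <- spec$receptor_atoms
  d2 <- sapply(seq_len(nrow(rec)), function(k) {
    (pts[, 1] - rec$x[k])^2 + (pts[, 2] - rec$y[k])^2 + (pts[, 3] - rec$z[k])^2
  })
  d <- sqrt(pmax(d2, 1e-12))
  paths <- character(0)
  for (t in unique(types)) {
    eps <- .type_eps(t)
    sr6 <- (spec$map_sigma / d)^6
    vals <- rowSums(4 * eps * (sr6^2 - sr6))
    vals <- pmin(vals, 1e3)
    m <- grid_map(spec$grid$spacing, spec$grid$npts, spec$grid$center, t,
                  array(vals, dim = c(n, n, n)))
    f <- file.path(dir, paste0("receptor.", t, ".map"))
    write_map(m, f)
    paths[t] <- f
  }
  evals <- rowSums(sweep(332.0636 / (4 * d^2), 2, rec$charge, `*`))
  evals <- pmin(pmax(evals, -1e3), 1e3)
  em <- grid_map(spec$grid$spacing, spec$grid$npts, spec$grid$center, "e",
                 array(evals, dim = c(n, n, n)))
  f <- file.path(dir, "receptor.e.map")
  write_map(em, f)
  paths["e"] <- f
  dvals <- rowSums(0.05 * exp(-d2 / (2 * 2.5^2)))
  dm <- grid_map(spec$grid$spacing, spec$grid$npts, spec$grid$center, "d",
                 array(dvals, dim = c(n, n, n)))
  f <- file.path(dir, "receptor.d.map")
  write_map(dm, f)
  paths["d"] <- f
  write_fld(stats::setNames(basename(paths), names(paths)),
            file.path(dir, "maps.fld"))
  invisible(paths)
}

#' Generate a toy PDBQT ligand
#'
#' Builds a zigzag chain of `atoms` atoms with 1.5 Angstrom bonds, types
#' cycled from the spec's type set, small alternating partial charges
#' (+/- 0.05 e), and the requested number of rotatable bonds encoded as
#' nested BRANCH blocks at the chain's tail. The text parses under
#' [read_pdbqt()] to a matching torsion count and round-trips stably.
#'
#' @param spec a [toy_complex_spec()] (its `ligand_spec` is used).
#' @param file optional output path.
#' @return the PDBQT lines, invisibly.
#' @export
make_toy_ligand <- function(spec, file = NULL) {
  ls <- spec$ligand_spec
  n <- ls$atoms
  ntor <- ls$torsions
  if (n < 1) stop("ligand needs at least 1 atom")
  if (ntor > n - 2) stop("infeasible torsion count for ", n, " atoms")
  # zigzag chain in the xy plane, 1.5 A bonds
  ang <- (seq_len(n) - 1) * 0.6
  xyz <- cbind(cumsum(c(0, rep(1.5, n - 1)) * cos(c(0, ang[-1]))),
               cumsum(c(0, rep(1.5, n - 1)) * sin(c(0, ang[-1]))),
               rep(0, n))
  xyz <- sweep(xyz, 2, colMeans(xyz))
  types <- rep(ls$types, length.out = n)
  charges <- rep(c(0.05, -0.05), length.out = n)
  atom_line <- function(i) {
    sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  0.00  0.00    %+7.4f %-2s",
            i, paste0(types[i], i), xyz[i, 1], xyz[i, 2], xyz[i, 3],
            charges[i], types[i])
  }
  n_root <- n - ntor
  out <- c("ROOT", vapply(seq_len(n_root), atom_line, ""), "ENDROOT")
  if (ntor > 0) {
    for (k in seq_len(ntor)) {
      a <- n_root + k
      out <- c(out, sprintf("BRANCH %d %d", a - 1, a), atom_line(a))
    }
    for (k in rev(seq_len(ntor))) {
      a <- n_root + k
      out <- c(out, sprintf("ENDBRANCH %d %d", a - 1, a))
    }
  }
  out <- c(out, sprintf("TORSDOF %d", ntor))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Generate a complete toy screen
#'
#' Builds `n_jobs` job directories (parameter file, ligand, maps, grid
#' index) plus the job-list file. `mode = "replicated"` docks the same
#' ligand in every job, the replicated-library design used for throughput
#' studies; `mode = "varied"` varies torsion counts (cycling 0..6 as atom
#' counts allow) and grows the atom-type set from job to job, which
#' exercises lazy map loading under the reuse policy. Each job's parameter
#' file carries a distinct numeric seed derived from `seed`, so screens are
#' reproducible end to end.
#'
#' @param n_jobs number of jobs (>= 0).
#' @param dir output root; jobs are written to `dir/job_001`, ...
#' @param spec template [toy_complex_spec()].
#' @param mode `"replicated"` or `"varied"`.
#' @param params a [docking_parameters()] template written to every job
#'   (its `seed` is replaced per job).
#' @param type_sets for `varied` mode, optional list of atom-type vectors,
#'   one per job (recycled), overriding the default growth pattern.
#' @param seed screen-level seed.
#' @return path of the job-list file (`dir/joblist.txt`); the report of a
#'   later [run_screen()] refers to the job directories written here.
#' @export
make_screen <- function(n_jobs, dir, spec = toy_complex_spec(),
                        mode = c("replicated", "varied"),
                        params = docking_parameters(),
                        type_sets = NULL, seed = spec$seed) {
  mode <- match.arg(mode)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  joblist <- file.path(dir, "joblist.txt")
  if (n_jobs == 0) {
    writeLines(character(0), joblist)
    return(joblist)
  }
  all_types <- c("C", "N", "O", "S", "P", "F")
  jobs <- character(n_jobs)
  for (j in seq_len(n_jobs)) {
    jd <- file.path(dir, sprintf("job_%03d", j))
    dir.create(jd, showWarnings = FALSE)
    if (mode == "replicated") {
      jspec <- spec
    } else {
      if (!is.null(type_sets)) {
        tt <- type_sets[[((j - 1) %% length(type_sets)) + 1]]
      } else {
        tt <- all_types[seq_len(min(j, length(all_types)))]
      }
      natoms <- max(spec$ligand_spec$atoms, length(tt) + 2)
      ntor <- min(6L, (j - 1L) %% 7L, natoms - 2L)
      jspec <- toy_complex_spec(
        well_center = spec$well_center, grid_npts = spec$grid$npts,
        grid_spacing = spec$grid$spacing, grid_center = spec$grid$center,
        ligand_atoms = natoms, ligand_torsions = ntor, ligand_types = tt,
        seed = spec$seed)
    }
    make_toy_ligand(jspec, file.path(jd, "ligand.pdbqt"))
    make_toy_maps(jspec, types = unique(rep(jspec$ligand_spec$types,
                                            length.out = jspec$ligand_spec$atoms)),
                  dir = jd)
    p <- params
    p$seed <- seed * 10000 + j * 100
    write_parameters(p, file.path(jd, "job.dpf"))
    jobs[j] <- jd
  }
  writeLines(jobs, joblist)
  joblist
}
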