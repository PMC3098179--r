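# Pose scoring: grid-interpolated intermolecular energy (affinity +
# charge-weighted electrostatic + |charge|-weighted desolvation per atom)
# plus a simple intramolecular 12-6 Lennard-Jones / screened-Coulomb term
# over eligible nonbonded pairs.

.LJ_EPS_DEFAULT <- 0.1   # kcal/mol
.LJ_SIG_DEFAULT <- 3.4   # Angstrom

# Bonds are inferred from the input geometry with a distance cutoff (PDBQT
# carries only the rotatable bonds); 1.9 A covers ordinary covalent bonds
# without bridging nonbonded contacts in the toy chemistry used here.
.BOND_CUTOFF <- 1.9

.bond_graph <- function(ligand) {
  at <- ligand$atoms
  n <- nrow(at)
  adj <- vector("list", n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                    (at$z[i] - at$z[j])^2)
        if (d <= .BOND_CUTOFF) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  # rotatable bonds are bonds by definition
  for (e in ligand$edges) {
    if (!(e$j %in% adj[[e$i]])) {
      adj[[e$i]] <- c(adj[[e$i]], e$j)
      adj[[e$j]] <- c(adj[[e$j]], e$i)
    }
  }
  adj
}

.bond_distances <- function(adj) {
  n <- length(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (d[s, w] > d[s, v] + 1) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

.group_of <- function(ligand) {
  g <- integer(nrow(ligand$atoms))
  for (k in seq_along(ligand$groups)) g[ligand$groups[[k]]] <- k
  g
}

#' Eligible nonbonded pairs of a ligand
#'
#' Atom pairs separated by at least 3 bonds (bond graph inferred from the
#' input geometry plus the rotatable bonds) and belonging to different
#' rigid groups. A rigid ligand therefore has no eligible pairs. Per-pair
#' Lennard-Jones parameters default to epsilon = 0.1 kcal/mol, sigma = 3.4
#' Angstrom for every type pair unless `lj_table` supplies values.
#'
#' @param ligand a `ligand`.
#' @param lj_table optional data.frame with columns `type_a`, `type_b`,
#'   `eps`, `sigma` (unordered type pairs).
#' @return a list with integer vectors `i`, `j` and numeric vectors `eps`,
#'   `sigma`, `qq` (charge products).
#' @export
eligible_pairs <- function(ligand, lj_table = NULL) {
  n <- nrow(ligand$atoms)
  grp <- .group_of(ligand)
  empty <- list(i = integer(0), j = integer(0), eps = numeric(0),
                sigma = numeric(0), qq = numeric(0))
  if (n < 2 || ligand$n_torsions == 0) return(empty)
  bd <- .bond_distances(.bond_graph(ligand))
  lookup <- function(ta, tb) {
    if (!is.null(lj_table)) {
      hit <- which((lj_table$type_a == ta & lj_table$type_b == tb) |
                     (lj_table$type_a == tb & lj_table$type_b == ta))
      if (length(hit)) {
        return(c(lj_table$eps[hit[1]], lj_table$sigma[hit[1]]))
      }
    }
    c(.LJ_EPS_DEFAULT, .LJ_SIG_DEFAULT)
  }
  out <- empty
  at <- ligand$atoms
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (grp[i] != grp[j] && bd[i, j] >= 3) {
        es <- lookup(at$type[i], at$type[j])
        out$i <- c(out$i, i)
        out$j <- c(out$j, j)
        out$eps <- c(out$eps, es[1])
        out$sigma <- c(out$sigma, es[2])
        out$qq <- c(out$qq, at$charge[i] * at$charge[j])
      }
    }
  }
  out
}

# resolve the map set a ligand needs from a cache (maps must be resident or
# loadable via `sources`); returns blobs for the C++ kernels plus the
# 1-based type index per atom
.map_set <- function(ligand, cache, sources = NULL) {
  types <- unique(ligand$atoms$type)
  for (t in c(types, "e", "d")) {
    if (!exists(t, envir = cache$loaded, inherits = FALSE)) {
      cache_get(cache, t,
                if (!is.null(sources) && t %in% names(sources)) sources[[t]] else NULL)
    }
  }
  aff <- lapply(types, function(t)
    .map_blob(get(t, envir = cache$loaded, inherits = FALSE)))
  list(aff = aff,
       type_idx = match(ligand$atoms$type, types),
       emap = .map_blob(get("e", envir = cache$loaded, inherits = FALSE)),
       dmap = .map_blob(get("d", envir = cache$loaded, inherits = FALSE)))
}

#' Grid-based intermolecular energy
#'
#' Sum over atoms of `M_type(x) + q * M_e(x) + |q| * M_d(x)`, each map
#' evaluated by trilinear interpolation at the atom position. An atom
#' outside the grid box contributes the out-of-grid penalty once instead of
#' its map terms.
#'
#' @param coords n-by-3 matrix of atom positions (Angstrom).
#' @param ligand the `ligand` (for charges and atom types).
#' @param cache a `map_cache` with the needed maps resident (or loadable
#'   through `sources`).
#' @param sources optional named map-path vector for lazy loading.
#' @return energy in kcal/mol.
#' @export
intermolecular_energy <- function(coords, ligand, cache, sources = NULL) {
  ms <- .map_set(ligand, cache, sources)
  coords <- as.matrix(coords)
  total <- 0
  for (a in seq_len(nrow(coords))) {
    m <- ms$aff[[ms$type_idx[a]]]
    p <- coords[a, ]
    hi <- (m$n - 1) * m$spacing
    inside <- all(p >= m$origin) && all(p <= m$origin + hi)
    if (!inside) {
      total <- total + out_of_grid_penalty()
    } else {
      q <- ligand$atoms$charge[a]
      total <- total +
        cpp_interpolate(m, matrix(p, 1)) +
        q * cpp_interpolate(ms$emap, matrix(p, 1)) +
        abs(q) * cpp_interpolate(ms$dmap, matrix(p, 1))
    }
  }
  total
}

#' Intramolecular (internal) energy
#'
#' Sum over eligible nonbonded pairs (see [eligible_pairs()]) of 12-6
#' Lennard-Jones plus Coulomb with a distance-dependent dielectric
#' `eps_r = 4r` (332.0636 q_i q_j / (4 r^2) in kcal/mol with Angstrom and
#' elementary charges). Deterministic given coordinates; pair distances are
#' floored at 0.01 Angstrom.
#'
#' @inheritParams intermolecular_energy
#' @param pairs optionally, a precomputed [eligible_pairs()] list.
#' @return energy in kcal/mol.
#' @export
internal_energy <- function(coords, ligand, pairs = NULL) {
  if (is.null(pairs)) pairs <- eligible_pairs(ligand)
  if (length(pairs$i) == 0) return(0)
  sum(cpp_internal_pairs_energy(as.matrix(coords), pairs))
}

#' Score a pose
#'
#' Applies the genome state to the ligand and returns the energy breakdown
#' (`intermolecular`, `internal`, `total = intermolecular + internal`,
#' `eval_count_delta = 1`). Scoring is a pure function of the state, the
#' ligand and the map contents: cache policy, thread count and call order
#' never change any returned energy. Exactly one evaluation-budget unit is
#' consumed per call; pass `counter` (an environment with field `n`) to
#' accumulate it.
#'
#' @param state a `genome_state`.
#' @param ligand a `ligand`.
#' @param cache a `map_cache`.
#' @param sources optional named map-path vector for lazy loading.
#' @param pairs optional precomputed [eligible_pairs()].
#' @param counter optional evaluation counter from [new_eval_counter()].
#' @return a list of class `energy_breakdown`.
#' @export
score_pose <- function(state, ligand, cache, sources = NULL, pairs = NULL,
                       counter = NULL) {
  if (length(state$torsions) != ligand$n_torsions) {
    stop("state has ", length(state$torsions), " torsions but ligand has ",
         ligand$n_torsions)
  }
  if (is.null(pairs)) pairs <- eligible_pairs(ligand)
  ms <- .map_set(ligand, cache, sources)
  coords <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  br <- cpp_score(coords, ligand$atoms$charge, ms$type_idx, ligand$root,
                  ligand$edges, pairs, ms$aff, ms$emap, ms$dmap,
                  state$translation, state$quaternion, state$torsions)
  if (!is.null(counter)) counter$n <- counter$n + 1L
  structure(list(intermolecular = br$intermolecular, internal = br$internal,
                 total = br$total, eval_count_delta = 1L),
            class = "energy_breakdown")
}

#' Evaluation counter
#'
#' A mutable counter for energy evaluations, the budget unit of the genetic
#' search (one unit per full-pose score).
#' @return an environment with integer field `n = 0`.
#' @export
new_eval_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy: total %.4f = intermolecular %.4f + internal %.4f kcal/mol\n",
              x$total, x$intermolecular, x$internal))
  invisible(x)
}
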