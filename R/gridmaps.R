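# In-memory grid maps, trilinear interpolation, and the persistence-policy
# map cache that carries the screen's I/O optimization: under `reuse` a map
# loaded once stays resident for the worker's lifetime, under `reload` the
# residency is dropped after every docking.

#' Construct a grid map
#'
#' A grid map holds one probe type's precomputed interaction energies
#' (kcal/mol) on a regular cubic lattice of `npts + 1` points per axis with
#' the given spacing (Angstrom per interval), centered at `center`.
#'
#' @param spacing Angstrom per lattice interval (> 0).
#' @param npts even interval count per axis (points per axis = `npts + 1`).
#' @param center box center, length-3 numeric (Angstrom).
#' @param atom_type type label; `"e"` and `"d"` are reserved for the
#'   electrostatic and desolvation maps.
#' @param values a `(npts+1)^3` array (or vector in x-fastest order).
#' @return an object of class `grid_map`.
#' @export
grid_map <- function(spacing, npts, center, atom_type, values) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  npts <- as.integer(npts)
  if (npts < 2 || npts %% 2 != 0) stop("npts must be even and >= 2")
  n <- npts + 1L
  if (length(values) != n^3) {
    stop("need ", n^3, " values for npts = ", npts, ", got ", length(values))
  }
  if (!all(is.finite(values))) stop("map values must be finite")
  values <- array(as.numeric(values), dim = c(n, n, n))
  center <- as.numeric(center)
  origin <- center - npts * spacing / 2
  structure(list(
    header = list(spacing = spacing, npts = npts, center = center,
                  atom_type = atom_type),
    values = values,
    origin = origin
  ), class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  h <- x$header
  cat(sprintf("grid map '%s': %d^3 points, spacing %.4g A, center (%g, %g, %g)\n",
              h$atom_type, h$npts + 1L, h$spacing,
              h$center[1], h$center[2], h$center[3]))
  invisible(x)
}

# flat representation handed to the C++ kernels
.map_blob <- function(map) {
  list(values = as.vector(map$values), n = map$header$npts + 1L,
       spacing = map$header$spacing, origin = map$origin)
}

#' Trilinear interpolation on a grid map
#'
#' For points inside the box, the trilinear blend of the 8 surrounding
#' lattice values; at lattice points this equals the stored value exactly,
#' and affine fields are reproduced to machine precision. Points outside
#' the box score the declared out-of-grid penalty (+1e5 kcal/mol).
#'
#' @param map a `grid_map`.
#' @param point length-3 numeric, or an n-by-3 matrix of points (Angstrom).
#' @return interpolated energy (kcal/mol), one value per point.
#' @export
interpolate <- function(map, point) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 3, byrow = TRUE)
  if (ncol(point) != 3) stop("points must have 3 columns")
  if (!all(is.finite(point))) stop("non-finite point")
  cpp_interpolate(.map_blob(map), point)
}

#' Out-of-grid penalty constant
#'
#' The energy assigned to any point outside a map's box (and, in scoring,
#' once per atom outside the box): +1e5 kcal/mol. Keeps the genetic search
#' inside the grid without clamping at the boundary.
#' @return a number.
#' @export
out_of_grid_penalty <- function() 1e5

# ---------------------------------------------------------------------------
# Map cache
# ---------------------------------------------------------------------------

#' Create a map cache
#'
#' The cache mediates every grid-map file read of a worker. Under
#' `policy = "reuse"` a map, once read, persists for the cache's lifetime
#' (mirroring node-resident maps that persist until program termination),
#' so each atom type is read from disk at most once however many dockings
#' request it; previously unused types are loaded lazily when a ligand
#' first needs them. Under `policy = "reload"` residency is dropped at the
#' end of every docking, so each docking re-reads its maps. The per-type
#' file-read counter is exposed for tests and profiling, and the policy
#' never affects any energy: only how often files are read.
#'
#' @param policy `"reuse"` or `"reload"`.
#' @return an object of class `map_cache` (an environment).
#' @export
map_cache <- function(policy = c("reuse", "reload")) {
  policy <- match.arg(policy)
  e <- new.env(parent = emptyenv())
  e$policy <- policy
  e$loaded <- new.env(parent = emptyenv())     # atom_type -> grid_map
  e$load_counter <- new.env(parent = emptyenv())  # atom_type -> reads
  class(e) <- "map_cache"
  e
}

#' @export
print.map_cache <- function(x, ...) {
  cat("map cache (policy =", x$policy, "):",
      length(ls(x$loaded)), "resident,",
      sum(unlist(as.list(x$load_counter))), "file reads\n")
  invisible(x)
}

#' Fetch a map through the cache
#'
#' Returns the resident map for `atom_type`, reading `source` (a map file
#' path) only when the type is not yet resident. Every file read increments
#' the type's load counter.
#'
#' @param cache a `map_cache`.
#' @param atom_type type label.
#' @param source path of the map file for this type.
#' @return a `grid_map`.
#' @export
cache_get <- function(cache, atom_type, source) {
  if (exists(atom_type, envir = cache$loaded, inherits = FALSE)) {
    return(get(atom_type, envir = cache$loaded, inherits = FALSE))
  }
  if (is.null(source) || is.na(source) || !file.exists(source)) {
    stop(errorCondition(
      paste0("missing map for atom type '", atom_type, "'",
             if (!is.null(source) && !is.na(source)) paste0(" (", source, ")")),
      class = c("missing_map_error", "error"),
      atom_type = atom_type))
  }
  map <- read_map(file = source)
  n_prev <- if (exists(atom_type, envir = cache$load_counter, inherits = FALSE))
    get(atom_type, envir = cache$load_counter, inherits = FALSE) else 0L
  assign(atom_type, n_prev + 1L, envir = cache$load_counter)
  assign(atom_type, map, envir = cache$loaded)
  map
}

#' Make a docking's maps resident
#'
#' Loads the maps for every required atom type plus the reserved
#' electrostatic (`e`) and desolvation (`d`) maps, looking filenames up in
#' `sources` (as returned by [read_fld()]). Under `reuse`, only
#' previously-unseen types cause file reads. Also verifies that all
#' resident maps for this docking share one grid geometry.
#'
#' @param cache a `map_cache`.
#' @param required_types character vector of the ligand's atom types.
#' @param sources named character vector, atom type -> map path.
#' @return the types actually read from disk by this call, invisibly.
#' @export
cache_begin_docking <- function(cache, required_types, sources) {
  types <- unique(c(required_types, "e", "d"))
  read_now <- character(0)
  for (t in types) {
    fresh <- !exists(t, envir = cache$loaded, inherits = FALSE)
    cache_get(cache, t, if (t %in% names(sources)) sources[[t]] else NULL)
    if (fresh) read_now <- c(read_now, t)
  }
  hs <- lapply(types, function(t) {
    h <- get(t, envir = cache$loaded, inherits = FALSE)$header
    c(h$spacing, h$npts, h$center)
  })
  if (length(unique(lapply(hs, function(v) paste(v, collapse = " ")))) != 1) {
    stop("grid maps of one docking must share spacing, size and center")
  }
  invisible(read_now)
}

#' End a docking
#'
#' Under `reload`, drops all resident maps so the next docking re-reads its
#' files; under `reuse`, a no-op.
#'
#' @param cache a `map_cache`.
#' @export
cache_end_docking <- function(cache) {
  if (cache$policy == "reload") {
    rm(list = ls(cache$loaded), envir = cache$loaded)
  }
  invisible(NULL)
}

#' Map file-read counts
#'
#' @param cache a `map_cache`.
#' @return named integer vector: atom type -> number of file reads performed
#'   over the cache's lifetime.
#' @export
cache_load_counts <- function(cache) {
  counts <- unlist(as.list(cache$load_counter))
  if (length(counts) == 0) return(stats::setNames(integer(0), character(0)))
  counts[order(names(counts))]
}
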