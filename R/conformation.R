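# Pose parameterization: a genome (translation + unit quaternion + relative
# torsion angles) applied to ligand coordinates, and plain pose RMSD.

#' Construct a genome state
#'
#' A pose is parameterized by the position of the ligand's root-group
#' centroid (Angstrom), a unit quaternion `(w, x, y, z)` for the rigid-body
#' orientation, and one torsion angle per rotatable bond in degrees,
#' relative to the input conformation and wrapped to `(-180, 180]`. The
#' quaternion is renormalized on construction.
#'
#' @param translation length-3 numeric (Angstrom).
#' @param quaternion length-4 numeric `(w, x, y, z)`; normalized here.
#' @param torsions numeric vector of torsion angles (degrees), possibly
#'   length 0 for a rigid ligand.
#' @return an object of class `genome_state`.
#' @export
genome_state <- function(translation, quaternion = c(1, 0, 0, 0),
                         torsions = numeric(0)) {
  translation <- as.numeric(translation)
  quaternion <- as.numeric(quaternion)
  if (length(translation) != 3 || !all(is.finite(translation))) {
    stop("translation must be 3 finite numbers")
  }
  if (length(quaternion) != 4 || !all(is.finite(quaternion))) {
    stop("quaternion must be 4 finite numbers")
  }
  n <- sqrt(sum(quaternion^2))
  if (n <= 0) stop("quaternion must be nonzero")
  quaternion <- quaternion / n
  torsions <- wrap_angle(as.numeric(torsions))
  structure(list(translation = translation, quaternion = quaternion,
                 torsions = torsions), class = "genome_state")
}

#' Wrap angles to (-180, 180] degrees
#' @param a numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

#' @export
print.genome_state <- function(x, ...) {
  cat(sprintf("genome state: t = (%.3f, %.3f, %.3f), %d torsion(s)\n",
              x$translation[1], x$translation[2], x$translation[3],
              length(x$torsions)))
  invisible(x)
}

#' Identity genome state for a ligand
#'
#' The state that reproduces the ligand's input coordinates: translation at
#' the root-group centroid, identity quaternion, all torsions at 0 (torsion
#' genes are relative to the input conformation).
#'
#' @param ligand a `ligand`.
#' @return a `genome_state`.
#' @export
identity_state <- function(ligand) {
  at <- ligand$atoms
  ctr <- c(mean(at$x[ligand$root]), mean(at$y[ligand$root]),
           mean(at$z[ligand$root]))
  genome_state(ctr, c(1, 0, 0, 0), rep(0, ligand$n_torsions))
}

#' Apply a genome state to a ligand
#'
#' Torsions are applied in tree order from the root outward, each rotating
#' its moved set about the current bond axis (right-hand rule looking from
#' the proximal to the distal bond atom); then the whole body is rotated by
#' the quaternion about the root-group centroid and translated so that
#' centroid lands at `state$translation`. The input coordinates are not
#' modified.
#'
#' @param ligand a `ligand`.
#' @param state a `genome_state` with `length(torsions) == n_torsions`.
#' @return an n-by-3 matrix of atom coordinates (Angstrom).
#' @export
apply_state <- function(ligand, state) {
  if (length(state$torsions) != ligand$n_torsions) {
    stop("state has ", length(state$torsions), " torsions but ligand has ",
         ligand$n_torsions)
  }
  coords <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  cpp_apply_state(coords, ligand$root, ligand$edges,
                  state$translation, state$quaternion, state$torsions)
}

#' Pose RMSD
#'
#' Root-mean-square deviation over matched atoms, with no superposition and
#' no symmetry correction: the poses are compared in the shared receptor
#' frame, as is standard for docking-cluster analysis.
#'
#' @param a,b n-by-3 coordinate matrices with the same atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}
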