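#' Trajectory container
#'
#' A trajectory holds wrapped particle coordinates (nm) on a cubic periodic
#' box, a constant snapshot interval (ps) and an atom table assigning each
#' atom an identifier, a role and a molecule id.  Coordinates are stored as
#' an `n_atoms x 3 x n_frames` array.
#'
#' @param coords numeric array, `n_atoms x 3 x n_frames`, nm.
#' @param box_edge cubic box edge, nm.
#' @param dt snapshot interval, ps.
#' @param atoms data frame with columns `name`, `resname`, `resid`, `role`
#'   (one of `"peptide-H"`, `"fluorine"`, `"water-O"`, `"other"`) and
#'   `mol_id`; a derived `id` column (`"6TrpHE1"`-style) is added if absent.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, box_edge, dt, atoms) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("'coords' must be an n_atoms x 3 x n_frames array")
  if (!is.numeric(box_edge) || box_edge <= 0)
    stop("'box_edge' must be a positive length (nm)")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive (ps)")
  if (nrow(atoms) != dim(coords)[1])
    stop(sprintf("atom table has %d rows but coordinates carry %d atoms",
                 nrow(atoms), dim(coords)[1]))
  required <- c("name", "resname", "resid", "role", "mol_id")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(atoms$role),
                 c("peptide-H", "fluorine", "water-O", "other"))
  if (length(bad)) stop("unknown atom roles: ", paste(bad, collapse = ", "))
  if (is.null(atoms$id)) atoms$id <- atom_id(atoms)
  structure(list(coords = coords, box_edge = box_edge, dt = dt,
                 time = (seq_len(dim(coords)[3]) - 1) * dt,
                 atoms = atoms),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d atoms, %d frames, dt = %g ps, box %g nm\n roles: %s\n",
    dim(x$coords)[1], dim(x$coords)[3], x$dt, x$box_edge,
    paste(sprintf("%s=%d", names(table(x$atoms$role)), table(x$atoms$role)),
          collapse = " ")))
  invisible(x)
}

#' @export
dim.trajectory <- function(x) dim(x$coords)

n_frames <- function(traj) dim(traj$coords)[3]

# "6TrpHE1"-style identifier from residue number + title-case residue name +
# atom name (the convention used in published tables)
atom_id <- function(atoms) {
  rn <- tolower(atoms$resname)
  substr(rn, 1, 1) <- toupper(substr(rn, 1, 1))
  paste0(atoms$resid, rn, atoms$name)
}

#' Resolve an atom identifier to an index
#'
#' Accepts an integer index, an `id` string such as `"6TrpHE1"`, or a plain
#' atom name when unique.
#'
#' @param traj a [trajectory].
#' @param ref identifier (see above).
#' @return integer atom index.
#' @export
select_atom <- function(traj, ref) {
  if (is.numeric(ref)) {
    ref <- as.integer(ref)
    if (ref < 1 || ref > nrow(traj$atoms)) stop("atom index out of range")
    return(ref)
  }
  hit <- which(traj$atoms$id == ref)
  if (length(hit) == 0L) hit <- which(traj$atoms$name == ref)
  if (length(hit) == 0L) stop(sprintf("atom '%s' not found", ref))
  if (length(hit) > 1L)
    stop(sprintf("atom '%s' matches %d atoms", ref, length(hit)))
  hit
}

# default reference hydrogen: the unique peptide-H if present
.default_ref <- function(traj) {
  h <- which(traj$atoms$role == "peptide-H")
  if (length(h) == 0L) stop("trajectory has no peptide-H atom")
  h[1]
}

#' Minimum-image distance between two atoms in one frame
#'
#' @param traj a [trajectory].
#' @param i,j atom identifiers (see [select_atom()]).
#' @param frame frame index (default 1).
#' @return distance in nm, at most `sqrt(3)/2 * box_edge`.
#' @export
min_image_distance <- function(traj, i, j, frame = 1L) {
  i <- select_atom(traj, i); j <- select_atom(traj, j)
  d <- traj$coords[i, , frame] - traj$coords[j, , frame]
  d <- d - traj$box_edge * round(d / traj$box_edge)
  sqrt(sum(d^2))
}

#' Interatomic distance time series
#'
#' Per-frame minimum-image distance between two atoms, the quantity used to
#' follow conformational or solvent-contact separations.
#'
#' @inheritParams min_image_distance
#' @return An object of class `distance_series`: numeric vector of nm with
#'   `time` attribute; `mean` and `range` are reported by `print()`.
#' @export
distance_series <- function(traj, i, j) {
  i <- select_atom(traj, i); j <- select_atom(traj, j)
  d <- matrix(traj$coords[i, , ] - traj$coords[j, , ], nrow = 3L)
  d <- d - traj$box_edge * round(d / traj$box_edge)
  structure(sqrt(colSums(d^2)), time = traj$time, class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance series: %d frames, mean %.4f nm, range %.4f-%.4f nm\n",
              length(x), mean(x), min(x), max(x)))
  invisible(x)
}

#' Unwrapped view of a trajectory
#'
#' Removes periodic wrapping by accumulating minimum-image frame-to-frame
#' displacements, as needed by mean-squared-displacement estimators.  Valid
#' while no particle moves more than half a box edge between snapshots.
#'
#' @param traj a [trajectory].
#' @return coordinate array of the same shape, unwrapped.
#' @export
unwrap_coords <- function(traj) {
  .unwrap_cpp(traj$coords, traj$box_edge)
}
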