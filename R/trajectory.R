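# In-memory trajectory container.
#
# Coordinates are stored as a dense array [n_atoms, 3, n_frames] in nm,
# with one orthorhombic box (Lx, Ly, Lz) and one time (ps) per frame.
# Atom metadata lives in a data.frame; lipid atoms carry the group label
# resolved from their species' lipid_spec.

#' Construct a membrane trajectory object
#'
#' @param atoms data.frame with columns `atom_name`, `residue_index`,
#'   `residue_name`, `element`, `mass` and (after classification) `role`
#'   (`"lipid"`, `"water"`, `"ion"`) and `group` (`"headgroup"`,
#'   `"glycerol"`, `"tails"`, `"water"`, `"ions"`; NA for hydrogens not in
#'   the heavy-atom partition)
#' @param coords numeric array `[n_atoms, 3, n_frames]`, nm
#' @param times numeric vector of frame times, ps, strictly increasing
#' @param box numeric matrix `[n_frames, 3]` of box lengths, nm
#' @param specs named list of `lipid_spec`, keyed by species
#' @return object of class `membrane_trajectory`
#' @export
membrane_trajectory <- function(atoms, coords, times, box, specs = list()) {
  stopifnot(is.data.frame(atoms), is.array(coords), length(dim(coords)) == 3)
  n_atoms <- nrow(atoms)
  n_frames <- length(times)
  if (n_frames < 1) stop("trajectory needs at least one frame", call. = FALSE)
  if (!all(dim(coords) == c(n_atoms, 3, n_frames))) {
    stop("coords must be [n_atoms, 3, n_frames] = [", n_atoms, ", 3, ",
         n_frames, "]", call. = FALSE)
  }
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3,
                                       byrow = TRUE)
  if (!all(dim(box) == c(n_frames, 3)) || any(box <= 0)) {
    stop("box must be a positive [n_frames, 3] matrix", call. = FALSE)
  }
  if (n_frames > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (any(!nzchar(atoms$atom_name))) stop("empty atom name", call. = FALSE)
  if (any(atoms$mass <= 0)) stop("non-positive atom mass", call. = FALSE)
  structure(
    list(atoms = atoms, coords = coords, times = times, box = box,
         specs = specs),
    class = "membrane_trajectory"
  )
}

#' @export
print.membrane_trajectory <- function(x, ...) {
  cat(sprintf("<membrane_trajectory> %d atoms, %d frames (%.1f-%.1f ps)\n",
              nrow(x$atoms), n_frames(x), min(x$times), max(x$times)))
  if ("role" %in% names(x$atoms)) {
    tb <- table(x$atoms$role)
    cat("  roles:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  if (length(x$specs)) {
    cat("  species:", paste(names(x$specs), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj `membrane_trajectory`
#' @return integer
#' @export
n_frames <- function(traj) length(traj$times)

#' Restrict a trajectory to a time window
#'
#' Keeps the frames with `t_start <= time <= t_end`, preserving order.
#' Typical use is to discard an equilibration transient and analyze only
#' the final window of a run.
#'
#' @param traj `membrane_trajectory`
#' @param t_start,t_end window bounds in ps (`t_start < t_end`)
#' @return `membrane_trajectory` restricted to the window
#' @export
slice_time <- function(traj, t_start, t_end) {
  stopifnot(t_start < t_end)
  keep <- which(traj$times >= t_start & traj$times <= t_end)
  if (!length(keep)) {
    stop("empty time window [", t_start, ", ", t_end, "] ps: trajectory spans [",
         min(traj$times), ", ", max(traj$times), "] ps", call. = FALSE)
  }
  membrane_trajectory(traj$atoms, traj$coords[, , keep, drop = FALSE],
                      traj$times[keep], traj$box[keep, , drop = FALSE],
                      traj$specs)
}

# Indices of one atom name within each lipid residue of a species.
# Returns a data.frame(residue_index, atom_index).
atom_index_by_residue <- function(traj, species, atom_name) {
  a <- traj$atoms
  sel <- which(a$residue_name == species & a$atom_name == atom_name)
  data.frame(residue_index = a$residue_index[sel], atom_index = sel)
}

# Minimum-image displacement of (possibly vectorized) coordinate
# differences under an orthorhombic box length L (same shape recycling as
# base arithmetic).
min_image <- function(d, L) d - L * round(d / L)
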