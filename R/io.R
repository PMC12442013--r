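# File I/O: GRO (hand-rolled fixed-width text, single- or multi-frame),
# DCD (CHARMM-style binary; written here, read back through bio3d), and
# PDB via bio3d.  GRO/DCD coordinates are nm internally, Angstrom in DCD
# and PDB as those formats prescribe.

#' Read a GRO file (single- or multi-frame)
#'
#' GROMACS `.gro` files concatenate frames; the title line is scanned for a
#' `t= <time>` tag (ps).  Frames without a time tag are numbered 0, 1, ...
#' ps.  Only orthorhombic boxes (first three box-line fields) are
#' supported.
#'
#' @param path path to the `.gro` file
#' @return list with `atoms` (data.frame: `residue_index`, `residue_name`,
#'   `atom_name`), `coords` array `[n_atoms, 3, n_frames]` in nm, `times`
#'   (ps), `box` matrix `[n_frames, 3]` in nm
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list(); times <- numeric(); boxes <- list()
  atoms <- NULL
  i <- 1L
  while (i + 1L <= length(lines) && nzchar(trimws(lines[i + 1L]))) {
    title <- lines[i]
    natoms <- as.integer(trimws(lines[i + 1L]))
    at_lines <- lines[(i + 2L):(i + 1L + natoms)]
    box_line <- lines[i + 2L + natoms]
    tm <- regmatches(title, regexec("t=\\s*([0-9eE+.-]+)", title))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2])
               else length(frames))
    if (is.null(atoms)) {
      atoms <- data.frame(
        residue_index = as.integer(substr(at_lines, 1, 5)),
        residue_name = trimws(substr(at_lines, 6, 10)),
        atom_name = trimws(substr(at_lines, 11, 15)),
        stringsAsFactors = FALSE
      )
    }
    xyz <- matrix(c(as.numeric(substr(at_lines, 21, 28)),
                    as.numeric(substr(at_lines, 29, 36)),
                    as.numeric(substr(at_lines, 37, 44))),
                  ncol = 3)
    frames[[length(frames) + 1L]] <- xyz
    bx <- as.numeric(strsplit(trimws(box_line), "\\s+")[[1]])[1:3]
    boxes[[length(boxes) + 1L]] <- bx
    i <- i + 3L + natoms
    if (i > length(lines)) break
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  coords <- array(unlist(frames), dim = c(nrow(atoms), 3, length(frames)))
  list(atoms = atoms, coords = coords, times = times,
       box = do.call(rbind, boxes))
}

#' Write a trajectory (or selected frames) as a GRO file
#'
#' @param traj `membrane_trajectory`
#' @param path output path
#' @param frames integer indices of frames to write (default: all)
#' @param title title prefix for each frame
#' @return `path`, invisibly
#' @export
write_gro <- function(traj, path, frames = seq_len(n_frames(traj)),
                      title = "bilayr system") {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  atom_no <- (seq_len(nrow(a)) - 1L) %% 99999L + 1L
  res_no <- a$residue_index %% 100000L
  for (f in frames) {
    xyz <- traj$coords[, , f]
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    res_no, a$residue_name, a$atom_name, atom_no,
                    xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(sprintf("%s, t= %.4f", title, traj$times[f]),
                 sprintf("%5d", nrow(a)), body,
                 sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1],
                         traj$box[f, 2], traj$box[f, 3])), con)
  }
  invisible(path)
}

# Fortran-style unformatted record: length, payload, length.
.write_record <- function(con, payload_writer, nbytes) {
  writeBin(as.integer(nbytes), con, size = 4)
  payload_writer()
  writeBin(as.integer(nbytes), con, size = 4)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Coordinates are stored in Angstrom as single precision, with the
#' orthorhombic unit cell per frame and the frame spacing (ps) in the
#' header's timestep field.  Frame times must be uniformly spaced.
#'
#' @param traj `membrane_trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj)
  dt <- if (nf > 1) diff(traj$times)[1] else 1
  if (nf > 2 && max(abs(diff(traj$times) - dt)) > 1e-6 * dt) {
    stop("DCD requires uniformly spaced frames", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L   # crystal (unit-cell) records present
  icntrl[20] <- 24L  # CHARMM version tag
  .write_record(con, function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl[1:9], con, size = 4)
    writeBin(as.numeric(dt), con, size = 4)        # timestep, ps, float32
    writeBin(icntrl[11:20], con, size = 4)
  }, 84L)
  title <- sprintf("%-80s", "bilayr trajectory")
  .write_record(con, function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, 80, eos = NULL)
  }, 84L)
  .write_record(con, function() writeBin(nrow(traj$atoms), con, size = 4), 4L)
  na <- nrow(traj$atoms)
  for (f in seq_len(nf)) {
    cell <- c(traj$box[f, 1] * 10, 0, traj$box[f, 2] * 10, 0, 0,
              traj$box[f, 3] * 10)
    .write_record(con, function() writeBin(cell, con, size = 8), 48L)
    xyz <- traj$coords[, , f] * 10
    for (ax in 1:3) {
      .write_record(con, function() writeBin(xyz[, ax], con, size = 4),
                    4L * na)
    }
  }
  invisible(path)
}

# Pull frame-timing fields straight from a DCD header (bio3d does not
# expose the timestep).
.read_dcd_timing <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "integer", 1, size = 4)          # record length
  readChar(con, 4)                              # 'CORD'
  ic <- readBin(con, "integer", 9, size = 4)
  dt <- readBin(con, "numeric", 1, size = 4)
  list(nframes = ic[1], istart = ic[2], nsavc = ic[3], dt_ps = dt)
}

#' Read a DCD trajectory
#'
#' Coordinates and unit cells are read with [bio3d::read.dcd]; frame times
#' are reconstructed from the header timestep (interpreted as ps).
#'
#' @param path path to the `.dcd` file
#' @return list with `coords` array `[n_atoms, 3, n_frames]` (nm), `times`
#'   (ps), `box` matrix (nm)
#' @export
read_dcd_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  xyz <- bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)
  cell <- bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)
  timing <- .read_dcd_timing(path)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m / 10
  }
  box <- cbind(cell[, 1], cell[, 2], cell[, 3]) / 10
  times <- timing$istart + (seq_len(nf) - 1) * timing$nsavc * timing$dt_ps
  list(coords = coords, times = times, box = box)
}

#' Read a PDB file as topology (and frames, if multi-model)
#'
#' Uses [bio3d::read.pdb].  The box is taken from CRYST1 when present;
#' frame times are numbered 0, 1, ... ps (PDB carries no time axis).
#'
#' @param path path to the `.pdb` file
#' @return list with `atoms`, `coords` (nm), `times`, `box` as in
#'   [read_gro()]
#' @export
read_pdb_system <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(residue_index = at$resno,
                      residue_name = trimws(at$resid),
                      atom_name = trimws(at$elety),
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  }
  # bio3d does not expose CRYST1; take it from the header directly
  cryst <- grep("^CRYST1", readLines(path, n = 200), value = TRUE)
  abc <- if (length(cryst)) {
    as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                 substr(cryst[1], 25, 33)))
  } else NA
  box <- if (!anyNA(abc) && all(abc > 0)) {
    matrix(abc / 10, nrow = nf, ncol = 3, byrow = TRUE)
  } else {
    # fall back to the coordinate extent; analyses needing periodicity
    # should be given a real box
    ext <- apply(coords, 2, function(m) diff(range(m))) + 1
    matrix(ext, nrow = nf, ncol = 3, byrow = TRUE)
  }
  list(atoms = atoms, coords = coords, times = seq_len(nf) - 1, box = box)
}
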