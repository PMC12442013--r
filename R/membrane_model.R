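# System loading and lipid-group resolution.
#
# Every lipid residue in the input must be covered by a lipid_spec; water
# and ion residues are recognized by configurable residue-name sets.  Heavy
# atoms of a lipid are classified into headgroup / glycerol / tails by the
# spec's group map; lipid hydrogens are attached to no group (they are
# excluded from lateral-density group masses for comparability with
# united-atom parametrizations).

.default_water_resnames <- c("SOL", "TIP3", "TIP3P", "WAT", "HOH", "SPC")
.default_ion_resnames <- c("NA", "CL", "K", "MG", "CA", "SOD", "CLA", "POT")

# Classify atoms in place; errors on unknown residues / uncovered atoms.
classify_atoms <- function(atoms, specs, water_resnames, ion_resnames) {
  atoms$element <- guess_element(atoms$atom_name)
  atoms$mass <- element_mass(atoms$element)
  atoms$role <- NA_character_
  atoms$group <- NA_character_
  res <- atoms$residue_name
  atoms$role[res %in% water_resnames] <- "water"
  atoms$group[res %in% water_resnames] <- "water"
  atoms$role[res %in% ion_resnames] <- "ion"
  atoms$group[res %in% ion_resnames] <- "ions"
  lipid_res <- setdiff(unique(res),
                       c(water_resnames, ion_resnames))
  unknown <- setdiff(lipid_res, names(specs))
  if (length(unknown)) {
    stop("no lipid spec for residue name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sp in lipid_res) {
    spec <- specs[[sp]]
    sel <- res == sp
    atoms$role[sel] <- "lipid"
    for (g in names(spec$groups)) {
      atoms$group[sel & atoms$atom_name %in% spec$groups[[g]]] <- g
    }
    uncovered <- sel & is.na(atoms$group) & atoms$element != "H"
    if (any(uncovered)) {
      stop("heavy atom(s) of ", sp, " not covered by its group map: ",
           paste(unique(atoms$atom_name[uncovered]), collapse = ", "),
           call. = FALSE)
    }
  }
  atoms
}

#' Load a bilayer system from topology + trajectory files
#'
#' Reads a topology (`.gro` or `.pdb`) and, optionally, a trajectory
#' (`.dcd`, or a multi-frame `.gro`/`.pdb`), resolves every lipid atom to a
#' headgroup/glycerol/tails group through the supplied specs, and tags
#' water and ion residues.  When no trajectory file is given the topology's
#' own frame(s) are used.
#'
#' @param topology_path path to a `.gro` or `.pdb` file
#' @param trajectory_path optional path to a `.dcd`, `.gro` or `.pdb`
#'   trajectory with the same atom order
#' @param lipid_specs list of [lipid_spec()] objects (or paths to YAML
#'   spec files); one per lipid residue name present
#' @param water_resnames,ion_resnames residue names recognized as
#'   water / ions
#' @return `membrane_trajectory`
#' @export
load_system <- function(topology_path, trajectory_path = NULL, lipid_specs,
                        water_resnames = .default_water_resnames,
                        ion_resnames = .default_ion_resnames) {
  top <- switch(tolower(tools::file_ext(topology_path)),
                gro = read_gro(topology_path),
                pdb = read_pdb_system(topology_path),
                stop("unsupported topology format: ", topology_path,
                     call. = FALSE))
  specs <- lapply(lipid_specs, function(s) {
    if (is.character(s)) read_lipid_spec(s) else s
  })
  names(specs) <- vapply(specs, `[[`, character(1), "species")
  atoms <- classify_atoms(top$atoms, specs, water_resnames, ion_resnames)
  if (is.null(trajectory_path)) {
    return(membrane_trajectory(atoms, top$coords, top$times, top$box, specs))
  }
  trj <- switch(tolower(tools::file_ext(trajectory_path)),
                dcd = read_dcd_trajectory(trajectory_path),
                gro = read_gro(trajectory_path),
                pdb = read_pdb_system(trajectory_path),
                stop("unsupported trajectory format: ", trajectory_path,
                     call. = FALSE))
  if (dim(trj$coords)[1] != nrow(atoms)) {
    stop("trajectory atom count (", dim(trj$coords)[1],
         ") does not match topology (", nrow(atoms), ")", call. = FALSE)
  }
  membrane_trajectory(atoms, trj$coords, trj$times, trj$box, specs)
}

#' Assign lipids to leaflets
#'
#' The bilayer midplane is the mean z of all phosphorus atoms in the chosen
#' frame; a lipid belongs to the upper leaflet iff its phosphorus sits
#' above the midplane.  The assignment is computed once (default: first
#' frame) and held fixed for the rest of the analysis; lipid flip-flop is
#' negligible on the timescales this pipeline addresses.
#'
#' @param traj `membrane_trajectory` with classified lipids
#' @param frame frame index used for the assignment (default 1)
#' @return object of class `leaflet_assignment`: data.frame
#'   (`residue_index`, `species`, `p_atom_index`, `leaflet`) plus
#'   attributes `midplane_z` (nm) and `frame`
#' @export
assign_leaflets <- function(traj, frame = 1L) {
  ptab <- phosphorus_table(traj)
  if (nrow(ptab) < 2) {
    stop("need at least 2 lipids with phosphorus atoms", call. = FALSE)
  }
  z <- traj$coords[ptab$atom_index, 3, frame]
  mid <- mean(z)
  leaflet <- ifelse(z > mid, "upper", "lower")
  if (length(unique(leaflet)) < 2) {
    stop("degenerate bilayer: all phosphorus atoms on one side of the ",
         "midplane (monolayer?)", call. = FALSE)
  }
  out <- data.frame(residue_index = ptab$residue_index,
                    species = ptab$species,
                    p_atom_index = ptab$atom_index,
                    leaflet = leaflet,
                    stringsAsFactors = FALSE)
  attr(out, "midplane_z") <- mid
  attr(out, "frame") <- frame
  class(out) <- c("leaflet_assignment", "data.frame")
  out
}

# One row per lipid: residue_index, species, index of its phosphorus atom.
phosphorus_table <- function(traj) {
  res <- lapply(names(traj$specs), function(sp) {
    p_name <- traj$specs[[sp]]$phosphorus_atom
    tab <- atom_index_by_residue(traj, sp, p_name)
    if (nrow(tab)) tab$species <- sp
    tab
  })
  do.call(rbind, res[vapply(res, nrow, integer(1)) > 0])
}

# Counts per leaflet, as a named integer vector c(upper=, lower=).
leaflet_counts <- function(leaflets) {
  c(upper = sum(leaflets$leaflet == "upper"),
    lower = sum(leaflets$leaflet == "lower"))
}
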