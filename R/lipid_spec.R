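# Declarative per-species lipid specifications.
#
# A lipid spec maps the atom nomenclature of one residue type onto the
# quantities the analyses need: the headgroup/glycerol/tails partition of
# the heavy atoms (headgroup runs from the top of the lipid down to and
# including the phosphorus; glycerol from the phosphoester oxygen to the
# ester oxygens; tails from the carbonyl carbon outward), the phosphorus
# atom and the PO4 atom set, the C-H pairs per carbon label, and the
# hydrogen-bonding atoms with their per-atom capacities (neutral oxygen 2,
# charged oxygen 3, polar hydrogen 1).

#' Construct a lipid specification
#'
#' @param species residue name of the lipid (e.g. `"POPC"`)
#' @param groups named list with elements `headgroup`, `glycerol`, `tails`,
#'   each a character vector of heavy-atom names; together they must cover
#'   every heavy atom of the residue, with no overlaps
#' @param phosphorus_atom name of the phosphorus atom
#' @param po4_atoms character vector of the phosphate-group atom names; must
#'   contain `phosphorus_atom`
#' @param ch_pairs named list: carbon label -> list of length-2 character
#'   vectors `c(carbon_name, hydrogen_name)`
#' @param hbond_atoms named list: atom name -> list with `role`
#'   (`"donor_H"` or `"acceptor"`) and integer `capacity` in 1..3
#' @param segments optional named character vector mapping carbon labels to
#'   a segment tag in `c("headgroup", "sn-1", "sn-2")`, used by the
#'   order-parameter comparison
#' @return object of class `lipid_spec`
#' @export
lipid_spec <- function(species, groups, phosphorus_atom, po4_atoms,
                       ch_pairs = list(), hbond_atoms = list(),
                       segments = NULL) {
  stopifnot(is.character(species), length(species) == 1, nzchar(species))
  need <- c("headgroup", "glycerol", "tails")
  if (!all(need %in% names(groups))) {
    stop("groups must name headgroup, glycerol and tails", call. = FALSE)
  }
  all_atoms <- unlist(groups[need], use.names = FALSE)
  if (anyDuplicated(all_atoms)) {
    stop("atom(s) assigned to more than one group in spec for ", species,
         ": ", paste(all_atoms[duplicated(all_atoms)], collapse = ", "),
         call. = FALSE)
  }
  if (!phosphorus_atom %in% po4_atoms) {
    stop("phosphorus_atom must be a member of po4_atoms", call. = FALSE)
  }
  for (lbl in names(ch_pairs)) {
    ch_pairs[[lbl]] <- lapply(ch_pairs[[lbl]], function(p) {
      p <- as.character(unlist(p))
      if (length(p) != 2) stop("ch_pairs entries must be (C, H) pairs",
                               call. = FALSE)
      p
    })
  }
  for (nm in names(hbond_atoms)) {
    h <- hbond_atoms[[nm]]
    if (!h$role %in% c("donor_H", "acceptor")) {
      stop("hbond role must be donor_H or acceptor (atom ", nm, ")",
           call. = FALSE)
    }
    if (!h$capacity %in% 1:3) {
      stop("hbond capacity must be 1, 2 or 3 (atom ", nm, ")", call. = FALSE)
    }
  }
  structure(
    list(species = species,
         groups = groups[need],
         phosphorus_atom = phosphorus_atom,
         po4_atoms = po4_atoms,
         ch_pairs = ch_pairs,
         hbond_atoms = hbond_atoms,
         segments = segments),
    class = "lipid_spec"
  )
}

#' @export
print.lipid_spec <- function(x, ...) {
  cat(sprintf("<lipid_spec> %s: %d headgroup / %d glycerol / %d tail atoms, %d C-H labels, %d H-bond atoms\n",
              x$species, length(x$groups$headgroup), length(x$groups$glycerol),
              length(x$groups$tails), length(x$ch_pairs),
              length(x$hbond_atoms)))
  invisible(x)
}

#' Read a lipid specification from a YAML file
#'
#' One document per species with keys `species`, `groups`,
#' `phosphorus_atom`, `po4_atoms`, `ch_pairs`, `hbond_atoms`, and optional
#' `segments`.
#'
#' @param path path to the YAML file
#' @return `lipid_spec`
#' @export
read_lipid_spec <- function(path) {
  if (!file.exists(path)) stop("lipid spec file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  segments <- if (!is.null(y$segments)) unlist(y$segments) else NULL
  hb <- lapply(y$hbond_atoms, function(h) {
    h$capacity <- as.integer(h$capacity)
    h
  })
  lipid_spec(species = y$species, groups = y$groups,
             phosphorus_atom = y$phosphorus_atom,
             po4_atoms = unlist(y$po4_atoms),
             ch_pairs = y$ch_pairs, hbond_atoms = hb, segments = segments)
}

#' Write a lipid specification to YAML
#'
#' @param spec `lipid_spec`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_lipid_spec <- function(spec, path) {
  y <- list(species = spec$species, groups = spec$groups,
            phosphorus_atom = spec$phosphorus_atom,
            po4_atoms = spec$po4_atoms,
            ch_pairs = spec$ch_pairs,
            hbond_atoms = spec$hbond_atoms)
  if (!is.null(spec$segments)) y$segments <- as.list(spec$segments)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Load a bundled lipid specification
#'
#' The package ships specifications for POPC, POPE and POPG using
#' CHARMM36-style atom nomenclature.
#'
#' @param species one of `"POPC"`, `"POPE"`, `"POPG"`
#' @return `lipid_spec`
#' @export
bundled_lipid_spec <- function(species) {
  path <- system.file("extdata", "lipid_specs",
                      paste0(tolower(species), ".yaml"), package = "bilayr")
  if (!nzchar(path)) {
    stop("no bundled spec for species '", species, "'", call. = FALSE)
  }
  read_lipid_spec(path)
}

# Per-molecule H-bond capacity: the sum of the per-atom capacities of the
# spec's hbond atoms restricted to one group (headgroup/glycerol) or to the
# whole molecule.
hbond_capacity <- function(spec, group = NULL) {
  atoms <- names(spec$hbond_atoms)
  if (!is.null(group)) atoms <- intersect(atoms, spec$groups[[group]])
  # donor hydrogens are not heavy atoms and so are not in the group map;
  # attribute each donor H to the group of any heavy atom it is listed with
  if (!is.null(group)) {
    hs <- names(spec$hbond_atoms)[vapply(spec$hbond_atoms,
                                         function(h) h$role == "donor_H",
                                         logical(1))]
    owner <- vapply(hs, function(h) {
      g <- spec$hbond_atoms[[h]]$group
      if (is.null(g)) NA_character_ else g
    }, character(1))
    atoms <- union(atoms, hs[!is.na(owner) & owner == group])
  }
  if (!length(atoms)) return(0L)
  sum(vapply(spec$hbond_atoms[atoms], function(h) as.integer(h$capacity),
             integer(1)))
}
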