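# Packing and hydrogen bonding: PO4-PO4 radial distribution functions,
# geometric H-bond detection, and the capacity-normalized H-bond statistic.
#
# The normalization corrects observed H-bond counts for differences in
# molecule abundance and per-molecule bonding capacity:
#   N_max    = sum_i chi_i * n_i   over every compound i in the system,
#   P(Y)     = chi_Y * n_Y / N_max,
#   N_norm(X,Y) = N_obs(X,Y) / (N_max * [P(X) + P(Y)]),
# with per-atom capacities chi: neutral oxygen 2, charged oxygen 3, polar
# hydrogen 1, summed per molecule of each type.

# Center of mass of the PO4 group of every lipid of one species, one
# frame.  Returns a matrix [n_lipids, 3].
po4_com <- function(traj, species, frame) {
  spec <- traj$specs[[species]]
  if (is.null(spec)) stop("no spec for species ", species, call. = FALSE)
  a <- traj$atoms
  sel <- which(a$residue_name == species & a$atom_name %in% spec$po4_atoms)
  if (!length(sel)) stop("species ", species, " has no PO4 atoms",
                         call. = FALSE)
  m <- a$mass[sel]
  res <- a$residue_index[sel]
  xyz <- traj$coords[sel, , frame]
  wsum <- rowsum(xyz * m, res)
  sweep(wsum, 1, rowsum(m, res)[, 1], "/")
}

# All minimum-image pair distances between rows of A and B ([n,3]
# matrices) under orthorhombic box L; if B is NULL, unique self-pairs of A
# (i < j) are returned.
pair_distances <- function(A, B = NULL, L) {
  if (is.null(B)) {
    n <- nrow(A)
    if (n < 2) return(numeric(0))
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d2 <- 0
    for (ax in 1:3) {
      d <- min_image(A[ij[, 1], ax] - A[ij[, 2], ax], L[ax])
      d2 <- d2 + d^2
    }
  } else {
    d2 <- 0
    for (ax in 1:3) {
      d <- min_image(rep(A[, ax], times = nrow(B)) -
                       rep(B[, ax], each = nrow(A)), L[ax])
      d2 <- d2 + d^2
    }
  }
  sqrt(d2)
}

#' Radial distribution function between PO4 centers of mass
#'
#' Standard 3D pair RDF with shell normalization by the ideal-gas pair
#' density `N_A * N_B / V` per frame (self-pairs excluded when the two
#' species coincide), averaged over frames.
#'
#' @param traj `membrane_trajectory`
#' @param species_A,species_B lipid species names
#' @param r_max maximum distance, nm; must not exceed half the smallest
#'   box edge
#' @param dr bin width, nm
#' @param frame_stride analyze every `frame_stride`-th frame
#' @return object of class `rdf_result`: data.frame (`r`, `g`) with
#'   attributes `species`, `dr`, `r_max`
#' @export
rdf_po4 <- function(traj, species_A, species_B = species_A, r_max = 2.0,
                    dr = 0.02, frame_stride = 1L) {
  if (any(r_max > apply(traj$box, 1, min) / 2)) {
    stop("r_max = ", r_max, " nm exceeds half the smallest box edge",
         call. = FALSE)
  }
  frames <- seq(1, n_frames(traj), by = frame_stride)
  edges <- seq(0, r_max, by = dr)
  nbin <- length(edges) - 1L
  gacc <- numeric(nbin)
  same <- identical(species_A, species_B)
  for (f in frames) {
    A <- po4_com(traj, species_A, f)
    B <- if (same) NULL else po4_com(traj, species_B, f)
    L <- traj$box[f, ]
    V <- prod(L)
    d <- pair_distances(A, B, L)
    nA <- nrow(A); nB <- if (same) nA else nrow(B)
    h <- tabulate(pmin(floor(d / dr) + 1L, nbin + 1L), nbin + 1L)[1:nbin]
    npairs_ideal <- if (same) nA * (nA - 1) else nA * nB
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbin + 1)]^3)
    # unique self-pairs were counted once; the ideal count uses ordered
    # pairs, so double the histogram in the A == B case
    if (same) h <- 2 * h
    gacc <- gacc + h / (npairs_ideal / V * shell)
  }
  g <- gacc / length(frames)
  out <- data.frame(r = edges[-length(edges)] + dr / 2, g = g)
  attr(out, "species") <- c(species_A, species_B)
  attr(out, "dr") <- dr
  attr(out, "r_max") <- r_max
  class(out) <- c("rdf_result", "data.frame")
  out
}

#' Detect hydrogen bonds in one frame
#'
#' A donor-H...acceptor triple is counted as a bond iff the donor-acceptor
#' distance is at most `d_cut` and the H-donor-acceptor angle is at most
#' `angle_cut`, both under the minimum-image convention in all three axes.
#' The defaults (0.35 nm, 30 degrees) are the customary geometric
#' criterion for trajectory analysis.
#'
#' @param coords `[n_atoms, 3]` coordinate matrix, nm
#' @param box length-3 box vector, nm
#' @param donors data.frame with columns `donor` (heavy-atom index) and
#'   `hydrogen` (index of the attached polar H)
#' @param acceptors integer vector of acceptor atom indices
#' @param d_cut donor-acceptor distance cutoff, nm
#' @param angle_cut H-donor-acceptor angle cutoff, degrees
#' @return data.frame (`donor`, `hydrogen`, `acceptor`, `distance`,
#'   `angle`) with one row per bond
#' @export
detect_hbonds <- function(coords, box, donors, acceptors, d_cut = 0.35,
                          angle_cut = 30) {
  nd <- nrow(donors); na <- length(acceptors)
  if (!nd || !na) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  di <- rep(seq_len(nd), times = na)
  ai <- rep(seq_len(na), each = nd)
  D <- coords[donors$donor, , drop = FALSE]
  A <- coords[acceptors, , drop = FALSE]
  dv <- matrix(0, nd * na, 3)
  for (ax in 1:3) {
    dv[, ax] <- min_image(A[ai, ax] - D[di, ax], box[ax])
  }
  dist <- sqrt(rowSums(dv^2))
  keep <- dist <= d_cut & acceptors[ai] != donors$donor[di]
  if (!any(keep)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  di <- di[keep]; ai <- ai[keep]; dv <- dv[keep, , drop = FALSE]
  dist <- dist[keep]
  H <- coords[donors$hydrogen[di], , drop = FALSE]
  hv <- matrix(0, length(di), 3)
  for (ax in 1:3) {
    hv[, ax] <- min_image(H[, ax] - coords[donors$donor[di], ax], box[ax])
  }
  cosang <- rowSums(hv * dv) / (sqrt(rowSums(hv^2)) * dist)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- ang <= angle_cut
  data.frame(donor = donors$donor[di[ok]],
             hydrogen = donors$hydrogen[di[ok]],
             acceptor = acceptors[ai[ok]],
             distance = dist[ok], angle = ang[ok])
}

#' Normalize an H-bond census
#'
#' @param types data.frame with one row per molecule type: `type` (label),
#'   `n` (molecule count), `chi` (per-molecule H-bond capacity, the sum of
#'   its atoms' capacities)
#' @param n_obs data.frame of observed mean bond counts per ordered type
#'   pair: columns `X`, `Y`, `N_obs`
#' @return object of class `hbond_census`: the `n_obs` table extended with
#'   `N_norm`, plus attributes `N_max` and `P` (named probabilities
#'   summing to 1)
#' @export
normalize_hbonds <- function(types, n_obs) {
  stopifnot(all(c("type", "n", "chi") %in% names(types)),
            all(c("X", "Y", "N_obs") %in% names(n_obs)))
  N_max <- sum(types$chi * types$n)
  if (N_max == 0) stop("N_max is zero: no H-bonding capacity in the census",
                       call. = FALSE)
  P <- stats::setNames(types$chi * types$n / N_max, types$type)
  miss <- setdiff(unique(c(n_obs$X, n_obs$Y)), types$type)
  if (length(miss)) {
    stop("type(s) in n_obs missing from the census: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n_obs$N_norm <- n_obs$N_obs / (N_max * (P[n_obs$X] + P[n_obs$Y]))
  attr(n_obs, "N_max") <- N_max
  attr(n_obs, "P") <- P
  class(n_obs) <- c("hbond_census", "data.frame")
  n_obs
}

# H-bond atom selections for a trajectory: donors (heavy atom + attached
# H) and acceptors, each tagged with a census type.  Lipid types are
# species:group; all waters pool into "solvent".
hbond_selections <- function(traj) {
  a <- traj$atoms
  donors <- list(); acceptors <- list()
  for (sp in names(traj$specs)) {
    spec <- traj$specs[[sp]]
    for (atom in names(spec$hbond_atoms)) {
      h <- spec$hbond_atoms[[atom]]
      grp <- if (!is.null(h$group)) h$group else {
        gs <- names(spec$groups)[vapply(spec$groups,
                                        function(g) atom %in% g, logical(1))]
        if (length(gs)) gs[1] else NA_character_
      }
      if (is.na(grp) || !grp %in% c("headgroup", "glycerol")) next
      type <- paste0(sp, ":", grp)
      idx <- which(a$residue_name == sp & a$atom_name == atom)
      if (h$role == "acceptor") {
        acceptors[[length(acceptors) + 1L]] <-
          data.frame(index = idx, type = type)
      } else {
        # donor hydrogen: attach to the heavy atom it is bonded to, named
        # in h$bonded_to (defaults to the preceding heavy atom row)
        heavy <- h$bonded_to
        if (is.null(heavy)) next
        res <- a$residue_index[idx]
        heavy_idx <- vapply(seq_along(idx), function(k) {
          which(a$residue_index == res[k] & a$atom_name == heavy)[1]
        }, integer(1))
        donors[[length(donors) + 1L]] <-
          data.frame(donor = heavy_idx, hydrogen = idx, type = type)
      }
    }
  }
  w_o <- which(a$role %in% "water" & a$element == "O")
  if (length(w_o)) {
    acceptors[[length(acceptors) + 1L]] <-
      data.frame(index = w_o, type = "solvent")
    for (off in 1:2) {
      donors[[length(donors) + 1L]] <-
        data.frame(donor = w_o, hydrogen = w_o + off, type = "solvent")
    }
  }
  list(donors = do.call(rbind, donors), acceptors = do.call(rbind, acceptors))
}

# Per-molecule-type census table (type, n, chi) for the normalization.
hbond_type_table <- function(traj) {
  a <- traj$atoms
  rows <- list()
  for (sp in names(traj$specs)) {
    spec <- traj$specs[[sp]]
    n_mol <- length(unique(a$residue_index[a$residue_name == sp]))
    if (!n_mol) next
    for (grp in c("headgroup", "glycerol")) {
      rows[[length(rows) + 1L]] <-
        data.frame(type = paste0(sp, ":", grp), n = n_mol,
                   chi = hbond_capacity(spec, grp))
    }
  }
  n_wat <- length(unique(a$residue_index[a$role %in% "water"]))
  if (n_wat) {
    # per-atom rules for a 3-site water: one neutral O (2) + two polar H
    # (1 each) -> chi = 4
    rows[[length(rows) + 1L]] <- data.frame(type = "solvent", n = n_wat,
                                            chi = 4L)
  }
  do.call(rbind, rows)
}

#' H-bond census over a trajectory
#'
#' Runs [detect_hbonds()] on every analyzed frame, accumulates the mean
#' bond count per ordered donor-type/acceptor-type pair, and applies the
#' capacity normalization of [normalize_hbonds()].  Census types are
#' species:headgroup, species:glycerol, and a pooled "solvent" type; the
#' per-molecule capacities are computed from the per-atom rules and
#' reported in the result's `types` attribute for inspection.
#'
#' @param traj `membrane_trajectory`
#' @param d_cut,angle_cut geometric criterion, see [detect_hbonds()]
#' @param frame_stride analyze every `frame_stride`-th frame
#' @return `hbond_census` (see [normalize_hbonds()]) with attribute `types`
#' @export
hbond_census <- function(traj, d_cut = 0.35, angle_cut = 30,
                         frame_stride = 1L) {
  sel <- hbond_selections(traj)
  types <- hbond_type_table(traj)
  if (is.null(sel$donors) || is.null(sel$acceptors)) {
    stop("no H-bond donors/acceptors defined by the specs", call. = FALSE)
  }
  frames <- seq(1, n_frames(traj), by = frame_stride)
  pair_keys <- character(0)
  tally <- numeric(0)
  for (f in frames) {
    bonds <- detect_hbonds(traj$coords[, , f], traj$box[f, ],
                           sel$donors[, c("donor", "hydrogen")],
                           sel$acceptors$index, d_cut, angle_cut)
    if (!nrow(bonds)) next
    dt <- sel$donors$type[match(bonds$donor, sel$donors$donor)]
    at <- sel$acceptors$type[match(bonds$acceptor, sel$acceptors$index)]
    key <- paste(dt, at, sep = "|")
    tb <- table(key)
    for (k in names(tb)) {
      j <- match(k, pair_keys)
      if (is.na(j)) {
        pair_keys <- c(pair_keys, k); tally <- c(tally, tb[[k]])
      } else tally[j] <- tally[j] + tb[[k]]
    }
  }
  if (!length(pair_keys)) {
    n_obs <- data.frame(X = character(0), Y = character(0),
                        N_obs = numeric(0))
  } else {
    parts <- strsplit(pair_keys, "|", fixed = TRUE)
    n_obs <- data.frame(X = vapply(parts, `[`, "", 1),
                        Y = vapply(parts, `[`, "", 2),
                        N_obs = tally / length(frames),
                        stringsAsFactors = FALSE)
  }
  out <- normalize_hbonds(types, n_obs)
  attr(out, "types") <- types
  attr(out, "params") <- list(d_cut = d_cut, angle_cut = angle_cut,
                              frame_stride = frame_stride)
  out
}
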