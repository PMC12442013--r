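# Structural observables: area per lipid, P-P thickness, lateral
# mass-density profiles with block-average errors, inner-region water
# counts, and per-leaflet 2D density maps.

#' Area per lipid
#'
#' Per frame, the x-y box area divided by the number of lipids in one
#' leaflet, reported in Angstrom^2.  With unequal leaflet occupancies the
#' two per-leaflet values are averaged (and a message records it).
#'
#' @param traj `membrane_trajectory`
#' @param leaflets [assign_leaflets()] result
#' @return [ts_stat()] in Angstrom^2
#' @export
area_per_lipid <- function(traj, leaflets) {
  cnt <- leaflet_counts(leaflets)
  if (any(cnt == 0)) stop("empty leaflet", call. = FALSE)
  if (cnt["upper"] != cnt["lower"]) {
    message("unequal leaflet occupancy (", cnt["upper"], "/", cnt["lower"],
            "); using the per-leaflet mean")
  }
  area <- traj$box[, 1] * traj$box[, 2]            # nm^2
  vals <- 100 * (area / cnt["upper"] + area / cnt["lower"]) / 2   # A^2
  ts_stat(unname(vals), traj$times, unit = "A^2")
}

#' Bilayer thickness (P-P distance)
#'
#' Per frame, the absolute difference between the mean z of the upper- and
#' lower-leaflet phosphorus atoms.
#'
#' @param traj `membrane_trajectory`
#' @param leaflets [assign_leaflets()] result
#' @return [ts_stat()] in nm
#' @export
bilayer_thickness <- function(traj, leaflets) {
  up <- leaflets$p_atom_index[leaflets$leaflet == "upper"]
  lo <- leaflets$p_atom_index[leaflets$leaflet == "lower"]
  if (!length(up) || !length(lo)) {
    stop("phosphorus atoms missing from a leaflet", call. = FALSE)
  }
  zu <- colMeans(matrix(traj$coords[up, 3, ], nrow = length(up)))
  zl <- colMeans(matrix(traj$coords[lo, 3, ], nrow = length(lo)))
  ts_stat(abs(zu - zl), traj$times, unit = "nm")
}

# Midplane z per frame (mean of all phosphorus z).
midplane_series <- function(traj, leaflets) {
  idx <- leaflets$p_atom_index
  colMeans(matrix(traj$coords[idx, 3, ], nrow = length(idx)))
}

#' Lateral mass-density profile along the bilayer normal
#'
#' Mass histogram along z per atom group (headgroup, glycerol, tails,
#' water, ions) divided by the bin volume `Lx * Ly * dz` and averaged over
#' frames, in kg/m^3.  Frames are re-centered so the phosphorus midplane
#' sits at z = 0 before binning.  Errors are block averages: the profile is
#' recomputed per time block and the block error is the standard deviation
#' (N-1) across blocks.  Lipid hydrogens carry no group label and are
#' therefore excluded from the lipid group masses, which keeps all-atom
#' profiles comparable with united-atom ones.
#'
#' @param traj `membrane_trajectory`
#' @param leaflets [assign_leaflets()] result (used for re-centering)
#' @param bin_width z bin width, nm
#' @param block_length block length for the error estimate, ps
#' @return object of class `density_profile`: data.frame in long format
#'   (`z`, `group`, `density`, `block_error`) with attributes
#'   `box_xy_area` (mean, nm^2), `bin_width`, `n_blocks`
#' @export
lateral_density <- function(traj, leaflets, bin_width = 0.1,
                            block_length = 10000) {
  ids <- block_ids(traj$times, block_length)
  mid <- midplane_series(traj, leaflets)
  Lz <- max(traj$box[, 3])
  edges <- seq(-Lz / 2, Lz / 2 + bin_width, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  groups <- c("headgroup", "glycerol", "tails", "water", "ions")
  grp <- traj$atoms$group
  mass <- traj$atoms$mass
  nf <- n_frames(traj)
  # per-frame mass histograms, accumulated per block
  nb <- max(ids)
  acc <- array(0, dim = c(length(centers), length(groups), nb),
               dimnames = list(NULL, groups, NULL))
  frames_per_block <- tabulate(ids, nb)
  sel_list <- lapply(groups, function(g) which(!is.na(grp) & grp == g))
  names(sel_list) <- groups
  for (f in seq_len(nf)) {
    vol <- traj$box[f, 1] * traj$box[f, 2] * bin_width      # nm^3
    z <- traj$coords[, 3, f] - mid[f]
    z <- min_image(z, traj$box[f, 3])
    bin <- pmin(pmax(floor((z + Lz / 2) / bin_width) + 1L, 1L),
                length(centers))
    for (g in groups) {
      sel <- sel_list[[g]]
      if (!length(sel)) next
      h <- unname(rowsum(mass[sel], bin[sel]))
      at <- sort(unique(bin[sel]))
      # kg/m^3 = (mass in u * amu_kg) / (vol in nm^3 * 1e-27 m^3/nm^3)
      acc[at, g, ids[f]] <- acc[at, g, ids[f]] +
        h[, 1] * bilayer_constants$amu_kg / (vol * 1e-27)
    }
  }
  per_block <- sweep(acc, 3, frames_per_block, "/")
  mean_prof <- apply(per_block, c(1, 2), stats::weighted.mean,
                     w = frames_per_block)
  err_prof <- apply(per_block, c(1, 2), stats::sd)
  out <- data.frame(
    z = rep(centers, times = length(groups)),
    group = rep(groups, each = length(centers)),
    density = as.vector(mean_prof),
    block_error = as.vector(err_prof),
    stringsAsFactors = FALSE
  )
  attr(out, "box_xy_area") <- mean(traj$box[, 1] * traj$box[, 2])
  attr(out, "bin_width") <- bin_width
  attr(out, "n_blocks") <- nb
  attr(out, "n_lipids") <- length(unique(
    traj$atoms$residue_index[traj$atoms$role %in% "lipid"]))
  class(out) <- c("density_profile", "data.frame")
  out
}

# 3-bin moving average (ends handled by shrinking the window).
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out[1] <- mean(x[1:2]); out[n] <- mean(x[(n - 1):n])
  out
}

#' Water count in the bilayer's inner region
#'
#' Locates the two glycerol density peaks (one on each side of z = 0,
#' after a 3-bin moving-average smoothing), converts the water mass
#' density to molecules per nm of z, integrates it between the peaks with
#' the trapezoid rule, and divides by the total lipid count.
#'
#' @param profile a [lateral_density()] result
#' @param n_lipids total lipid count (default: taken from the profile)
#' @return list with `waters_per_lipid`, `n_waters` (the integral),
#'   `peak_z` (the two glycerol peak positions, nm)
#' @export
inner_water_count <- function(profile, n_lipids = attr(profile, "n_lipids")) {
  gly <- profile[profile$group == "glycerol", ]
  wat <- profile[profile$group == "water", ]
  if (!nrow(gly) || !any(gly$density > 0)) {
    stop("peak detection failed: no glycerol density in the profile",
         call. = FALSE)
  }
  sm <- smooth3(gly$density)
  neg <- gly$z < 0; pos <- gly$z > 0
  if (!any(sm[neg] > 0) || !any(sm[pos] > 0)) {
    stop("peak detection failed: need one glycerol peak on each side of ",
         "z = 0 (found densities only on one side)", call. = FALSE)
  }
  z1 <- gly$z[neg][which.max(sm[neg])]
  z2 <- gly$z[pos][which.max(sm[pos])]
  inside <- wat$z >= z1 & wat$z <= z2
  if (sum(inside) < 2) {
    return(list(waters_per_lipid = 0, n_waters = 0, peak_z = c(z1, z2)))
  }
  A <- attr(profile, "box_xy_area")                      # nm^2
  # molecules per nm of z: rho[kg/m^3] * A[nm^2] * 1e-27 / m_water[kg]
  m_w <- bilayer_constants$m_water_amu * bilayer_constants$amu_kg
  rho_n <- wat$density[inside] * A * 1e-27 / m_w
  zz <- wat$z[inside]
  n_waters <- sum(diff(zz) * (rho_n[-1] + rho_n[-length(rho_n)]) / 2)
  list(waters_per_lipid = n_waters / n_lipids, n_waters = n_waters,
       peak_z = c(z1, z2))
}

#' Per-leaflet 2D density map
#'
#' x-y histogram of one species' atoms (by default its phosphorus atoms)
#' in one leaflet, computed per time interval and averaged, on a fixed
#' 0.1 x 0.1 nm^2 grid.  Units are counts/nm^2 or kg/m^3 assuming a slab
#' thickness of one leaflet (configurable via `units`).
#'
#' @param traj `membrane_trajectory`
#' @param leaflets [assign_leaflets()] result
#' @param species lipid species name
#' @param leaflet `"upper"` or `"lower"`
#' @param atoms `"phosphorus"` (default) or `"all"` (all atoms of the
#'   species' residues in that leaflet)
#' @param bin_width bin width, nm (0.1 by default, both axes)
#' @param interval averaging interval, ps
#' @param units `"counts_nm2"` (counts/nm^2) only at present
#' @return object of class `density_map_2d`: matrix of mean densities with
#'   attributes `x_centers`, `y_centers`, `bin_width`
#' @export
density_map_2d <- function(traj, leaflets, species, leaflet = "upper",
                           atoms = c("phosphorus", "all"), bin_width = 0.1,
                           interval = 10000, units = "counts_nm2") {
  atoms <- match.arg(atoms)
  res_sel <- leaflets$residue_index[leaflets$leaflet == leaflet &
                                      leaflets$species == species]
  if (!length(res_sel)) stop("empty selection: no ", species, " in the ",
                             leaflet, " leaflet", call. = FALSE)
  if (atoms == "phosphorus") {
    idx <- leaflets$p_atom_index[leaflets$leaflet == leaflet &
                                   leaflets$species == species]
  } else {
    idx <- which(traj$atoms$residue_index %in% res_sel &
                   traj$atoms$residue_name == species)
  }
  L <- max(traj$box[, 1:2])
  nbin <- ceiling(L / bin_width)
  span <- max(traj$times) - min(traj$times)
  ids <- if (span >= 2 * interval) block_ids(traj$times, interval) else
    rep(1L, n_frames(traj))
  nb <- max(ids)
  acc <- matrix(0, nbin, nbin)
  counts <- matrix(0, nbin, nbin)
  per_int <- array(0, dim = c(nbin, nbin, nb))
  for (f in seq_len(n_frames(traj))) {
    x <- traj$coords[idx, 1, f] %% traj$box[f, 1]
    y <- traj$coords[idx, 2, f] %% traj$box[f, 2]
    bx <- pmin(floor(x / bin_width) + 1L, nbin)
    by <- pmin(floor(y / bin_width) + 1L, nbin)
    tab <- table(factor(bx, levels = seq_len(nbin)),
                 factor(by, levels = seq_len(nbin)))
    per_int[, , ids[f]] <- per_int[, , ids[f]] + unclass(tab)
  }
  frames_per_int <- tabulate(ids, nb)
  for (b in seq_len(nb)) per_int[, , b] <- per_int[, , b] / frames_per_int[b]
  dens <- apply(per_int, c(1, 2), stats::weighted.mean, w = frames_per_int) /
    bin_width^2
  attr(dens, "x_centers") <- (seq_len(nbin) - 0.5) * bin_width
  attr(dens, "y_centers") <- (seq_len(nbin) - 0.5) * bin_width
  attr(dens, "bin_width") <- bin_width
  attr(dens, "units") <- units
  class(dens) <- c("density_map_2d", class(dens))
  dens
}
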