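# Synthetic bilayer generator.
#
# Builds idealized planar-bilayer trajectories whose every observable is
# prescribed, so the analysis pipeline can be validated by round-trip
# recovery: lipids on a per-leaflet square lattice at a prescribed area per
# lipid, phosphorus planes a prescribed distance apart (small Gaussian
# jitter, sd 0.05 nm), a glycerol band offset toward the midplane, tail
# carbons below the glycerol, C-H hydrogens drawn from prescribed
# tilt-angle models, an exact count of water molecules uniformly placed
# between the glycerol bands plus a bulk slab outside the headgroups,
# lateral motion as a 2D Gaussian random walk with prescribed D, and
# frame-wise box areas drawn i.i.d. Gaussian with the variance implied by a
# prescribed area compressibility modulus.  There is no force field and no
# Hamiltonian: the construction is geometric.

.P_JITTER_SD <- 0.05    # nm; per-lipid per-frame rigid z jitter
.CH_BOND_NM <- 0.109
.OH_BOND_NM <- 0.09572
.HOH_ANGLE_DEG <- 104.52

#' Specification for a synthetic bilayer
#'
#' The defaults describe the reference validation system: one species, 100
#' lipids per leaflet at 0.625 nm^2 per lipid, phosphate planes 4 nm
#' apart, 0.8 inner waters per lipid, fixed C-H tilt angles per carbon,
#' D = 0.01 nm^2/ns, K_A = 300 mN/m at 310 K, 500 frames spaced 100 ps.
#'
#' @param species data.frame with columns `name`, `n_upper`, `n_lower`
#' @param area_per_lipid nm^2
#' @param leaflet_P_separation nm, distance between the mean P planes
#' @param glycerol_offset nm, distance of the glycerol band below the P
#'   plane (toward the midplane)
#' @param n_waters_inner_per_lipid waters per lipid placed uniformly
#'   between the glycerol bands
#' @param n_waters_bulk_per_lipid waters per lipid in the bulk slab outside
#'   the headgroups
#' @param ch_theta_model named list: carbon label -> `list(type = "fixed",
#'   theta_deg = ...)` or `list(type = "isotropic")`; `NULL` uses a default
#'   profile of fixed angles over the synthetic species' labels
#' @param D_lateral named numeric, nm^2/ns per species (recycled if
#'   unnamed scalar)
#' @param K_A area compressibility modulus, mN/m
#' @param temperature K
#' @param n_frames,frame_dt frame count and spacing (ps)
#' @param n_tail_carbons tail carbons with C-H pairs per chain
#' @param seed integer RNG seed; all sub-generators derive from it
#' @return object of class `synthetic_spec`
#' @export
synthetic_bilayer_spec <- function(species = data.frame(name = "SYN",
                                                        n_upper = 100L,
                                                        n_lower = 100L),
                                   area_per_lipid = 0.625,
                                   leaflet_P_separation = 4.0,
                                   glycerol_offset = 0.5,
                                   n_waters_inner_per_lipid = 0.8,
                                   n_waters_bulk_per_lipid = 3,
                                   ch_theta_model = NULL,
                                   D_lateral = 0.01,
                                   K_A = 300,
                                   temperature = 310,
                                   n_frames = 500L,
                                   frame_dt = 100,
                                   n_tail_carbons = 4L,
                                   seed = 1L) {
  stopifnot(area_per_lipid > 0, leaflet_P_separation > 0,
            glycerol_offset > 0, glycerol_offset < leaflet_P_separation / 2,
            n_waters_inner_per_lipid >= 0, n_waters_bulk_per_lipid >= 0,
            all(D_lateral >= 0), K_A > 0, temperature > 0,
            n_frames >= 1, frame_dt > 0, n_tail_carbons >= 1)
  if (is.null(names(D_lateral))) {
    D_lateral <- stats::setNames(rep(D_lateral, nrow(species)),
                                 species$name)
  }
  spec <- list(species = species, area_per_lipid = area_per_lipid,
               leaflet_P_separation = leaflet_P_separation,
               glycerol_offset = glycerol_offset,
               n_waters_inner_per_lipid = n_waters_inner_per_lipid,
               n_waters_bulk_per_lipid = n_waters_bulk_per_lipid,
               ch_theta_model = ch_theta_model,
               D_lateral = D_lateral, K_A = K_A,
               temperature = temperature,
               n_frames = as.integer(n_frames), frame_dt = frame_dt,
               n_tail_carbons = as.integer(n_tail_carbons),
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

# Build the lipid_spec and the internal geometry template of a synthetic
# species.  The template gives, per atom, its fixed offset from the lipid's
# phosphorus reference: dz_in (nm, positive toward the bilayer midplane)
# and lateral (dx, dy).
synthetic_species_template <- function(name = "SYN", n_tail_carbons = 4L,
                                       glycerol_offset = 0.5) {
  gz <- glycerol_offset
  heavy <- list(
    list("N",   "headgroup", -0.35,  0.10,  0.00),
    list("C12", "headgroup", -0.25,  0.05,  0.10),
    list("C11", "headgroup", -0.15, -0.05,  0.08),
    list("O12", "headgroup", -0.08, -0.08, -0.05),
    list("O13", "headgroup", -0.05,  0.12, -0.06),
    list("O14", "headgroup", -0.05, -0.12,  0.06),
    list("P",   "headgroup",  0.00,  0.00,  0.00),
    list("O11", "glycerol",  gz - 0.03,  0.06,  0.02),
    list("C1",  "glycerol",  gz - 0.01,  0.00,  0.08),
    list("C2",  "glycerol",  gz + 0.00,  0.05, -0.04),
    list("C3",  "glycerol",  gz + 0.01, -0.06, -0.03),
    list("O21", "glycerol",  gz + 0.03,  0.10,  0.05),
    list("O31", "glycerol",  gz + 0.03, -0.10, -0.06),
    list("C21", "tails",     gz + 0.12,  0.12,  0.06),
    list("O22", "tails",     gz + 0.10,  0.18,  0.10),
    list("C31", "tails",     gz + 0.12, -0.12, -0.07),
    list("O32", "tails",     gz + 0.10, -0.18, -0.11)
  )
  ch_pairs <- list()
  segments <- c()
  # headgroup C-H label
  ch_pairs[["C12"]] <- list(c("C12", "H12A"), c("C12", "H12B"))
  segments["C12"] <- "headgroup"
  for (k in seq_len(n_tail_carbons) + 1L) {
    c2 <- sprintf("C2%d", k); c3 <- sprintf("C3%d", k)
    heavy[[length(heavy) + 1L]] <-
      list(c2, "tails", gz + 0.12 + 0.127 * (k - 1), 0.12, 0.06)
    heavy[[length(heavy) + 1L]] <-
      list(c3, "tails", gz + 0.12 + 0.127 * (k - 1), -0.12, -0.07)
    ch_pairs[[c2]] <- list(c(c2, sprintf("H%dR", k)),
                           c(c2, sprintf("H%dS", k)))
    ch_pairs[[c3]] <- list(c(c3, sprintf("H%dX", k)),
                           c(c3, sprintf("H%dY", k)))
    segments[c2] <- "sn-2"; segments[c3] <- "sn-1"
  }
  heavy_df <- data.frame(
    atom_name = vapply(heavy, `[[`, character(1), 1),
    group = vapply(heavy, `[[`, character(1), 2),
    dz_in = vapply(heavy, `[[`, numeric(1), 3),
    dx = vapply(heavy, `[[`, numeric(1), 4),
    dy = vapply(heavy, `[[`, numeric(1), 5),
    stringsAsFactors = FALSE
  )
  groups <- split(heavy_df$atom_name, heavy_df$group)
  spec <- lipid_spec(
    species = name,
    groups = list(headgroup = groups$headgroup, glycerol = groups$glycerol,
                  tails = groups$tails),
    phosphorus_atom = "P",
    po4_atoms = c("P", "O11", "O12", "O13", "O14"),
    ch_pairs = ch_pairs,
    hbond_atoms = c(
      stats::setNames(lapply(c("O13", "O14"), function(a)
        list(role = "acceptor", capacity = 3L)), c("O13", "O14")),
      stats::setNames(lapply(c("O11", "O12", "O21", "O31", "O22", "O32"),
                             function(a) list(role = "acceptor",
                                              capacity = 2L)),
                      c("O11", "O12", "O21", "O31", "O22", "O32"))
    ),
    segments = segments
  )
  # hydrogen atoms of the C-H pairs, attached to their carbon's template row
  hyd <- do.call(rbind, lapply(names(ch_pairs), function(lbl) {
    do.call(rbind, lapply(ch_pairs[[lbl]], function(p) {
      data.frame(atom_name = p[2], carbon = p[1], label = lbl,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(spec = spec, heavy = heavy_df, hydrogens = hyd)
}

# Default C-H tilt model: fixed angles, distinct per label, so the S_CH
# profile is non-trivial and exactly known.
default_ch_theta_model <- function(labels, segments) {
  out <- list()
  k2 <- 0; k3 <- 0
  for (lbl in labels) {
    seg <- segments[[lbl]]
    theta <- if (identical(seg, "headgroup")) {
      80
    } else if (identical(seg, "sn-2")) {
      k2 <- k2 + 1; 34 + 3 * k2
    } else {
      k3 <- k3 + 1; 30 + 3 * k3
    }
    out[[lbl]] <- list(type = "fixed", theta_deg = theta)
  }
  out
}

# Closed-form S_CH of a tilt model: fixed theta -> (3 cos^2 theta - 1)/2,
# isotropic -> 0.
model_sch <- function(model) {
  if (model$type == "fixed") {
    c2 <- cos(model$theta_deg * pi / 180)^2
    (3 * c2 - 1) / 2
  } else if (model$type == "isotropic") {
    0
  } else {
    stop("unknown ch_theta_model type: ", model$type, call. = FALSE)
  }
}

#' Draw C-H bond orientations from a tilt model
#'
#' @param theta_model `list(type = "fixed", theta_deg = ...)` or
#'   `list(type = "isotropic")`; the polar angle is measured from +z,
#'   azimuth uniform
#' @param n_samples number of unit vectors
#' @param seed optional integer seed (uses the current RNG state if NULL)
#' @return `n_samples x 3` matrix of unit vectors
#' @export
generate_ch_orientations <- function(theta_model, n_samples, seed = NULL) {
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  phi <- stats::runif(n_samples, 0, 2 * pi)
  cos_t <- if (theta_model$type == "fixed") {
    rep(cos(theta_model$theta_deg * pi / 180), n_samples)
  } else if (theta_model$type == "isotropic") {
    stats::runif(n_samples, -1, 1)
  } else {
    stop("unknown ch_theta_model type: ", theta_model$type, call. = FALSE)
  }
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  cbind(sin_t * cos(phi), sin_t * sin(phi), cos_t)
}

#' Generate 2D Gaussian random walks
#'
#' Per-axis increments are i.i.d. Gaussian with variance `2 * D * dt`, so
#' the expected squared lateral displacement after time t is `4 * D * t`.
#'
#' @param D diffusion coefficient, nm^2/ns
#' @param dt step duration, ns
#' @param n_steps number of steps
#' @param n_particles number of independent walkers
#' @param seed optional integer seed
#' @return array `[n_particles, 2, n_steps + 1]` of positions starting at
#'   the origin, nm
#' @export
generate_random_walk_2d <- function(D, dt, n_steps, n_particles,
                                    seed = NULL) {
  stopifnot(D >= 0, dt > 0, n_steps >= 1, n_particles >= 1)
  if (!is.null(seed)) set.seed(seed)
  sd_step <- sqrt(2 * D * dt)
  inc <- array(stats::rnorm(n_particles * 2 * n_steps, 0, sd_step),
               dim = c(n_particles, 2, n_steps))
  out <- array(0, dim = c(n_particles, 2, n_steps + 1))
  for (s in seq_len(n_steps)) out[, , s + 1] <- out[, , s] + inc[, , s]
  out
}

#' Generate a fluctuating box-area series
#'
#' i.i.d. Gaussian areas with mean `mean_area` and the variance implied by
#' the area-fluctuation (Feller-Pastor) relation
#' `Var(A) = kB * T * mean_area / K_A` (with 1 mN/m = 1 zJ/nm^2 the
#' variance comes out in nm^4).
#'
#' @param mean_area nm^2
#' @param K_A mN/m (may be `Inf` for a rigid box)
#' @param T_K temperature, K
#' @param n_samples series length
#' @param seed optional integer seed
#' @return numeric vector of areas, nm^2
#' @export
generate_area_series <- function(mean_area, K_A, T_K, n_samples,
                                 seed = NULL) {
  stopifnot(mean_area > 0, K_A > 0, T_K > 0, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- bilayer_constants$kB_zJ_per_K * T_K * mean_area / K_A
  stats::rnorm(n_samples, mean_area, sqrt(v))
}

#' Generate a synthetic bilayer trajectory with its ground-truth manifest
#'
#' @param spec [synthetic_bilayer_spec()]
#' @return list with elements `trajectory` (`membrane_trajectory`) and
#'   `manifest` (class `synthetic_manifest`): the prescribed area per lipid
#'   (nm^2), P-P thickness (nm), inner water count per lipid, S_CH per
#'   species and carbon label, D per species (nm^2/ns), K_A (mN/m), and
#'   the per-lipid leaflet labels
#' @export
generate_bilayer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sp_tab <- spec$species
  n_lipids <- sum(sp_tab$n_upper) + sum(sp_tab$n_lower)
  if (n_lipids < 2) stop("need at least 2 lipids", call. = FALSE)

  # lattice geometry: box area = area_per_lipid * mean leaflet count
  n_u <- sum(sp_tab$n_upper); n_l <- sum(sp_tab$n_lower)
  A0 <- spec$area_per_lipid * mean(c(n_u, n_l))
  L0 <- sqrt(A0)
  n_side_u <- ceiling(sqrt(n_u)); n_side_l <- ceiling(sqrt(n_l))
  if (L0 / max(n_side_u, n_side_l) < 0.3) {
    stop("packing error: lattice spacing below 0.3 nm; increase ",
         "area_per_lipid or reduce lipid counts", call. = FALSE)
  }
  sep <- spec$leaflet_P_separation
  gz <- sep / 2 - spec$glycerol_offset   # glycerol band |z| from midplane
  Lz <- sep + 5.0
  z0 <- Lz / 2

  # per-species templates and the assembled topology
  tmpl <- lapply(seq_len(nrow(sp_tab)), function(i)
    synthetic_species_template(sp_tab$name[i], spec$n_tail_carbons,
                               spec$glycerol_offset))
  names(tmpl) <- sp_tab$name
  specs <- lapply(tmpl, `[[`, "spec")
  theta_model <- spec$ch_theta_model
  if (is.null(theta_model)) {
    lbls <- names(specs[[1]]$ch_pairs)
    theta_model <- default_ch_theta_model(lbls, specs[[1]]$segments)
  }

  # lipid bookkeeping: upper leaflet residues first, then lower
  lip <- data.frame(
    residue_index = seq_len(n_lipids),
    species = c(rep(sp_tab$name, sp_tab$n_upper),
                rep(sp_tab$name, sp_tab$n_lower)),
    leaflet = c(rep("upper", n_u), rep("lower", n_l)),
    stringsAsFactors = FALSE
  )

  # topology rows: lipid atoms (heavy then C-H hydrogens, per lipid), waters
  atom_rows <- vector("list", n_lipids)
  for (i in seq_len(n_lipids)) {
    tp <- tmpl[[lip$species[i]]]
    nm <- c(tp$heavy$atom_name, tp$hydrogens$atom_name)
    atom_rows[[i]] <- data.frame(atom_name = nm,
                                 residue_index = i,
                                 residue_name = lip$species[i],
                                 stringsAsFactors = FALSE)
  }
  n_inner <- as.integer(round(spec$n_waters_inner_per_lipid * n_lipids))
  n_bulk <- as.integer(round(spec$n_waters_bulk_per_lipid * n_lipids))
  n_waters <- n_inner + n_bulk
  if (n_waters > 0) {
    wat <- data.frame(
      atom_name = rep(c("OW", "HW1", "HW2"), n_waters),
      residue_index = n_lipids + rep(seq_len(n_waters), each = 3),
      residue_name = "SOL",
      stringsAsFactors = FALSE
    )
    atoms <- rbind(do.call(rbind, atom_rows), wat)
  } else {
    atoms <- do.call(rbind, atom_rows)
  }
  atoms <- classify_atoms(atoms, specs, .default_water_resnames,
                          .default_ion_resnames)
  n_atoms <- nrow(atoms)

  # static per-lipid structure indices
  lip_start <- cumsum(c(0, vapply(atom_rows, nrow, integer(1))))[
    seq_len(n_lipids)]
  # lattice sites per leaflet
  site_xy <- function(n, n_side, L) {
    cell <- L / n_side
    idx <- seq_len(n) - 1L
    cbind((idx %% n_side + 0.5) * cell,
          (idx %/% n_side + 0.5) * cell)
  }
  lattice0 <- rbind(site_xy(n_u, n_side_u, L0), site_xy(n_l, n_side_l, L0))

  # sub-generators derived from the one named seed
  area_seed <- spec$seed + 1L
  walk_seed <- spec$seed + 2L
  frame_seed <- spec$seed + 3L

  dt_ns <- spec$frame_dt / 1000
  areas <- generate_area_series(A0, spec$K_A, spec$temperature,
                                spec$n_frames, seed = area_seed)
  if (spec$n_frames > 2) {
    # standardize the draw so the emitted series carries the prescribed
    # mean and (N-1) variance exactly: the manifest K_A is then a property
    # of the trajectory itself, not of the finite draw
    v_target <- bilayer_constants$kB_zJ_per_K * spec$temperature * A0 /
      spec$K_A
    areas <- A0 + (areas - mean(areas)) * sqrt(v_target / stats::var(areas))
  }
  areas[areas <= 0] <- A0   # guard; unreachable for physical K_A
  # random walks per species (one stream, species in table order)
  set.seed(walk_seed)
  walk <- array(0, dim = c(n_lipids, 2, spec$n_frames))
  if (spec$n_frames > 1) {
    for (sp in sp_tab$name) {
      rows <- which(lip$species == sp)
      w <- generate_random_walk_2d(spec$D_lateral[[sp]], dt_ns,
                                   spec$n_frames - 1L, length(rows))
      walk[rows, , ] <- w
    }
  }

  coords <- array(NA_real_, dim = c(n_atoms, 3, spec$n_frames))
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_dt
  box <- cbind(sqrt(areas), sqrt(areas), Lz)

  # flatten the per-lipid templates into global index/offset vectors so the
  # frame loop is fully vectorized
  hv_idx <- integer(0); hv_lip <- integer(0)
  hv_dx <- hv_dy <- hv_dz <- numeric(0)
  hy_idx <- integer(0); hy_cidx <- integer(0); hy_lbl <- character(0)
  for (i in seq_len(n_lipids)) {
    tp <- tmpl[[lip$species[i]]]
    nh <- nrow(tp$heavy)
    rows <- lip_start[i] + seq_len(nh)
    hv_idx <- c(hv_idx, rows)
    hv_lip <- c(hv_lip, rep(i, nh))
    hv_dx <- c(hv_dx, tp$heavy$dx); hv_dy <- c(hv_dy, tp$heavy$dy)
    hv_dz <- c(hv_dz, tp$heavy$dz_in)
    hrows <- lip_start[i] + nh + seq_len(nrow(tp$hydrogens))
    hy_idx <- c(hy_idx, hrows)
    hy_cidx <- c(hy_cidx, rows[match(tp$hydrogens$carbon,
                                     tp$heavy$atom_name)])
    hy_lbl <- c(hy_lbl, tp$hydrogens$label)
  }
  n_hyd <- length(hy_idx)
  hy_fixed_cos <- rep(NA_real_, n_hyd)   # NA marks isotropic labels
  for (lbl in unique(hy_lbl)) {
    m <- theta_model[[lbl]]
    if (m$type == "fixed") {
      hy_fixed_cos[hy_lbl == lbl] <- cos(m$theta_deg * pi / 180)
    }
  }

  set.seed(frame_seed)
  sgn <- ifelse(lip$leaflet == "upper", 1, -1)   # +1: P plane above midplane
  for (f in seq_len(spec$n_frames)) {
    s_f <- sqrt(areas[f] / A0)
    L_f <- box[f, 1]
    ref_xy <- (lattice0 + walk[, , f]) * s_f
    ref_xy <- ref_xy %% L_f
    z_jit <- stats::rnorm(n_lipids, 0, .P_JITTER_SD)
    z_P <- z0 + sgn * sep / 2 + z_jit
    fc <- matrix(NA_real_, n_atoms, 3)
    # heavy atoms: lattice reference + template offsets; dz_in points toward
    # the midplane (subtract for upper leaflet, add for lower)
    fc[hv_idx, 1] <- ref_xy[hv_lip, 1] + hv_dx
    fc[hv_idx, 2] <- ref_xy[hv_lip, 2] + hv_dy
    fc[hv_idx, 3] <- z_P[hv_lip] - sgn[hv_lip] * hv_dz
    # hydrogens: carbon position + bond vector from the tilt model
    phi <- stats::runif(n_hyd, 0, 2 * pi)
    cos_t <- hy_fixed_cos
    iso <- is.na(cos_t)
    if (any(iso)) cos_t[iso] <- stats::runif(sum(iso), -1, 1)
    sin_t <- sqrt(pmax(0, 1 - cos_t^2))
    u <- cbind(sin_t * cos(phi), sin_t * sin(phi), cos_t)
    fc[hy_idx, ] <- fc[hy_cidx, , drop = FALSE] + .CH_BOND_NM * u
    if (n_waters > 0) {
      z_w <- c(
        if (n_inner > 0) stats::runif(n_inner, z0 - gz, z0 + gz),
        if (n_bulk > 0) {
          lo <- stats::runif(n_bulk) < 0.5
          ifelse(lo, stats::runif(n_bulk, 0.2, z0 - sep / 2 - 0.85),
                 stats::runif(n_bulk, z0 + sep / 2 + 0.85, Lz - 0.2))
        }
      )
      o_xy <- cbind(stats::runif(n_waters, 0, L_f),
                    stats::runif(n_waters, 0, L_f))
      wrows <- nrow(atoms) - 3 * n_waters + seq_len(3 * n_waters)
      o_rows <- wrows[seq(1, length(wrows), by = 3)]
      fc[o_rows, ] <- cbind(o_xy, z_w)
      # two O-H bonds at the water geometry, random orientation
      e1 <- generate_ch_orientations(list(type = "isotropic"), n_waters)
      raw <- generate_ch_orientations(list(type = "isotropic"), n_waters)
      e2 <- raw - rowSums(raw * e1) * e1
      e2 <- e2 / sqrt(rowSums(e2^2))
      ang <- .HOH_ANGLE_DEG * pi / 180
      fc[o_rows + 1L, ] <- fc[o_rows, ] + .OH_BOND_NM * e1
      fc[o_rows + 2L, ] <- fc[o_rows, ] +
        .OH_BOND_NM * (cos(ang) * e1 + sin(ang) * e2)
    }
    coords[, , f] <- fc
  }

  traj <- membrane_trajectory(atoms, coords, times, box, specs)

  sch <- lapply(specs, function(s) {
    vapply(names(s$ch_pairs), function(lbl) model_sch(theta_model[[lbl]]),
           numeric(1))
  })
  manifest <- structure(list(
    area_per_lipid = mean(c(A0 / n_u, A0 / n_l)),
    box_area = A0,
    thickness = sep,
    inner_waters_per_lipid = n_inner / n_lipids,
    n_inner_waters = n_inner,
    sch = sch,
    ch_theta_model = theta_model,
    D_lateral = spec$D_lateral,
    K_A = spec$K_A,
    temperature = spec$temperature,
    leaflets = lip[, c("residue_index", "species", "leaflet")],
    seed = spec$seed,
    n_frames = spec$n_frames,
    frame_dt = spec$frame_dt
  ), class = "synthetic_manifest")

  list(trajectory = traj, manifest = manifest)
}

#' Write a synthetic system to disk
#'
#' Emits a GRO file of the first frame (topology), a DCD trajectory, one
#' YAML lipid spec per species, and the ground-truth manifest as JSON, so
#' the pipeline can be exercised end-to-end through real file I/O.
#'
#' @param sim result of [generate_bilayer()]
#' @param dir output directory (created if needed)
#' @param stem filename stem
#' @return named list of the paths written
#' @export
write_synthetic_system <- function(sim, dir, stem = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj <- sim$trajectory
  paths <- list(
    topology = file.path(dir, paste0(stem, ".gro")),
    trajectory = file.path(dir, paste0(stem, ".dcd")),
    manifest = file.path(dir, paste0(stem, "_manifest.json"))
  )
  write_gro(traj, paths$topology, frames = 1L, title = "synthetic bilayer")
  write_dcd(traj, paths$trajectory)
  m <- unclass(sim$manifest)
  m$leaflets <- as.list(m$leaflets)
  jsonlite::write_json(m, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (sp in names(traj$specs)) {
    p <- file.path(dir, paste0(stem, "_", tolower(sp), ".yaml"))
    write_lipid_spec(traj$specs[[sp]], p)
    paths[[paste0("spec_", sp)]] <- p
  }
  paths
}
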