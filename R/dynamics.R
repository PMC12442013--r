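# Lateral dynamics and mechanics: displacement distributions, diffusion
# coefficients from the 2D random-walk relation <r^2> = 4 D t, and the
# area compressibility modulus from box-area fluctuations,
# K_A = kB T <A> / <(A - <A>)^2>.

# Unwrapped lateral positions of each lipid's phosphorus atom:
# array [n_lipids, 2, n_frames].  Unwrapping is done in box-relative
# (fractional) coordinates and rescaled by the mean box edge, which
# removes affine box-fluctuation (barostat-like) motion from the
# displacement signal.  Assumes per-frame displacements below half a box
# edge per axis; warns otherwise.
unwrap_lateral <- function(traj, leaflets) {
  idx <- leaflets$p_atom_index
  nl <- length(idx)
  nf <- n_frames(traj)
  pos <- array(NA_real_, dim = c(nl, 2, nf))
  L_ref <- colMeans(traj$box[, 1:2, drop = FALSE])
  frac_prev <- sweep(matrix(traj$coords[idx, 1:2, 1], nrow = nl), 2,
                     traj$box[1, 1:2], "/")
  pos[, , 1] <- sweep(frac_prev, 2, L_ref, "*")
  if (nf > 1) {
    warned <- FALSE
    for (f in 2:nf) {
      frac <- sweep(matrix(traj$coords[idx, 1:2, f], nrow = nl), 2,
                    traj$box[f, 1:2], "/")
      d <- min_image(frac - frac_prev, 1)
      if (!warned && any(abs(d) > 0.45)) {
        warning("per-frame displacements approach half the box edge; ",
                "frame spacing may be too coarse for reliable unwrapping")
        warned <- TRUE
      }
      frac_prev <- frac_prev + d
      pos[, , f] <- sweep(frac_prev, 2, L_ref, "*")
    }
  }
  pos
}

#' Lateral displacement distribution
#'
#' Tracks each lipid's phosphorus atom, unwraps its lateral coordinates
#' across periodic images, subtracts the per-leaflet center-of-mass drift,
#' and collects displacement magnitudes `r = |delta xy|` over (by default
#' maximally overlapping) time origins for a given window.  The histogram
#' is normalized to a probability density.
#'
#' @param traj `membrane_trajectory`
#' @param leaflets [assign_leaflets()] result
#' @param window window length, ns
#' @param species restrict to one species (default: all lipids)
#' @param origin_stride stride between time origins, frames (default 1:
#'   every frame)
#' @param bin_width histogram bin width, nm
#' @return object of class `displacement_distribution`: data.frame (`r`,
#'   `density`) with attributes `window_ns`, `r_samples` (the raw
#'   displacement magnitudes), `species`
#' @export
lateral_displacements <- function(traj, leaflets, window, species = NULL,
                                  origin_stride = 1L, bin_width = 0.05) {
  window_ps <- window * 1000
  span <- max(traj$times) - min(traj$times)
  if (window_ps > span) {
    stop("window (", window, " ns) exceeds the trajectory span (",
         span / 1000, " ns)", call. = FALSE)
  }
  pos <- unwrap_lateral(traj, leaflets)
  # per-leaflet center-of-mass drift subtraction
  for (lf in c("upper", "lower")) {
    rows <- which(leaflets$leaflet == lf)
    if (!length(rows)) next
    com <- apply(pos[rows, , , drop = FALSE], c(2, 3), mean)
    for (ax in 1:2) {
      pos[rows, ax, ] <- pos[rows, ax, ] -
        matrix(com[ax, ], length(rows), dim(pos)[3], byrow = TRUE)
    }
  }
  keep <- if (is.null(species)) seq_len(nrow(leaflets)) else
    which(leaflets$species == species)
  if (!length(keep)) stop("no lipids selected", call. = FALSE)
  dt <- diff(traj$times)[1]
  lag <- as.integer(round(window_ps / dt))
  if (lag < 1 || lag >= n_frames(traj)) {
    stop("window does not fit the frame spacing", call. = FALSE)
  }
  origins <- seq(1L, n_frames(traj) - lag, by = origin_stride)
  dx <- pos[keep, 1, origins + lag, drop = FALSE] -
    pos[keep, 1, origins, drop = FALSE]
  dy <- pos[keep, 2, origins + lag, drop = FALSE] -
    pos[keep, 2, origins, drop = FALSE]
  r <- sqrt(as.vector(dx)^2 + as.vector(dy)^2)
  edges <- seq(0, max(r) + bin_width, by = bin_width)
  h <- graphics::hist(r, breaks = edges, plot = FALSE)
  out <- data.frame(r = h$mids, density = h$density)
  attr(out, "window_ns") <- window
  attr(out, "r_samples") <- r
  attr(out, "species") <- species
  class(out) <- c("displacement_distribution", "data.frame")
  out
}

#' Diffusion coefficient from lateral displacements
#'
#' Two estimators of the 2D random-walk relation are reported: the moment
#' estimator `D = <r^2> / (4 t)`, and a maximum-likelihood fit of the 2D
#' random-walk displacement density `p(r) = r/(2 D t) exp(-r^2/(4 D t))`
#' (solved numerically from the score equation; its closed form coincides
#' with the moment estimator, so the two serve as mutual cross-checks).
#'
#' @param dist a [lateral_displacements()] result, or a numeric vector of
#'   displacement magnitudes (nm)
#' @param window window length in ns (taken from `dist` when it is a
#'   distribution object)
#' @return data.frame (`estimator`, `D_nm2_ns`, `D_cm2_s`) of class
#'   `diffusion_estimate`, attribute `msd` (nm^2)
#' @export
diffusion_from_displacements <- function(dist, window = NULL) {
  r <- if (inherits(dist, "displacement_distribution")) {
    window <- attr(dist, "window_ns"); attr(dist, "r_samples")
  } else as.numeric(dist)
  stopifnot(!is.null(window), window > 0)
  msd <- mean(r^2)
  if (!is.finite(msd) || msd <= 0) {
    stop("non-positive mean squared displacement", call. = FALSE)
  }
  d_msd <- msd / (4 * window)
  # MLE: d/dD log L = -n/D + sum(r^2)/(4 t D^2) = 0
  score <- function(D) -length(r) / D + sum(r^2) / (4 * window * D^2)
  d_mle <- stats::uniroot(score, c(d_msd * 1e-3, d_msd * 1e3),
                          tol = d_msd * 1e-14)$root
  out <- data.frame(estimator = c("msd", "mle"),
                    D_nm2_ns = c(d_msd, d_mle),
                    D_cm2_s = c(d_msd, d_mle) * 1e-5,
                    stringsAsFactors = FALSE)
  attr(out, "msd") <- msd
  attr(out, "window_ns") <- window
  class(out) <- c("diffusion_estimate", "data.frame")
  out
}

#' Area compressibility modulus from box-area fluctuations
#'
#' `K_A = kB T <A> / Var(A)` with the variance under N-1 normalization.
#' With kB T in zJ and areas in nm^2 the result is in mN/m directly
#' (1 mN/m = 1 zJ/nm^2).
#'
#' @param area_series numeric vector of x-y box areas, nm^2 (or a
#'   `membrane_trajectory`, whose per-frame box areas are used)
#' @param T_K temperature, K
#' @return list of class `compressibility_estimate`: `K_A` (mN/m),
#'   `mean_area` (nm^2), `area_variance` (nm^4), `T_K`, `n`
#' @export
area_compressibility <- function(area_series, T_K = 310) {
  if (inherits(area_series, "membrane_trajectory")) {
    area_series <- area_series$box[, 1] * area_series$box[, 2]
  }
  stopifnot(T_K > 0)
  if (length(area_series) < 100) {
    stop("need at least 100 area samples for a fluctuation estimate",
         call. = FALSE)
  }
  v <- stats::var(area_series)
  if (v == 0) {
    stop("zero area variance: K_A is infinite (rigid box?)", call. = FALSE)
  }
  structure(list(
    K_A = bilayer_constants$kB_zJ_per_K * T_K * mean(area_series) / v,
    mean_area = mean(area_series), area_variance = v, T_K = T_K,
    n = length(area_series)
  ), class = "compressibility_estimate")
}

#' @export
print.compressibility_estimate <- function(x, ...) {
  cat(sprintf("<compressibility_estimate> K_A = %.1f mN/m (<A> = %.2f nm^2, Var = %.4g nm^4, T = %g K, n = %d)\n",
              x$K_A, x$mean_area, x$area_variance, x$T_K, x$n))
  invisible(x)
}
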