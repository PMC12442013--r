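# Shared fixtures, built in code at test time.

# A small synthetic bilayer (2 x 16 lipids, 60 frames, 6 ns) for
# module-level tests.
small_bilayer <- function(seed = 42L, n_frames = 60L, ...) {
  spec <- synthetic_bilayer_spec(
    species = data.frame(name = "SYN", n_upper = 16L, n_lower = 16L),
    n_frames = n_frames, frame_dt = 100, seed = seed, ...)
  generate_bilayer(spec)
}

# Minimal hand-built trajectory: a few point atoms with explicit
# coordinates, for arithmetic-level checks.
toy_trajectory <- function(coords, box = c(5, 5, 5), times = NULL,
                           atom_name = NULL, residue_name = "SOL",
                           residue_index = NULL) {
  if (length(dim(coords)) == 2) {
    coords <- array(coords, dim = c(dim(coords), 1))
  }
  n <- dim(coords)[1]
  nf <- dim(coords)[3]
  atoms <- data.frame(
    atom_name = atom_name %||% rep("OW", n),
    residue_index = residue_index %||% seq_len(n),
    residue_name = rep(residue_name, length.out = n),
    stringsAsFactors = FALSE
  )
  atoms$element <- bilayr:::guess_element(atoms$atom_name)
  atoms$mass <- bilayr:::element_mass(atoms$element)
  atoms$role <- "water"
  atoms$group <- "water"
  membrane_trajectory(atoms, coords,
                      times %||% (seq_len(nf) - 1) * 100,
                      matrix(box, nf, 3, byrow = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force O(N^2) RDF oracle on a single frame (unique pairs, minimum
# image), independent of the package implementation.
brute_rdf <- function(X, L, r_max, dr) {
  n <- nrow(X)
  edges <- seq(0, r_max, by = dr)
  h <- numeric(length(edges) - 1)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- X[i, ] - X[j, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (r < r_max) {
        b <- floor(r / dr) + 1
        h[b] <- h[b] + 2   # ordered pairs
      }
    }
  }
  V <- prod(L)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  h / (n * (n - 1) / V * shell)
}

# Brute-force all-pairs H-bond oracle (distance + H-D-A angle criterion).
brute_hbonds <- function(coords, box, donors, acceptors, d_cut = 0.35,
                         angle_cut = 30) {
  out <- NULL
  for (i in seq_len(nrow(donors))) {
    for (a in acceptors) {
      if (a == donors$donor[i]) next
      dv <- coords[a, ] - coords[donors$donor[i], ]
      dv <- dv - box * round(dv / box)
      dist <- sqrt(sum(dv^2))
      if (dist > d_cut) next
      hv <- coords[donors$hydrogen[i], ] - coords[donors$donor[i], ]
      hv <- hv - box * round(hv / box)
      ang <- acos(sum(hv * dv) / (sqrt(sum(hv^2)) * dist)) * 180 / pi
      if (ang <= angle_cut) {
        out <- rbind(out, data.frame(donor = donors$donor[i],
                                     hydrogen = donors$hydrogen[i],
                                     acceptor = a))
      }
    }
  }
  out
}

# Random rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
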