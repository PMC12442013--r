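# RDF, geometric H-bond detection, capacity normalization.

test_that("RDF: two fixed particles give one bin at their separation", {
  spec <- bilayr:::synthetic_species_template("SYN")$spec
  po4 <- c("P", "O11", "O12", "O13", "O14")
  atoms <- data.frame(atom_name = rep("P", 2), residue_index = 1:2,
                      residue_name = "SYN", stringsAsFactors = FALSE)
  atoms$element <- "P"; atoms$mass <- 30.973762
  atoms$role <- "lipid"; atoms$group <- "headgroup"
  coords <- array(rbind(c(1, 1, 1), c(1, 1, 1.73)), c(2, 3, 1))
  tr <- membrane_trajectory(atoms, coords, 0, matrix(c(6, 6, 6), 1),
                            list(SYN = spec))
  r <- rdf_po4(tr, "SYN", r_max = 2.5, dr = 0.02)
  nz <- which(r$g > 0)
  expect_length(nz, 1)
  expect_equal(r$r[nz], 0.73, tolerance = 0.011)
  expect_error(rdf_po4(tr, "SYN", r_max = 4), "half the smallest")
})

test_that("RDF matches the brute-force O(N^2) oracle to 1e-12", {
  set.seed(7)
  n <- 200
  L <- c(8, 8, 8)
  X <- cbind(runif(n, 0, 8), runif(n, 0, 8), runif(n, 0, 8))
  spec <- bilayr:::synthetic_species_template("SYN")$spec
  atoms <- data.frame(atom_name = rep("P", n), residue_index = 1:n,
                      residue_name = "SYN", stringsAsFactors = FALSE)
  atoms$element <- "P"; atoms$mass <- 30.973762
  atoms$role <- "lipid"; atoms$group <- "headgroup"
  tr <- membrane_trajectory(atoms, array(X, c(n, 3, 1)), 0,
                            matrix(L, 1, 3), list(SYN = spec))
  g_pkg <- rdf_po4(tr, "SYN", r_max = 3, dr = 0.05)$g
  g_brute <- brute_rdf(X, L, r_max = 3, dr = 0.05)
  expect_lt(max(abs(g_pkg - g_brute)), 1e-12)
})

test_that("ideal-gas RDF is 1 within 5% over 0.5-3 nm at n = 1e4", {
  set.seed(13)
  n <- 10000
  L <- c(10, 10, 10)
  X <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10))
  spec <- bilayr:::synthetic_species_template("SYN")$spec
  atoms <- data.frame(atom_name = rep("P", n), residue_index = 1:n,
                      residue_name = "SYN", stringsAsFactors = FALSE)
  atoms$element <- "P"; atoms$mass <- 30.973762
  atoms$role <- "lipid"; atoms$group <- "headgroup"
  tr <- membrane_trajectory(atoms, array(X, c(n, 3, 1)), 0,
                            matrix(L, 1, 3), list(SYN = spec))
  r <- rdf_po4(tr, "SYN", r_max = 3.2, dr = 0.05)
  sel <- r$r >= 0.5 & r$r <= 3
  expect_true(all(abs(r$g[sel] - 1) < 0.05))
})

test_that("RDF number conservation: sum g * shellvol * rho = N - 1", {
  set.seed(21)
  n <- 150
  L <- c(6, 6, 6)
  X <- cbind(runif(n, 0, 6), runif(n, 0, 6), runif(n, 0, 6))
  spec <- bilayr:::synthetic_species_template("SYN")$spec
  atoms <- data.frame(atom_name = rep("P", n), residue_index = 1:n,
                      residue_name = "SYN", stringsAsFactors = FALSE)
  atoms$element <- "P"; atoms$mass <- 30.973762
  atoms$role <- "lipid"; atoms$group <- "headgroup"
  tr <- membrane_trajectory(atoms, array(X, c(n, 3, 1)), 0,
                            matrix(L, 1, 3), list(SYN = spec))
  dr <- 0.02; r_max <- 3.0
  r <- rdf_po4(tr, "SYN", r_max = r_max, dr = dr)
  edges <- seq(0, r_max, by = dr)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  rho <- n / prod(L)
  captured <- sum(r$g * shell * rho)
  # mean neighbor count within r_max, under the N(N-1)/V pair-density
  # convention (the n/(n-1) factor is the finite-N correction)
  d <- bilayr:::pair_distances(X, NULL, L)
  expected <- 2 * sum(d < r_max) / (n - 1)
  expect_equal(captured, expected, tolerance = 1e-9)
  expect_equal(captured, 2 * sum(d < r_max) / n, tolerance = 2 / n)
})

test_that("H-bond criterion: collinear in-range bonds pass, long ones do
          not", {
  # O-H...O collinear at 0.28 nm donor-acceptor distance
  coords <- rbind(c(1, 1, 1),          # donor O
                  c(1, 1, 1.1),        # H toward acceptor
                  c(1, 1, 1.28))       # acceptor O
  donors <- data.frame(donor = 1L, hydrogen = 2L)
  b <- detect_hbonds(coords, c(5, 5, 5), donors, acceptors = 3L)
  expect_equal(nrow(b), 1)
  expect_equal(b$distance, 0.28, tolerance = 1e-12)
  expect_equal(b$angle, 0, tolerance = 1e-6)
  # same geometry at 0.36 nm: no bond at the default cutoffs
  coords2 <- coords; coords2[3, 3] <- 1.36
  expect_equal(nrow(detect_hbonds(coords2, c(5, 5, 5), donors, 3L)), 0)
  # angle just over 30 degrees: no bond
  h <- c(1 + 0.1 * sin(31 * pi / 180), 1, 1 + 0.1 * cos(31 * pi / 180))
  coords3 <- rbind(c(1, 1, 1), h, c(1, 1, 1.3))
  expect_equal(nrow(detect_hbonds(coords3, c(5, 5, 5), donors, 3L)), 0)
})

test_that("H-bond detection matches the brute-force oracle and is
          rotation invariant", {
  set.seed(31)
  n_mol <- 100
  box <- c(3, 3, 3)
  O <- cbind(runif(n_mol, 0, 3), runif(n_mol, 0, 3), runif(n_mol, 0, 3))
  u <- generate_ch_orientations(list(type = "isotropic"), n_mol)
  H <- O + 0.1 * u
  coords <- rbind(O, H)
  donors <- data.frame(donor = seq_len(n_mol),
                       hydrogen = n_mol + seq_len(n_mol))
  acceptors <- seq_len(n_mol)
  b_pkg <- detect_hbonds(coords, box, donors, acceptors)
  b_oracle <- brute_hbonds(coords, box, donors, acceptors)
  key <- function(d) sort(paste(d$donor, d$acceptor))
  expect_identical(key(b_pkg), key(b_oracle))
  expect_gt(nrow(b_pkg), 0)
  # global rotation about the box center preserves the bond set when
  # particles stay in the primary cell (use a tight cluster to avoid
  # wrapping artifacts)
  cl <- coords / 4 + 1.1   # cluster well inside the box
  b1 <- detect_hbonds(cl, box, donors, acceptors)
  R <- random_rotation()
  ctr <- c(1.5, 1.5, 1.5)
  cl_rot <- sweep(sweep(cl, 2, ctr) %*% t(R), 2, ctr, "+")
  b2 <- detect_hbonds(cl_rot, box, donors, acceptors)
  expect_identical(key(b1), key(b2))
})

test_that("H-bond normalization reproduces the worked example and its
          invariants", {
  # types X (n=2, chi=2), Y (n=1, chi=1): N_max = 5, P(X) = 0.8,
  # P(Y) = 0.2, N_obs(X,Y) = 1 -> N_norm = 1 / (5 * 1.0) = 0.2
  types <- data.frame(type = c("X", "Y"), n = c(2, 1), chi = c(2, 1))
  n_obs <- data.frame(X = "X", Y = "Y", N_obs = 1)
  cen <- normalize_hbonds(types, n_obs)
  expect_equal(attr(cen, "N_max"), 5)
  expect_equal(unname(attr(cen, "P")), c(0.8, 0.2))
  expect_equal(cen$N_norm, 0.2)
  # N_obs = 0 -> N_norm = 0
  expect_equal(normalize_hbonds(types,
                                data.frame(X = "X", Y = "Y",
                                           N_obs = 0))$N_norm, 0)
  # error when capacities vanish
  expect_error(normalize_hbonds(data.frame(type = "X", n = 2, chi = 0),
                                n_obs), "N_max")
})

test_that("probabilities sum to 1 and N_norm is homogeneous over
          randomized censuses", {
  set.seed(41)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    types <- data.frame(type = paste0("T", seq_len(k)),
                        n = sample(1:500, k, replace = TRUE),
                        chi = sample(1:12, k, replace = TRUE))
    prs <- t(combn(types$type, 2))
    n_obs <- data.frame(X = prs[, 1], Y = prs[, 2],
                        N_obs = runif(nrow(prs), 0, 50))
    cen <- normalize_hbonds(types, n_obs)
    expect_equal(sum(attr(cen, "P")), 1, tolerance = 1e-12)
    # scaling all n_i by m leaves P unchanged and divides N_norm by m
    m <- sample(2:5, 1)
    types2 <- types; types2$n <- types2$n * m
    cen2 <- normalize_hbonds(types2, n_obs)
    expect_equal(unname(attr(cen2, "P")), unname(attr(cen, "P")),
                 tolerance = 1e-12)
    expect_equal(cen2$N_norm, cen$N_norm / m, tolerance = 1e-12)
    expect_equal(attr(cen2, "N_max"), m * attr(cen, "N_max"))
  }
})

test_that("the trajectory census pools solvent and exposes the capacity
          table", {
  sim <- small_bilayer(n_frames = 6L)
  cen <- hbond_census(sim$trajectory, frame_stride = 3L)
  types <- attr(cen, "types")
  expect_setequal(types$type,
                  c("SYN:headgroup", "SYN:glycerol", "solvent"))
  # per-atom rules: headgroup P-oxygens 2*3 + ester O12 2 -> 8;
  # glycerol O11 + O21 + O31 at 2 each -> 6; water O(2) + 2 H(1) -> 4
  expect_equal(types$chi[types$type == "SYN:headgroup"], 8)
  expect_equal(types$chi[types$type == "SYN:glycerol"], 6)
  expect_equal(types$chi[types$type == "solvent"], 4)
  expect_equal(sum(attr(cen, "P")), 1, tolerance = 1e-12)
  expect_true(all(cen$N_norm >= 0))
})
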