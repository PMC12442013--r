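# S_CH order parameters and the experimental comparison.

make_ch_trajectory <- function(theta_deg, n_frames = 4L) {
  labels <- names(bilayr:::synthetic_species_template("SYN")$spec$ch_pairs)
  model <- lapply(labels, function(l) list(type = "fixed",
                                           theta_deg = theta_deg))
  names(model) <- labels
  small_bilayer(n_frames = n_frames, ch_theta_model = model)
}

test_that("S_CH closed forms: theta = 0 gives 1, theta = 90 gives -0.5,
          magic angle gives 0", {
  sim0 <- make_ch_trajectory(0)
  s0 <- compute_sch(sim0$trajectory, "SYN", block_length = NULL)
  expect_equal(s0$S_CH, rep(1, nrow(s0)), tolerance = 1e-12)
  sim90 <- make_ch_trajectory(90)
  s90 <- compute_sch(sim90$trajectory, "SYN", block_length = NULL)
  expect_equal(s90$S_CH, rep(-0.5, nrow(s90)), tolerance = 1e-9)
  simM <- make_ch_trajectory(54.7356)
  sM <- compute_sch(simM$trajectory, "SYN", block_length = NULL)
  expect_lt(max(abs(sM$S_CH)), 1e-6)
})

test_that("isotropic orientations average to |S_CH| < 0.005 at 1e6
          samples", {
  u <- generate_ch_orientations(list(type = "isotropic"), 1e6, seed = 8)
  expect_lt(abs(mean((3 * u[, 3]^2 - 1) / 2)), 0.005)
})

test_that("S_CH is invariant under flipping C-H vectors", {
  sim <- small_bilayer(n_frames = 4L)
  s1 <- compute_sch(sim$trajectory, "SYN", block_length = NULL)
  tr <- sim$trajectory
  # flip every C-H vector about its carbon (theta -> 180 - theta)
  spec <- tr$specs$SYN
  for (lbl in names(spec$ch_pairs)) {
    for (p in spec$ch_pairs[[lbl]]) {
      ci <- which(tr$atoms$residue_name == "SYN" & tr$atoms$atom_name == p[1])
      hi <- which(tr$atoms$residue_name == "SYN" & tr$atoms$atom_name == p[2])
      v <- tr$coords[hi, , , drop = FALSE] - tr$coords[ci, , , drop = FALSE]
      v[, 3, ] <- -v[, 3, ]
      tr$coords[hi, , ] <- tr$coords[ci, , , drop = FALSE] + v
    }
  }
  s2 <- compute_sch(tr, "SYN", block_length = NULL)
  expect_equal(s2$S_CH, s1$S_CH, tolerance = 1e-12)
})

test_that("block errors agree with an independent per-block
          recomputation", {
  sim <- small_bilayer(n_frames = 40L)   # 4 ns
  tr <- sim$trajectory
  s <- compute_sch(tr, "SYN", block_length = 1000)
  lbl <- "C22"
  per_block <- vapply(0:3, function(b) {
    sl <- slice_time(tr, b * 1000, b * 1000 + 900)
    compute_sch(sl, "SYN", block_length = NULL)$S_CH[
      compute_sch(sl, "SYN", block_length = NULL)$label == lbl]
  }, numeric(1))
  expect_equal(s$block_error[s$label == lbl], sd(per_block),
               tolerance = 1e-10)
})

test_that("pooling order does not matter with equal pair counts", {
  sim <- small_bilayer(n_frames = 5L)
  tr <- sim$trajectory
  s_flat <- compute_sch(tr, "SYN", block_length = NULL)
  # per-lipid means first, then average across lipids and frames
  spec <- tr$specs$SYN
  lbl <- "C23"
  prs <- spec$ch_pairs[[lbl]]
  res_ids <- sort(unique(tr$atoms$residue_index[
    tr$atoms$residue_name == "SYN"]))
  per_lipid <- vapply(res_ids, function(res) {
    vals <- c()
    for (p in prs) {
      ci <- which(tr$atoms$residue_index == res & tr$atoms$atom_name == p[1])
      hi <- which(tr$atoms$residue_index == res & tr$atoms$atom_name == p[2])
      for (f in seq_len(n_frames(tr))) {
        v <- tr$coords[hi, , f] - tr$coords[ci, , f]
        vals <- c(vals, (3 * v[3]^2 / sum(v^2) - 1) / 2)
      }
    }
    mean(vals)
  }, numeric(1))
  expect_equal(mean(per_lipid), s_flat$S_CH[s_flat$label == lbl],
               tolerance = 1e-12)
})

test_that("label matching averages envelope members and flags gaps", {
  sim_set <- data.frame(
    species = "SYN", label = c("C22", "C23", "C24", "C12"),
    segment = c("sn-2", "sn-2", "sn-2", "headgroup"),
    S_CH = c(-0.20, -0.10, -0.30, 0.05),
    stringsAsFactors = FALSE
  )
  exp_tab <- data.frame(
    membrane = "M", species = "SYN",
    exp_label = c("C22-C24 envelope", "C12"),
    abs_SCH = c(0.18, 0.06),
    segment = c("sn-2", "headgroup"), stringsAsFactors = FALSE
  )
  pairs <- match_labels(sim_set, exp_tab,
                        label_map = list("C22-C24 envelope" =
                                           c("C22", "C23", "C24")))
  expect_equal(pairs$abs_sim[1], abs(mean(c(-0.20, -0.10, -0.30))))
  # identity mapping
  p2 <- match_labels(sim_set, exp_tab[2, ], label_map = NULL)
  expect_equal(p2$abs_sim, 0.05)
  expect_equal(p2$abs_exp, 0.06)
  # unmapped label -> error
  exp_bad <- exp_tab; exp_bad$exp_label[2] <- "C99"
  expect_error(match_labels(sim_set, exp_bad[2, ]), "mapping error")
})

test_that("MSE by segment: zero for identical tables, exact arithmetic,
          order invariance", {
  pairs <- data.frame(
    species = "SYN", exp_label = c("a", "b", "c"),
    segment = c("headgroup", "sn-1", "sn-2"),
    abs_sim = c(0.1, 0.2, 0.3), abs_exp = c(0.1, 0.2, 0.3),
    stringsAsFactors = FALSE
  )
  r <- mse_by_segment(pairs)
  expect_equal(r$mse, c(0, 0, 0))
  # single pair (0.2 vs 0.1) -> 0.01 exactly
  p1 <- data.frame(species = "SYN", exp_label = "a", segment = "sn-1",
                   abs_sim = 0.2, abs_exp = 0.1)
  r1 <- suppressWarnings(mse_by_segment(p1))
  expect_equal(r1$mse[r1$segment == "sn-1"], 0.01)
  # reordering pairs leaves the MSE unchanged
  set.seed(5)
  p <- data.frame(species = "SYN",
                  exp_label = letters[1:6],
                  segment = rep(c("sn-1", "sn-2"), 3),
                  abs_sim = runif(6, 0, 0.4), abs_exp = runif(6, 0, 0.4))
  ra <- suppressWarnings(mse_by_segment(p))
  rb <- suppressWarnings(mse_by_segment(p[sample(6), ]))
  expect_equal(ra$mse, rb$mse, tolerance = 1e-15)
})

test_that("the bundled reference table and lipid specs load cleanly", {
  tab <- read_experimental_op_table(
    system.file("extdata", "example_op_references_synthetic.csv",
                package = "bilayr"))
  expect_true(all(tab$abs_SCH >= 0 & tab$abs_SCH <= 0.5))
  for (sp in c("POPC", "POPE", "POPG")) {
    spec <- bundled_lipid_spec(sp)
    expect_s3_class(spec, "lipid_spec")
    expect_true(spec$phosphorus_atom %in% spec$po4_atoms)
    expect_true(length(spec$ch_pairs) > 20)
  }
  # POPE amine and POPG hydroxyls carry donor hydrogens
  pope <- bundled_lipid_spec("POPE")
  roles <- vapply(pope$hbond_atoms, `[[`, character(1), "role")
  expect_equal(sum(roles == "donor_H"), 3)
  popg <- bundled_lipid_spec("POPG")
  roles <- vapply(popg$hbond_atoms, `[[`, character(1), "role")
  expect_equal(sum(roles == "donor_H"), 2)
})
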