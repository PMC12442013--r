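# C-H order parameters and the comparison against experimental NMR
# references.
#
# For each C-H bond, S_CH = (1/2) <3 cos^2 theta - 1> with theta the angle
# between the bond vector and the membrane normal (+z); the average runs
# flat over all pairs, lipids and frames of a carbon label.  Experimental
# R-PDLF measurements yield |S_CH| only, so comparisons are made on
# magnitudes while simulation output keeps the sign.

#' Compute C-H order parameters for one species
#'
#' @param traj `membrane_trajectory`
#' @param species lipid species name; its spec must define `ch_pairs`
#' @param block_length block length for the error estimate, ps (`NULL` for
#'   no block errors)
#' @return object of class `order_parameter_set`: data.frame (`species`,
#'   `label`, `segment`, `S_CH`, `block_error`, `n_samples`)
#' @export
compute_sch <- function(traj, species, block_length = 10000) {
  spec <- traj$specs[[species]]
  if (is.null(spec)) stop("no spec for species ", species, call. = FALSE)
  if (!length(spec$ch_pairs)) {
    warning("species ", species, " defines no C-H pairs (united-atom ",
            "topology?); skipping S_CH")
    return(NULL)
  }
  a <- traj$atoms
  ids <- if (!is.null(block_length)) block_ids(traj$times, block_length)
         else rep(1L, n_frames(traj))
  nb <- max(ids)
  rows <- lapply(names(spec$ch_pairs), function(lbl) {
    prs <- spec$ch_pairs[[lbl]]
    cidx <- integer(0); hidx <- integer(0)
    for (p in prs) {
      ci <- which(a$residue_name == species & a$atom_name == p[1])
      hi <- which(a$residue_name == species & a$atom_name == p[2])
      if (length(ci) != length(hi)) {
        stop("unpaired C/H atoms for label ", lbl, call. = FALSE)
      }
      if (!length(hi)) {
        warning("no hydrogens resolvable for label ", lbl, " of ", species,
                "; label skipped")
        next
      }
      cidx <- c(cidx, ci); hidx <- c(hidx, hi)
    }
    if (!length(cidx)) return(NULL)
    per_block_sum <- numeric(nb); per_block_n <- numeric(nb)
    for (f in seq_len(n_frames(traj))) {
      v <- traj$coords[hidx, , f] - traj$coords[cidx, , f]
      for (ax in 1:3) v[, ax] <- min_image(v[, ax], traj$box[f, ax])
      c2 <- v[, 3]^2 / rowSums(v^2)
      s <- (3 * c2 - 1) / 2
      per_block_sum[ids[f]] <- per_block_sum[ids[f]] + sum(s)
      per_block_n[ids[f]] <- per_block_n[ids[f]] + length(s)
    }
    per_block <- per_block_sum / per_block_n
    data.frame(species = species, label = lbl,
               segment = if (!is.null(spec$segments) &&
                             lbl %in% names(spec$segments))
                 spec$segments[[lbl]] else NA_character_,
               S_CH = sum(per_block_sum) / sum(per_block_n),
               block_error = block_error(per_block),
               n_samples = sum(per_block_n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("order_parameter_set", "data.frame")
  out
}

#' Read an experimental order-parameter reference table
#'
#' CSV with columns `membrane`, `species`, `exp_label`, `abs_SCH`,
#' `segment`.  Unresolved experimental labels (envelopes covering several
#' carbons) are mapped onto simulation labels through a label map at
#' comparison time.
#'
#' @param path CSV path
#' @return data.frame of class `experimental_op_table`
#' @export
read_experimental_op_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("membrane", "species", "exp_label", "abs_SCH", "segment")
  if (!all(need %in% names(tab))) {
    stop("experimental OP table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tab$abs_SCH < 0 | tab$abs_SCH > 0.5)) {
    stop("experimental |S_CH| outside [0, 0.5]", call. = FALSE)
  }
  class(tab) <- c("experimental_op_table", "data.frame")
  tab
}

#' Pair simulated and experimental order parameters
#'
#' For an experimental label group the simulation value is the mean S_CH of
#' its member labels; the comparison is made on magnitudes.
#'
#' @param sim_set [compute_sch()] result
#' @param exp_table [read_experimental_op_table()] result (or compatible
#'   data.frame), already restricted to the relevant membrane
#' @param label_map named list: experimental label -> character vector of
#'   simulation labels; `NULL` uses the identity mapping
#' @return data.frame (`species`, `exp_label`, `segment`, `abs_sim`,
#'   `abs_exp`)
#' @export
match_labels <- function(sim_set, exp_table, label_map = NULL) {
  rows <- lapply(seq_len(nrow(exp_table)), function(i) {
    el <- exp_table$exp_label[i]
    sp <- exp_table$species[i]
    sim_labels <- if (!is.null(label_map) && el %in% names(label_map)) {
      label_map[[el]]
    } else el
    sel <- sim_set$species == sp & sim_set$label %in% sim_labels
    if (sum(sel) < length(sim_labels)) {
      stop("mapping error: experimental label '", el, "' (", sp,
           ") maps to simulation label(s) not present: ",
           paste(setdiff(sim_labels, sim_set$label[sim_set$species == sp]),
                 collapse = ", "), call. = FALSE)
    }
    data.frame(species = sp, exp_label = el,
               segment = exp_table$segment[i],
               abs_sim = abs(mean(sim_set$S_CH[sel])),
               abs_exp = exp_table$abs_SCH[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean squared error between simulated and experimental order parameters
#'
#' `MSE = mean over pairs of (|S_sim| - |S_exp|)^2`, reported per segment
#' (headgroup, sn-1, sn-2).  Segments without pairs are omitted with a
#' warning.
#'
#' @param pairs [match_labels()] result
#' @param segments segments to report
#' @return data.frame (`segment`, `mse`, `n_pairs`) of class `mse_report`
#' @export
mse_by_segment <- function(pairs, segments = c("headgroup", "sn-1", "sn-2")) {
  rows <- lapply(segments, function(seg) {
    sel <- pairs$segment == seg
    if (!any(sel)) {
      warning("no pairs for segment '", seg, "'; omitted")
      return(NULL)
    }
    data.frame(segment = seg,
               mse = mean((pairs$abs_sim[sel] - pairs$abs_exp[sel])^2),
               n_pairs = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mse_report", "data.frame")
  out
}
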