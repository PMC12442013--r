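# Physical constants and unit helpers.
#
# Internal length unit is the nanometre, time is the picosecond, mass the
# unified atomic mass unit.  Energies are carried in zeptojoule (1 zJ =
# 1e-21 J) because with areas in nm^2 the identity 1 mN/m = 1 zJ/nm^2 makes
# the compressibility modulus come out in mN/m with no loose factors.

#' Physical constants used by the package
#'
#' @format A named list:
#' \describe{
#'   \item{kB_zJ_per_K}{Boltzmann constant, zJ/K (1.380649e-2).}
#'   \item{amu_kg}{Unified atomic mass unit in kg.}
#'   \item{m_water_amu}{Mass of one water molecule, u.}
#' }
#' @export
bilayer_constants <- list(
  kB_zJ_per_K = 1.380649e-2,   # 1.380649e-23 J/K expressed in zJ/K
  amu_kg      = 1.66053906892e-27,
  m_water_amu = 18.01528
)

# Standard atomic masses (u), keyed by element symbol.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.973762,
  S = 32.06, NA. = 22.98977, CL = 35.453, K = 39.0983, MG = 24.305,
  CA = 40.078, F = 18.998
)

# Guess the element from an atom name the way PDB/GRO conventions imply:
# strip digits/primes, try the two-letter symbol first, then one letter.
guess_element <- function(atom_name) {
  vapply(atom_name, function(nm) {
    s <- toupper(gsub("[^A-Za-z]", "", nm))
    if (nzchar(s)) {
      two <- substr(s, 1, 2)
      key2 <- if (two == "NA") "NA." else two
      if (two %in% c("CL", "MG", "CA", "NA") && key2 %in% names(.element_masses))
        return(sub("\\.$", "", key2))
      one <- substr(s, 1, 1)
      if (one %in% names(.element_masses)) return(one)
    }
    stop("cannot infer element for atom name '", nm, "'", call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

element_mass <- function(element) {
  key <- ifelse(toupper(element) == "NA", "NA.", toupper(element))
  m <- .element_masses[key]
  if (anyNA(m)) {
    stop("no mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

#' Per-frame time series summary
#'
#' Container for a per-frame observable with its mean and standard deviation.
#' The standard deviation always uses N-1 normalization (the unbiased
#' estimator), the convention used throughout the package for error bars.
#'
#' @param values numeric vector, one value per frame
#' @param times frame times in ps (optional)
#' @param unit character label for the unit of `values`
#' @return An object of class `ts_stat` with elements `values`, `times`,
#'   `mean`, `std`, `unit`.
#' @export
ts_stat <- function(values, times = NULL, unit = "") {
  stopifnot(is.numeric(values), length(values) >= 1)
  structure(
    list(values = values, times = times, mean = mean(values),
         std = stats::sd(values), unit = unit),
    class = "ts_stat"
  )
}

#' @export
print.ts_stat <- function(x, ...) {
  cat(sprintf("<ts_stat> n = %d frames: mean = %.6g, sd = %.6g %s\n",
              length(x$values), x$mean, x$std, x$unit))
  invisible(x)
}

# Split frame times into contiguous blocks of block_length (ps).
# Returns an integer block id per frame.  A single frame is one block;
# otherwise the block length must not exceed the trajectory span.  A
# ragged tail shorter than a block is folded into the last full block.
block_ids <- function(times, block_length) {
  stopifnot(block_length > 0)
  if (length(times) == 1) return(1L)
  span <- max(times) - min(times)
  if (block_length > span) {
    stop("block length (", block_length, " ps) exceeds the trajectory ",
         "span (", span, " ps)", call. = FALSE)
  }
  ids <- as.integer(floor((times - min(times)) / block_length) + 1L)
  nb <- max(ids)
  # a trailing stub shorter than half a block folds into the last block
  if (nb > 1) {
    last_start <- min(times) + (nb - 1) * block_length
    if (max(times) - last_start < block_length / 2) {
      ids[ids == nb] <- nb - 1L
    }
  }
  ids
}

# Standard deviation across block means (N-1); the package-wide block error.
block_error <- function(per_block_values) {
  if (length(per_block_values) < 2) return(NA_real_)
  stats::sd(per_block_values)
}
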