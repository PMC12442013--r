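# Figure rendering.  All plots are built from the CSVs written by
# run_pipeline(), never from in-memory state, so the CSVs remain the
# contract between analysis and presentation.

read_stage_csv <- function(dir, name) {
  p <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(p)) return(NULL)
  utils::read.csv(p, stringsAsFactors = FALSE)
}

save_plot <- function(plot, path, width = 7, height = 5) {
  tryCatch({
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 120)
    path
  }, error = function(e) {
    warning("could not render ", path, ": ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
}

#' Render the comparative figures for a pipeline output directory
#'
#' Produces bar charts (mean with standard-deviation error bars) for area
#' per lipid, thickness and inner waters across systems; order-parameter
#' profiles per species; log-scale MSE bars per segment; and displacement
#' probability densities per window.  Re-rendering the same directory is
#' deterministic.
#'
#' @param output_dir the `output_dir` of a previous [run_pipeline()] call
#' @return character vector of the figure paths written, invisibly
#' @export
render_report <- function(output_dir) {
  labels <- list.dirs(output_dir, recursive = FALSE, full.names = FALSE)
  if (!length(labels)) {
    warning("no system outputs under ", output_dir, "; nothing to render")
    return(invisible(character(0)))
  }
  fig_dir <- file.path(output_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  written <- character(0)

  bar_data <- function(name, value_col) {
    do.call(rbind, lapply(labels, function(lbl) {
      tab <- read_stage_csv(file.path(output_dir, lbl), name)
      if (is.null(tab)) return(NULL)
      data.frame(label = lbl, mean = mean(tab[[value_col]]),
                 sd = stats::sd(tab[[value_col]]))
    }))
  }
  bars <- list(
    list("area_per_lipid", "area_A2", "Area per lipid (Å²)"),
    list("thickness", "thickness_nm", "P-P thickness (nm)")
  )
  for (b in bars) {
    d <- bar_data(b[[1]], b[[2]])
    if (is.null(d)) next
    p <- ggplot2::ggplot(d, ggplot2::aes(x = label, y = mean)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd,
                                          ymax = mean + sd), width = 0.2) +
      ggplot2::labs(x = NULL, y = b[[3]]) + ggplot2::theme_minimal()
    written <- c(written, save_plot(p, file.path(fig_dir,
                                                 paste0(b[[1]], ".png"))))
  }

  sch <- do.call(rbind, lapply(labels, function(lbl) {
    tab <- read_stage_csv(file.path(output_dir, lbl), "sch")
    if (!is.null(tab)) cbind(system = lbl, tab)
  }))
  if (!is.null(sch)) {
    sch$abs_SCH <- abs(sch$S_CH)
    p <- ggplot2::ggplot(sch, ggplot2::aes(x = label, y = abs_SCH,
                                           colour = system,
                                           group = system)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~species + segment, scales = "free_x") +
      ggplot2::labs(x = "carbon", y = "|S_CH|") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
    written <- c(written, save_plot(p, file.path(fig_dir, "sch.png"),
                                    width = 9))
  }

  mse <- do.call(rbind, lapply(labels, function(lbl) {
    tab <- read_stage_csv(file.path(output_dir, lbl), "mse")
    if (!is.null(tab)) cbind(system = lbl, tab)
  }))
  if (!is.null(mse)) {
    p <- ggplot2::ggplot(mse, ggplot2::aes(x = system, y = mse,
                                           fill = segment)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = NULL, y = "MSE (log scale)") +
      ggplot2::theme_minimal()
    written <- c(written, save_plot(p, file.path(fig_dir, "mse.png")))
  }

  for (lbl in labels) {
    files <- list.files(file.path(output_dir, lbl),
                        pattern = "^displacement_w.*\\.csv$")
    dd <- do.call(rbind, lapply(files, function(f) {
      w <- sub("^displacement_w([0-9.]+)\\.csv$", "\\1", f)
      cbind(window = paste0(w, " ns"),
            utils::read.csv(file.path(output_dir, lbl, f)))
    }))
    if (is.null(dd)) next
    p <- ggplot2::ggplot(dd, ggplot2::aes(x = r, y = density,
                                          colour = window)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "lateral displacement r (nm)",
                    y = "probability density", title = lbl) +
      ggplot2::theme_minimal()
    written <- c(written, save_plot(p, file.path(
      fig_dir, paste0("displacement_", lbl, ".png"))))
  }
  invisible(written)
}
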