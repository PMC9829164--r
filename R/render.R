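#' Spatiotemporal voltage map of a simulation
#'
#' Cells on the vertical axis (Purkinje end at the top), time on the
#' horizontal axis, colour = membrane potential.
#'
#' @param result A `pvs_simulation`.
#' @param main Plot title.
#' @param zlim Colour range (mV).
#' @export
plot_voltage_map <- function(result, main = "membrane potential (mV)",
                             zlim = c(-90, 50)) {
  stopifnot(inherits(result, "pvs_simulation"))
  pal <- grDevices::hcl.colors(64, "Spectral", rev = TRUE)
  z <- t(result$v)[, rev(seq_len(nrow(result$v))), drop = FALSE]
  z[z < zlim[1]] <- zlim[1]; z[z > zlim[2]] <- zlim[2]
  graphics::image(x = result$times, y = seq_len(nrow(result$v)), z = z,
                  col = pal, zlim = zlim, xlab = "time (ms)",
                  ylab = "cell (Epi ... P)", main = main, useRaster = TRUE)
  invisible(result)
}

.CATEGORY_COLORS <- c(control = "#2ca02c", no_excitation = "#aaaaaa",
                      ap_prolongation = "#1f77b4", ap_alternans = "#ffd700",
                      ead = "#d62728", numeric_failure = "#000000",
                      missing = "#ffffff")

#' Category map of a sweep at one cycle length
#'
#' IKr block on one axis, ICaL block on the other, coloured by excitation
#' pattern: control green, no excitation gray, AP prolongation blue, AP
#' alternans yellow, EAD events red. Missing runs render white and are
#' reported.
#'
#' @param sweep A [run_sweep()] result.
#' @param cl Cycle length to display (ms); default: the first in the sweep.
#' @export
plot_category_map <- function(sweep, cl = NULL) {
  stopifnot(inherits(sweep, "pvs_sweep"))
  if (is.null(cl)) cl <- min(sweep$cl)
  d <- sweep[sweep$cl == cl, ]
  krs <- sort(unique(sweep$s_kr_block)); cals <- sort(unique(sweep$s_cal_block))
  z <- matrix("missing", length(krs), length(cals),
              dimnames = list(krs, cals))
  for (i in seq_len(nrow(d)))
    z[as.character(d$s_kr_block[i]), as.character(d$s_cal_block[i])] <-
      d$category[i]
  if (any(z == "missing"))
    message(sum(z == "missing"), " missing runs at CL = ", cl)
  lv <- names(.CATEGORY_COLORS)
  zi <- matrix(match(z, lv), nrow(z), ncol(z))
  graphics::image(x = seq_along(krs), y = seq_along(cals), z = zi,
                  col = .CATEGORY_COLORS, zlim = c(1, length(lv)),
                  axes = FALSE, xlab = "IKr block", ylab = "ICaL block",
                  main = sprintf("excitation patterns, CL = %g ms", cl))
  graphics::axis(1, at = seq_along(krs), labels = krs)
  graphics::axis(2, at = seq_along(cals), labels = cals)
  graphics::box()
  invisible(sweep)
}

#' Render maps and tables of a simulation or sweep to files
#'
#' For a single simulation: the voltage map as PNG plus the raw matrix as
#' CSV. For a sweep: one category map PNG per cycle length (stacked pages
#' ordered from the shortest CL at the top of the file sequence), the label
#' table as CSV and as JSON-lines, and the control reference table.
#'
#' @param x A `pvs_simulation` or `pvs_sweep`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
render_maps <- function(x, dir = ".", prefix = "pvs") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (inherits(x, "pvs_simulation")) {
    png_path <- file.path(dir, paste0(prefix, "_voltage_map.png"))
    grDevices::png(png_path, width = 900, height = 500)
    plot_voltage_map(x)
    grDevices::dev.off()
    csv_path <- file.path(dir, paste0(prefix, "_voltage.csv"))
    write_simulation_csv(x, csv_path)
    paths <- c(png_path, csv_path)
  } else if (inherits(x, "pvs_sweep")) {
    for (cl in sort(unique(x$cl))) {
      p <- file.path(dir, sprintf("%s_category_map_cl%04d.png", prefix, cl))
      grDevices::png(p, width = 600, height = 600)
      plot_category_map(x, cl)
      grDevices::dev.off()
      paths <- c(paths, p)
    }
    lab <- file.path(dir, paste0(prefix, "_labels.csv"))
    utils::write.csv(as.data.frame(x), lab, row.names = FALSE)
    jl <- file.path(dir, paste0(prefix, "_labels.jsonl"))
    write_labels_json(x, jl)
    ctl <- file.path(dir, paste0(prefix, "_control_reference.csv"))
    utils::write.csv(attr(x, "control"), ctl, row.names = FALSE)
    paths <- c(paths, lab, jl, ctl)
  } else stop("don't know how to render ", class(x)[1], call. = FALSE)
  invisible(paths)
}
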