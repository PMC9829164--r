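#' Tissue (strand) configuration
#'
#' Describes the 1D Purkinje-ventricular strand: four layers in fixed order
#' P - Endo - M - Epi, each with `cells_per_layer` cells on a cell-centred
#' grid of total length `length` cm (default 2 cm, 200 cells, dx = 100 um).
#' Diffusion coefficients are per-face: `d_p` inside the Purkinje layer,
#' `d_v` inside and between ventricular layers, and `e_r * d_v` on the single
#' Purkinje-ventricular junction (PVJ) face between the last P and the first
#' Endo cell.
#'
#' The default diffusion values come from [default_profile()] for the chosen
#' resolution; pass `profile = "paper-canine"` for the literature profile
#' (D_P = 1.2, D_v = 0.1 mm^2/ms, E_R = 3.13), which will not reproduce the
#' calibration targets under the shipped membrane model.
#'
#' The stimulated region defaults to the first 1 mm of the strand (at least
#' 3 cells): a fixed physical stimulus length excites the strand at any grid
#' resolution.
#'
#' @param cells_per_layer Cells per layer (default 50; total = 4x).
#' @param length Strand length in cm.
#' @param d_p,d_v Purkinje / ventricular diffusion coefficients (mm^2/ms).
#' @param e_r PVJ electric ratio factor (dimensionless); the PVJ face
#'   coefficient is `e_r * d_v`.
#' @param scaling A [channel_scaling()] applied to every cell.
#' @param stim_cells Integer indices of stimulated cells (1-based, at the
#'   Purkinje end). `NULL` = first 1 mm.
#' @param stim_amplitude Stimulus current (uA/uF, negative = depolarizing).
#' @param stim_duration Stimulus duration (ms).
#' @param profile Name of the diffusion profile used for unspecified
#'   `d_p`/`d_v`/`e_r`: `"calibrated"` (default) or `"paper-canine"`.
#' @return An object of class `tissue_config`.
#' @export
#' @examples
#' cfg <- tissue_config(cells_per_layer = 10)  # 40-cell test strand
#' cfg$dx  # 0.05 cm
tissue_config <- function(cells_per_layer = 50, length = 2.0,
                          d_p = NULL, d_v = NULL, e_r = NULL,
                          scaling = channel_scaling(),
                          stim_cells = NULL, stim_amplitude = -80,
                          stim_duration = 1,
                          profile = c("calibrated", "paper-canine")) {
  profile <- match.arg(profile)
  bad <- character(0)
  if (!is.numeric(cells_per_layer) || cells_per_layer < 1 ||
      cells_per_layer != round(cells_per_layer))
    bad <- c(bad, "cells_per_layer")
  if (!is.numeric(length) || length <= 0) bad <- c(bad, "length")
  prof <- default_profile(cells_per_layer, name = profile)
  if (is.null(d_p)) d_p <- prof$d_p
  if (is.null(d_v)) d_v <- prof$d_v
  if (is.null(e_r)) e_r <- prof$e_r
  if (!is.numeric(d_p) || d_p <= 0) bad <- c(bad, "d_p")
  if (!is.numeric(d_v) || d_v <= 0) bad <- c(bad, "d_v")
  if (!is.numeric(e_r) || e_r <= 0) bad <- c(bad, "e_r")
  n_cells <- 4L * as.integer(cells_per_layer)
  if (is.null(stim_cells)) {
    dx_mm <- length * 10 / n_cells
    stim_cells <- seq_len(max(3L, as.integer(ceiling(1 / dx_mm))))
  }
  if (!all(stim_cells >= 1 & stim_cells <= n_cells)) bad <- c(bad, "stim_cells")
  if (!is.numeric(stim_duration) || stim_duration <= 0) bad <- c(bad, "stim_duration")
  if (length(bad) > 0)
    stop("invalid tissue configuration, offending fields: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  structure(list(
    cells_per_layer = as.integer(cells_per_layer),
    layer_order = .CELL_TYPES,
    n_cells = n_cells,
    length = length,
    dx = length / n_cells,          # cm
    d_p = d_p, d_v = d_v, e_r = e_r,
    scaling = scaling,
    stim_cells = as.integer(stim_cells),
    stim_amplitude = stim_amplitude,
    stim_duration = stim_duration,
    profile = profile
  ), class = "tissue_config")
}

#' @export
print.tissue_config <- function(x, ...) {
  cat(sprintf("<tissue_config> %d cells (4 x %d), %.1f cm, dx = %g cm\n",
              x$n_cells, x$cells_per_layer, x$length, x$dx))
  cat(sprintf("  D_P = %g, D_v = %g, PVJ = E_R x D_v = %g mm^2/ms\n",
              x$d_p, x$d_v, x$e_r * x$d_v))
  cat(sprintf("  stim: %g uA/uF x %g ms on cells %s\n", x$stim_amplitude,
              x$stim_duration, paste(range(x$stim_cells), collapse = "-")))
  invisible(x)
}

#' Pacing protocol
#'
#' @param cl Pacing cycle length (ms), > 0.
#' @param n_beats Total number of stimulated beats.
#' @param record_last How many trailing beats to record (default 2, matching
#'   the analysis convention of keeping the last two beats).
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cl, n_beats = 10, record_last = 2) {
  if (!is.numeric(cl) || length(cl) != 1 || cl <= 0)
    stop("`cl` must be a single positive number (ms)", call. = FALSE)
  if (n_beats < record_last || record_last < 1)
    stop("need n_beats >= record_last >= 1", call. = FALSE)
  structure(list(cl = cl, n_beats = as.integer(n_beats),
                 record_last = as.integer(record_last)),
            class = "pacing_protocol")
}

#' Assemble a tissue instance from a configuration
#'
#' Assigns each cell its cell-model variant by layer and builds the per-face
#' diffusion coefficient vector: `d_p` on faces internal to the P layer,
#' `d_v` inside and between ventricular layers, and `e_r * d_v` on the PVJ
#' face only.
#'
#' @param config A [tissue_config()].
#' @param scaling Optional [channel_scaling()] overriding the one in
#'   `config`.
#' @return An object of class `pvs_tissue` with the parameter matrix, face
#'   coefficients and initial states.
#' @export
#' @examples
#' tis <- build_tissue(tissue_config(cells_per_layer = 1))
#' tis$face_d  # 3 faces, PVJ between cells 1 and 2
build_tissue <- function(config, scaling = NULL) {
  stopifnot(inherits(config, "tissue_config"))
  if (is.null(scaling)) scaling <- config$scaling
  n <- config$n_cells
  types <- rep(config$layer_order, each = config$cells_per_layer)
  params <- vapply(config$layer_order, function(ty)
    make_cell(ty, scaling)$parameters, numeric(length(.PAR_NAMES)))
  pm <- params[, types]
  face_d <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    face_d[i] <-
      if (types[i] == "P" && types[i + 1] == "P") config$d_p
      else if (types[i] == "P") config$e_r * config$d_v  # the PVJ face
      else config$d_v
  }
  st <- initial_state()
  structure(list(
    config = config, scaling = scaling, cell_types = types,
    params = pm, face_d = face_d, dx_mm = config$dx * 10,
    state0 = matrix(rep(as.numeric(st), n), ncol = n,
                    dimnames = list(.STATE_NAMES, NULL))
  ), class = "pvs_tissue")
}

#' One explicit diffusion step on a voltage vector
#'
#' Flux-conservative update with sealed (no-flux) ends:
#' `v_i += (dt/dx^2) * (D_{i+1/2} (v_{i+1} - v_i) - D_{i-1/2} (v_i - v_{i-1}))`.
#' The summed update telescopes to zero, so the total voltage is conserved
#' to round-off.
#'
#' @param v Voltage vector (mV).
#' @param face_coeffs Per-face diffusion coefficients, length
#'   `length(v) - 1` (mm^2/ms).
#' @param dx Grid spacing (cm).
#' @param dt Time step (ms); must respect the explicit stability bound
#'   `dx^2 / (2 max(D))`.
#' @return Updated voltage vector.
#' @export
diffusion_step <- function(v, face_coeffs, dx, dt) {
  if (length(face_coeffs) != length(v) - 1)
    stop("`face_coeffs` must have length(v) - 1 entries", call. = FALSE)
  dx_mm <- dx * 10
  if (length(face_coeffs) > 0) {
    bound <- dx_mm^2 / (2 * max(face_coeffs))
    if (dt > bound)
      stop(sprintf("dt = %g ms exceeds the explicit stability bound %g ms",
                   dt, bound), call. = FALSE)
  }
  diffusion_step_cpp(as.numeric(v), as.numeric(face_coeffs), dx_mm, dt)
}

new_pvs_simulation <- function(raw, cl, cell_types, face_d, dx, record_last,
                               config) {
  structure(list(
    times = raw$times, v = raw$v, stim_times = raw$stim_times,
    final_state = raw$final_state, cl = cl, cell_types = cell_types,
    face_d = face_d, dx = dx,             # dx in cm here
    record_last = record_last, config = config
  ), class = "pvs_simulation")
}

#' @export
print.pvs_simulation <- function(x, ...) {
  cat(sprintf("<pvs_simulation> %d cells x %d samples, CL = %g ms, %d beats recorded\n",
              nrow(x$v), ncol(x$v), x$cl, x$record_last))
  invisible(x)
}

#' Beat windows of the recorded portion of a simulation
#'
#' @param result A `pvs_simulation`.
#' @return Data frame with one row per recorded beat: `beat` (1 = earliest
#'   recorded), `stim_time`, `t_start`, `t_end` (ms, absolute).
#' @export
beat_windows <- function(result) {
  stopifnot(inherits(result, "pvs_simulation"))
  nb <- length(result$stim_times)
  idx <- seq(nb - result$record_last + 1, nb)
  st <- result$stim_times[idx]
  data.frame(beat = seq_along(idx), stim_time = st, t_start = st,
             t_end = st + result$cl)
}

#' Integrate the cable equation over a paced strand
#'
#' Operator-split explicit integration: the membrane (reaction) step uses
#' Rush-Larsen gate updates and forward Euler for concentrations, the
#' diffusion step is the flux-conservative explicit update of
#' [diffusion_step()], and both advance with a shared adaptive time step
#' `dt = min(dt_max, 0.5 / max|dV/dt|)`, additionally capped by the
#' diffusion stability bound. Voltages are recorded every `output_dt` ms for
#' the last `record_last` beats. Deterministic for fixed inputs.
#'
#' @param tissue A [build_tissue()] instance.
#' @param protocol A [pacing_protocol()].
#' @param output_dt Output sampling interval (ms, default 0.5).
#' @param dt_min,dt_max Adaptive time-step bounds (ms).
#' @param state0 Optional initial state matrix (states x cells), e.g. the
#'   `final_state` of a previous run, for conditioned protocols.
#' @return A `pvs_simulation`: `times` (ms), `v` (cells x times, mV),
#'   `stim_times`, per-cell `cell_types`, face coefficients and the config.
#' @export
#' @examples
#' tis <- build_tissue(tissue_config(cells_per_layer = 10))
#' res <- simulate_tissue(tis, pacing_protocol(cl = 500, n_beats = 2))
#' range(res$v)
simulate_tissue <- function(tissue, protocol, output_dt = 0.5,
                            dt_min = 0.001, dt_max = 0.05, state0 = NULL) {
  stopifnot(inherits(tissue, "pvs_tissue"), inherits(protocol, "pacing_protocol"))
  cfg <- tissue$config
  if (is.null(state0)) state0 <- tissue$state0
  raw <- run_cable_cpp(state0, tissue$params, tissue$face_d,
                       tissue$dx_mm, as.integer(cfg$stim_cells - 1L),
                       cfg$stim_amplitude, cfg$stim_duration,
                       protocol$cl, protocol$n_beats, protocol$record_last,
                       output_dt, dt_min, dt_max)
  new_pvs_simulation(raw, cl = protocol$cl, cell_types = tissue$cell_types,
                     face_d = tissue$face_d, dx = cfg$dx,
                     record_last = protocol$record_last, config = cfg)
}
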