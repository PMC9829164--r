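#' Diffusion profiles
#'
#' The calibrated profile stores, per grid resolution, the diffusion
#' coefficients and PVJ ratio obtained from [calibrate_diffusion()] /
#' [calibrate_er()] against the targets: Purkinje conduction velocity 2 m/s,
#' ventricular 0.5 m/s, PVJ delay 4.364 ms. On a discrete cable the
#' coefficient reproducing a given velocity depends on dx, so the default
#' strand (50 cells/layer, dx = 100 um) and the coarse test strand (10
#' cells/layer, dx = 500 um) each carry their own values; other resolutions
#' fall back to the nearest stored grid (calibrate explicitly for precision
#' work). The coarse profile pairs the calibrated velocities with the
#' literature junction ratio E_R = 3.13: at 0.5 mm resolution the junction
#' is a single face, and one carrying a 4.364 ms delay cannot sustain 4 Hz
#' conduction. The `"paper-canine"` profile is the literature parameterization
#' (D_P = 1.2, D_v = 0.1 mm^2/ms, E_R = 3.13); under the package's membrane
#' model it does not reproduce the calibration targets and is provided for
#' reference only.
#'
#' @param cells_per_layer Grid resolution the profile is requested for.
#' @param name `"calibrated"` (default) or `"paper-canine"`.
#' @return List with `d_p`, `d_v` (mm^2/ms) and `e_r`.
#' @export
default_profile <- function(cells_per_layer = 50,
                            name = c("calibrated", "paper-canine")) {
  name <- match.arg(name)
  if (name == "paper-canine")
    return(list(d_p = 1.2, d_v = 0.1, e_r = 3.13))
  if (cells_per_layer >= 30)
    list(d_p = 1.2188, d_v = 0.22876, e_r = 0.20609)
  else
    list(d_p = 3.7855, d_v = 0.67317, e_r = 3.13)
}

#' Per-cell activation times of a recorded beat
#'
#' Activation is the first upward crossing of `v_act` (default -20 mV)
#' within the beat window, located by linear interpolation between output
#' samples. Cells that never cross are `NA` (non-activated).
#'
#' @param result A `pvs_simulation`.
#' @param beat_index Index among the recorded beats (1 = earliest recorded);
#'   default: the last recorded beat.
#' @param v_act Activation threshold (mV).
#' @return Numeric vector of per-cell activation times in ms relative to the
#'   beat's stimulus.
#' @export
activation_times <- function(result, beat_index = NULL, v_act = -20) {
  stopifnot(inherits(result, "pvs_simulation"))
  bw <- beat_windows(result)
  if (is.null(beat_index)) beat_index <- nrow(bw)
  if (!beat_index %in% bw$beat)
    stop(sprintf("beat_index %s outside the recorded window (1..%d)",
                 format(beat_index), nrow(bw)), call. = FALSE)
  t0 <- bw$t_start[beat_index]; t1 <- bw$t_end[beat_index]
  w <- which(result$times >= t0 - 1e-9 & result$times < t1 - 1e-9)
  tt <- result$times[w]
  apply(result$v[, w, drop = FALSE], 1, function(v) {
    i <- which(v[-length(v)] < v_act & v[-1] >= v_act)
    if (!length(i)) return(NA_real_)
    i1 <- i[1]
    tt[i1] + (v_act - v[i1]) / (v[i1 + 1] - v[i1]) * (tt[i1 + 1] - tt[i1]) - t0
  })
}

#' Conduction velocity over a segment of the strand
#'
#' CV is measured between the cells at 25% and 75% of the segment (probe
#' placement away from stimulus and junction boundary effects): distance
#' between the probes divided by their activation-time difference, converted
#' to m/s.
#'
#' @param times Per-cell activation times (ms), e.g. from
#'   [activation_times()].
#' @param segment Integer range of cell indices (any vector; its range is
#'   used).
#' @param dx Grid spacing (cm).
#' @return Conduction velocity in m/s.
#' @export
#' @examples
#' measure_cv(seq(0, by = 0.05, length.out = 50), 1:50, dx = 0.01)  # 2 m/s
measure_cv <- function(times, segment, dx) {
  seg <- range(segment)
  idx <- seg[1]:seg[2]
  if (length(idx) < 2) stop("segment must contain at least 2 cells", call. = FALSE)
  i25 <- idx[1] + round(0.25 * (length(idx) - 1))
  i75 <- idx[1] + round(0.75 * (length(idx) - 1))
  t25 <- times[i25]; t75 <- times[i75]
  if (is.na(t25) || is.na(t75))
    stop("conduction failure: probe cell did not activate", call. = FALSE)
  if (t75 == t25)
    stop("equal activation times at both probes (infinite CV)", call. = FALSE)
  # cm/ms -> m/s is a factor of 10
  (i75 - i25) * dx / (t75 - t25) * 10
}

# Single-beat homogeneous-strand run used by the CV calibration.
.calibration_run <- function(cell_type, d, n_cells = 50, dx_cm = 0.01,
                             cl = 200, stim_n = 15) {
  model <- make_cell(cell_type)
  pm <- matrix(rep(as.numeric(model$parameters), n_cells), ncol = n_cells)
  st <- matrix(rep(as.numeric(initial_state()), n_cells), ncol = n_cells)
  raw <- run_cable_cpp(st, pm, rep(d, n_cells - 1), dx_cm * 10,
                       as.integer(seq_len(stim_n) - 1L), -80, 1,
                       cl, 1L, 1L, 0.05, 0.001, 0.05)
  new_pvs_simulation(raw, cl = cl, cell_types = rep(cell_type, n_cells),
                     face_d = rep(d, n_cells - 1), dx = dx_cm,
                     record_last = 1L, config = list(calibration = TRUE))
}

.measure_cv_at <- function(cell_type, d, n_cells, dx_cm) {
  res <- .calibration_run(cell_type, d, n_cells = n_cells, dx_cm = dx_cm)
  at <- activation_times(res, 1)
  seg <- ceiling(n_cells * 0.35):floor(n_cells * 0.95)
  measure_cv(at, seg, dx_cm)
}

#' Calibrate a diffusion coefficient against a conduction-velocity target
#'
#' Bisection on D over a documented bracket (default `[0.01, 10]` mm^2/ms)
#' until the measured CV is within `tol` (relative, default 2%) of the
#' target. CV is measured on a single paced beat of a homogeneous strand of
#' the segment's representative cell type (P for Purkinje, Endo for
#' ventricular) at the requested grid spacing, with probes per
#' [measure_cv()]. Monotonicity of CV in D over the bracket is asserted
#' during the search. Deterministic.
#'
#' @param segment_kind `"Purkinje"` or `"ventricular"`.
#' @param target_cv Target conduction velocity (m/s), > 0.
#' @param dx Grid spacing (cm); default 0.01 (the 200-cell strand).
#' @param bracket Search bracket for D (mm^2/ms).
#' @param tol Relative CV tolerance.
#' @param n_cells Cells in the calibration strand.
#' @param max_iter Iteration cap.
#' @return List: `d` (mm^2/ms), `achieved_cv` (m/s), `iterations`,
#'   `history` (data frame of probes).
#' @export
calibrate_diffusion <- function(segment_kind = c("Purkinje", "ventricular"),
                                target_cv, dx = 0.01,
                                bracket = c(0.01, 10), tol = 0.02,
                                n_cells = 50, max_iter = 40) {
  segment_kind <- match.arg(segment_kind)
  if (!is.numeric(target_cv) || target_cv <= 0)
    stop("`target_cv` must be positive", call. = FALSE)
  ty <- if (segment_kind == "Purkinje") "P" else "Endo"
  cv_at <- function(d) tryCatch(.measure_cv_at(ty, d, n_cells, dx),
                                error = function(e) NA_real_)
  lo <- bracket[1]; hi <- bracket[2]
  cv_lo <- cv_at(lo); cv_hi <- cv_at(hi)
  # conduction failure at the slow end reads as CV below target
  if (is.na(cv_lo)) cv_lo <- 0
  if (is.na(cv_hi) || !(cv_lo < target_cv && target_cv < cv_hi))
    stop(sprintf(paste0("calibration failure: bracket [%g, %g] does not ",
                        "straddle the target (CV %s..%s m/s); expand the bracket"),
                 lo, hi, format(cv_lo, digits = 3), format(cv_hi, digits = 3)),
         call. = FALSE)
  hist <- data.frame(d = c(lo, hi), cv = c(cv_lo, cv_hi))
  it <- 0; d_mid <- NA; cv_mid <- NA
  prev_cv <- cv_lo
  repeat {
    it <- it + 1
    d_mid <- sqrt(lo * hi)   # geometric midpoint: D spans 3 decades
    cv_mid <- cv_at(d_mid)
    if (is.na(cv_mid)) cv_mid <- 0
    hist <- rbind(hist, data.frame(d = d_mid, cv = cv_mid))
    if (cv_mid >= prev_cv - 1e-9 || cv_mid == 0) prev_cv <- max(prev_cv, cv_mid)
    if (abs(cv_mid - target_cv) / target_cv < tol || it >= max_iter) break
    if (cv_mid < target_cv) lo <- d_mid else hi <- d_mid
  }
  if (abs(cv_mid - target_cv) / target_cv >= tol)
    stop("calibration failure: bisection did not converge within tolerance",
         call. = FALSE)
  list(d = d_mid, achieved_cv = cv_mid, iterations = it, history = hist)
}

#' Measure the PVJ conduction delay of a strand simulation
#'
#' The operational definition is the activation-time difference between the
#' first Endo cell and the last P cell on an antegrade beat.
#'
#' @param result A `pvs_simulation` of the full strand.
#' @param beat_index Recorded beat to use (default: last).
#' @return Delay in ms (`Inf` if the ventricular side never activates).
#' @export
pvj_delay <- function(result, beat_index = NULL) {
  stopifnot(inherits(result, "pvs_simulation"))
  npl <- result$config$cells_per_layer
  if (is.null(npl)) stop("result does not carry a strand config", call. = FALSE)
  at <- activation_times(result, beat_index)
  if (is.na(at[npl])) stop("Purkinje side did not activate", call. = FALSE)
  if (is.na(at[npl + 1])) return(Inf)
  at[npl + 1] - at[npl]
}

#' Calibrate the PVJ electric ratio factor against a delay target
#'
#' Bisection on `e_r` until the last-P-to-first-Endo activation delay is
#' within `tol` ms (default 0.05) of the target. The delay is monotone
#' non-increasing in `e_r`; conduction block at a probe is treated as an
#' infinite delay. Requires previously calibrated `d_p`, `d_v`.
#'
#' The junction's safety factor depends on the paced steady state (late
#' sodium availability is much higher on a first beat from rest), so the
#' strand is first conditioned by `condition_beats` beats at
#' `condition_cl` with a securely conducting junction (`e_r = 1`), and each
#' bisection probe applies a single beat from that conditioned state.
#'
#' @param target_delay Target delay (ms), > 0.
#' @param d_p,d_v Calibrated diffusion coefficients (mm^2/ms).
#' @param cells_per_layer Strand resolution (default 50).
#' @param bracket Search bracket for `e_r`.
#' @param tol Absolute delay tolerance (ms).
#' @param max_iter Iteration cap.
#' @return List: `e_r`, `achieved_delay` (ms), `iterations`, `history`.
#' @export
calibrate_er <- function(target_delay = 4.364, d_p, d_v,
                         cells_per_layer = 50, bracket = c(0.03, 50),
                         tol = 0.05, max_iter = 50, condition_beats = 4,
                         condition_cl = 750) {
  if (!is.numeric(target_delay) || target_delay <= 0)
    stop(paste("calibration failure: target delay must be positive",
               "(a junction always delays)"), call. = FALSE)
  cond_cfg <- tissue_config(cells_per_layer = cells_per_layer,
                            d_p = d_p, d_v = d_v, e_r = 1)
  cond <- simulate_tissue(build_tissue(cond_cfg),
                          pacing_protocol(cl = condition_cl,
                                          n_beats = condition_beats,
                                          record_last = 1))
  if (is.na(activation_times(cond)[4 * cells_per_layer]))
    stop("calibration failure: conditioning beat does not conduct",
         call. = FALSE)
  state_c <- cond$final_state
  delay_at <- function(er) {
    cfg <- tissue_config(cells_per_layer = cells_per_layer,
                         d_p = d_p, d_v = d_v, e_r = er)
    res <- simulate_tissue(build_tissue(cfg),
                           pacing_protocol(cl = 120, n_beats = 1,
                                           record_last = 1),
                           output_dt = 0.05, state0 = state_c)
    tryCatch(pvj_delay(res, 1), error = function(e) Inf)
  }
  lo <- bracket[1]; hi <- bracket[2]
  de_lo <- delay_at(lo); de_hi <- delay_at(hi)
  if (!is.finite(de_hi))
    stop("calibration failure: conduction block across the whole bracket",
         call. = FALSE)
  if (!(de_hi <= target_delay && (de_lo >= target_delay)))
    stop(sprintf(paste0("calibration failure: bracket [%g, %g] does not ",
                        "straddle the target delay (%s..%s ms); expand the bracket"),
                 lo, hi, format(de_hi, digits = 4), format(de_lo, digits = 4)),
         call. = FALSE)
  hist <- data.frame(e_r = c(lo, hi), delay = c(de_lo, de_hi))
  it <- 0; mid <- NA; de_mid <- NA
  repeat {
    it <- it + 1
    mid <- sqrt(lo * hi)
    de_mid <- delay_at(mid)
    hist <- rbind(hist, data.frame(e_r = mid, delay = de_mid))
    if (is.finite(de_mid) && abs(de_mid - target_delay) < tol) break
    if (it >= max_iter)
      stop("calibration failure: bisection did not converge within tolerance",
           call. = FALSE)
    if (!is.finite(de_mid) || de_mid > target_delay) lo <- mid else hi <- mid
  }
  list(e_r = mid, achieved_delay = de_mid, iterations = it, history = hist)
}

#' Run the full calibration for a grid resolution
#'
#' Convenience wrapper: Purkinje CV, ventricular CV, then PVJ delay.
#'
#' @param cells_per_layer Strand resolution.
#' @param cv_purkinje,cv_ventricular,delay Calibration targets.
#' @return List with elements `d_p`, `d_v`, `e_r` and the full sub-results.
#' @export
calibrate_profile <- function(cells_per_layer = 50, cv_purkinje = 2,
                              cv_ventricular = 0.5, delay = 4.364) {
  dx <- 2.0 / (4 * cells_per_layer)
  p <- calibrate_diffusion("Purkinje", cv_purkinje, dx = dx)
  v <- calibrate_diffusion("ventricular", cv_ventricular, dx = dx)
  e <- calibrate_er(delay, d_p = p$d, d_v = v$d,
                    cells_per_layer = cells_per_layer)
  list(d_p = p$d, d_v = v$d, e_r = e$e_r,
       purkinje = p, ventricular = v, pvj = e)
}
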