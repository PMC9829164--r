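#' Write a simulation's voltage map to CSV
#'
#' Long header row of times, then one row per cell (cells on one axis, time
#' on the other, matching the map convention).
#'
#' @param result A `pvs_simulation`.
#' @param path Output file.
#' @export
write_simulation_csv <- function(result, path) {
  stopifnot(inherits(result, "pvs_simulation"))
  df <- as.data.frame(result$v)
  names(df) <- sprintf("t_%g", result$times)
  df <- cbind(cell = seq_len(nrow(df)), cell_type = result$cell_types, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a voltage-map CSV back into a minimal simulation object
#'
#' Supports analysis-only workflows on precomputed voltage maps: the
#' returned object carries times, voltages, cell types and stimulus times,
#' enough for every feature-extraction and classification function.
#'
#' @param path CSV written by [write_simulation_csv()].
#' @param cl Pacing cycle length of the recording (ms).
#' @param stim_times Stimulus times (ms); default: multiples of `cl`
#'   covering the recording.
#' @param dx Grid spacing (cm).
#' @param face_d Per-face diffusion coefficients (for pseudo-ECG); default:
#'   uniform 1.
#' @return A `pvs_simulation`.
#' @export
read_simulation_csv <- function(path, cl, stim_times = NULL, dx = 0.01,
                                face_d = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcols <- grep("^t_", names(df))
  times <- as.numeric(sub("^t_", "", names(df)[tcols]))
  v <- as.matrix(df[, tcols])
  dimnames(v) <- NULL
  if (is.null(stim_times))
    stim_times <- seq(0, max(times), by = cl)
  if (is.null(face_d)) face_d <- rep(1, nrow(v) - 1)
  record_last <- sum(stim_times >= min(times) - 1e-9)
  new_pvs_simulation(
    list(times = times, v = v, stim_times = stim_times, final_state = NULL),
    cl = cl, cell_types = as.character(df$cell_type), face_d = face_d,
    dx = dx, record_last = max(1L, record_last),
    config = list(from_csv = TRUE))
}

#' Write per-run sweep labels as JSON lines
#'
#' One JSON object per run: id, block levels, CL, category, subtype,
#' EAD conduction velocity and event count.
#'
#' @param sweep A [run_sweep()] result.
#' @param path Output file.
#' @export
write_labels_json <- function(sweep, path) {
  stopifnot(inherits(sweep, "pvs_sweep"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sweep))) {
    row <- as.list(as.data.frame(sweep)[i, ])
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Write a calibration report as JSON
#'
#' @param profile A [calibrate_profile()] result.
#' @param path Output file.
#' @export
write_calibration_json <- function(profile, path) {
  rep <- list(
    targets = list(cv_purkinje = 2, cv_ventricular = 0.5, pvj_delay = 4.364),
    d_p = profile$d_p, d_v = profile$d_v, e_r = profile$e_r,
    achieved = list(cv_purkinje = profile$purkinje$achieved_cv,
                    cv_ventricular = profile$ventricular$achieved_cv,
                    pvj_delay = profile$pvj$achieved_delay),
    iterations = list(purkinje = profile$purkinje$iterations,
                      ventricular = profile$ventricular$iterations,
                      pvj = profile$pvj$iterations))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
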