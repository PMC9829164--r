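#' Pseudo-ECG from a strand simulation
#'
#' Extracellular unipolar potential at a virtual electrode on the strand
#' axis, `electrode_distance` cm beyond the epicardial end:
#' `phi(t) = -K * sum_faces D_face * (dV/dx)|_face * d(1/r)/dx|_face * dx`,
#' with `r` the distance from each face midpoint to the electrode. `K = 1`:
#' amplitudes are in arbitrary units (sign is meaningful). With this
#' convention a depolarization wave travelling toward the electrode gives a
#' positive deflection, and epicardium repolarizing before midmyocardium an
#' upright T-wave.
#'
#' @param result A `pvs_simulation`.
#' @param electrode_distance Distance from the epicardial end (cm), > 0.
#' @param k Lead-field constant (default 1).
#' @return Object of class `pseudo_ecg`: `times` (ms), `phi`
#'   (arbitrary units), `electrode_distance`.
#' @export
compute_pseudo_ecg <- function(result, electrode_distance = 2.0, k = 1) {
  stopifnot(inherits(result, "pvs_simulation"))
  if (!is.numeric(electrode_distance) || electrode_distance <= 0)
    stop("electrode must lie outside the tissue (distance > 0)", call. = FALSE)
  n <- nrow(result$v)
  if (n < 2) stop("pseudo-ECG needs at least 2 cells", call. = FALSE)
  dx <- result$dx                                  # cm
  x_face <- (seq_len(n - 1)) * dx                  # face positions, cm
  x_e <- n * dx + electrode_distance
  r <- x_e - x_face
  wt <- -k * result$face_d / (r^2)                 # D * d(1/r)/dx * dx / dx
  dv <- diff(result$v)                             # (n-1) x T face differences
  phi <- as.numeric(crossprod(dv, wt))             # actually t(dv) %*% wt
  structure(list(times = result$times, phi = phi,
                 electrode_distance = electrode_distance, k = k,
                 cl = result$cl, stim_times = result$stim_times,
                 record_last = result$record_last),
            class = "pseudo_ecg")
}

#' @export
print.pseudo_ecg <- function(x, ...) {
  cat(sprintf("<pseudo_ecg> %d samples, electrode %.1f cm past the epicardium\n",
              length(x$phi), x$electrode_distance))
  invisible(x)
}

#' Per-cell repolarization times of a recorded beat
#'
#' Complete repolarization is the *last* downward crossing of `v_rep`
#' (default -70 mV) within the beat's analysis window, so EAD
#' re-depolarizations postpone the repolarization time. A cell whose voltage
#' is still above `v_rep` at the window end is marked unrepolarized (`NA`),
#' and a cell that never activates in the window (no upward crossing of
#' `v_act`; e.g. distal cells of a blocked beat, whose subthreshold
#' electrotonic humps are not action potentials) is also `NA`.
#'
#' @param result A `pvs_simulation`.
#' @param beat_index Recorded-beat index (default: last).
#' @param v_rep Repolarization threshold (mV).
#' @param v_act Activation threshold used for the primary-AP guard (mV).
#' @return Per-cell times (ms, relative to the beat's stimulus); `NA` =
#'   unrepolarized within the window or never activated.
#' @export
repolarization_times <- function(result, beat_index = NULL, v_rep = -70,
                                 v_act = -20) {
  stopifnot(inherits(result, "pvs_simulation"))
  bw <- beat_windows(result)
  if (is.null(beat_index)) beat_index <- nrow(bw)
  if (!beat_index %in% bw$beat)
    stop(sprintf("beat_index %s outside the recorded window", format(beat_index)),
         call. = FALSE)
  t0 <- bw$t_start[beat_index]; t1 <- bw$t_end[beat_index]
  w <- which(result$times >= t0 - 1e-9 & result$times < t1 - 1e-9)
  tt <- result$times[w]
  apply(result$v[, w, drop = FALSE], 1, function(v) {
    if (!any(v[-length(v)] < v_act & v[-1] >= v_act)) return(NA_real_)
    if (v[length(v)] > v_rep) return(NA_real_)     # ended depolarized
    i <- which(v[-length(v)] > v_rep & v[-1] <= v_rep)
    if (!length(i)) return(NA_real_)
    i1 <- i[length(i)]                             # last crossing
    tt[i1] + (v_rep - v[i1]) / (v[i1 + 1] - v[i1]) * (tt[i1 + 1] - tt[i1]) - t0
  })
}

#' QT interval and transmural dispersion of repolarization for one beat
#'
#' The QT interval is the time from the beat's stimulus to the last cell
#' reaching complete repolarization; `t_pe` (the Tpeak-end / TDR index) is
#' the difference between the first and last repolarization times.
#'
#' @param result A `pvs_simulation`.
#' @param beat_index Recorded-beat index (default: last).
#' @param v_rep Repolarization threshold (mV).
#' @return Object of class `beat_features`: `qt`, `t_pe` (ms; `NA` with
#'   `undefined = TRUE` when no cell repolarizes), `repol_times`,
#'   `first_repol_cell`, `last_repol_cell`, `n_unrepolarized`.
#' @export
compute_qt_tpe <- function(result, beat_index = NULL, v_rep = -70) {
  rt <- repolarization_times(result, beat_index, v_rep)
  ok <- which(!is.na(rt))
  if (!length(ok)) {
    return(structure(list(qt = NA_real_, t_pe = NA_real_, repol_times = rt,
                          first_repol_cell = NA_integer_,
                          last_repol_cell = NA_integer_,
                          n_unrepolarized = length(rt), undefined = TRUE),
                     class = "beat_features"))
  }
  first <- ok[which.min(rt[ok])]; last <- ok[which.max(rt[ok])]
  structure(list(qt = unname(rt[last]), t_pe = unname(rt[last] - rt[first]),
                 repol_times = rt, first_repol_cell = first,
                 last_repol_cell = last,
                 n_unrepolarized = sum(is.na(rt)), undefined = FALSE),
            class = "beat_features")
}

#' @export
print.beat_features <- function(x, ...) {
  if (isTRUE(x$undefined)) cat("<beat_features> undefined (no cell repolarized)\n")
  else cat(sprintf("<beat_features> QT = %.1f ms, Tpe = %.1f ms (%d unrepolarized)\n",
                   x$qt, x$t_pe, x$n_unrepolarized))
  invisible(x)
}

# T-wave window of one beat: [stim + qrs_blank, next stim), with baseline
# taken from the trailing diastolic samples of the window.
.twave_segment <- function(ecg, stim_time, t_end, qrs_blank) {
  w <- which(ecg$times >= stim_time + qrs_blank & ecg$times < t_end - 1e-9)
  if (length(w) < 5) return(NULL)
  phi <- ecg$phi[w]
  n <- length(phi)
  base <- median(phi[max(1, n - max(5, round(0.1 * n))):n])
  list(t = ecg$times[w] - stim_time, phi = phi - base)
}

.dominant_lobe <- function(seg) {
  pos <- max(seg$phi); neg <- -min(seg$phi)
  if (pos >= neg) list(sign = 1, amp = pos) else list(sign = -1, amp = neg)
}

# peaks of x with simple prominence (height above the higher of the two
# flanking minima)
.peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(i = integer(), prom = numeric()))
  i_pk <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(i_pk)) return(data.frame(i = integer(), prom = numeric()))
  prom <- vapply(i_pk, function(i) {
    left <- min(x[1:i]); right <- min(x[i:n])
    x[i] - max(left, right)
  }, numeric(1))
  data.frame(i = i_pk, prom = prom)
}

#' Reference T-wave metrics of a control beat
#'
#' Computes, from a control simulation at one cycle length, the quantities
#' against which relative morphology tags are judged: T-peak amplitude,
#' duration above half maximum, T-peak time and the control QT.
#'
#' @param result Control `pvs_simulation` at the cycle length of interest.
#' @param beat_index Recorded-beat index (default: last).
#' @param qrs_blank Blanking after the stimulus (ms, default 80) excluding
#'   the QRS-analog from the T-window.
#' @return List: `cl`, `qt`, `t_peak_amp`, `t_halfmax_width`, `t_peak_time`.
#' @export
control_reference <- function(result, beat_index = NULL, qrs_blank = 80) {
  stopifnot(inherits(result, "pvs_simulation"))
  bw <- beat_windows(result)
  if (is.null(beat_index)) beat_index <- nrow(bw)
  ecg <- compute_pseudo_ecg(result)
  feats <- compute_qt_tpe(result, beat_index)
  seg <- .twave_segment(ecg, bw$stim_time[beat_index], bw$t_end[beat_index],
                        qrs_blank)
  if (is.null(seg)) stop("control beat window too short", call. = FALSE)
  lobe <- .dominant_lobe(seg)
  s <- lobe$sign * seg$phi
  above <- s >= lobe$amp / 2
  dt <- median(diff(seg$t))
  list(cl = result$cl, qt = feats$qt, t_peak_amp = lobe$amp,
       t_halfmax_width = sum(above) * dt,
       t_peak_time = seg$t[which.max(s)])
}

#' Tag T-wave morphology of recorded beats
#'
#' Deterministic tags from documented operational rules, judged per beat on
#' the window from `qrs_blank` ms after the stimulus to the next stimulus:
#'
#' * polarity (`upright` / `inverted`): sign of the dominant lobe;
#' * `biphasic`: both signed lobes exceed the amplitude floor (5% of the
#'   control T-peak amplitude at the same CL);
#' * `notched`: two same-sign peaks with prominence above the floor;
#' * `broad_based`: duration above half maximum exceeds 1.5x the control
#'   T-wave duration;
#' * `late_pointed`: T-peak after 70% of the beat's QT interval and width at
#'   half maximum below 0.6x control.
#'
#' @param ecg A [compute_pseudo_ecg()] result.
#' @param beats Data frame with columns `stim_time`, `t_end` and `qt` (one
#'   row per beat to tag), e.g. assembled from [beat_windows()] and
#'   [compute_qt_tpe()].
#' @param control A [control_reference()] list for the same CL.
#' @param qrs_blank Post-stimulus blanking (ms).
#' @return List of character vectors (tag sets), one per beat.
#' @export
tag_twave_morphology <- function(ecg, beats, control, qrs_blank = 80) {
  stopifnot(inherits(ecg, "pseudo_ecg"))
  if (missing(control) || is.null(control))
    stop("a control reference is required for relative morphology tags",
         call. = FALSE)
  floor_amp <- 0.05 * control$t_peak_amp
  lapply(seq_len(nrow(beats)), function(b) {
    seg <- .twave_segment(ecg, beats$stim_time[b], beats$t_end[b], qrs_blank)
    if (is.null(seg)) return(character(0))
    tags <- character(0)
    lobe <- .dominant_lobe(seg)
    tags <- c(tags, if (lobe$sign > 0) "upright" else "inverted")
    pos <- max(seg$phi); neg <- -min(seg$phi)
    if (pos >= floor_amp && neg >= floor_amp) tags <- c(tags, "biphasic")
    pk <- .peaks(lobe$sign * seg$phi)
    if (sum(pk$prom >= floor_amp) >= 2) tags <- c(tags, "notched")
    s <- lobe$sign * seg$phi
    dt <- median(diff(seg$t))
    width <- sum(s >= lobe$amp / 2) * dt
    if (width > 1.5 * control$t_halfmax_width) tags <- c(tags, "broad_based")
    qt <- beats$qt[b]
    if (!is.na(qt)) {
      t_peak <- seg$t[which.max(s)]
      if (t_peak > 0.7 * qt && width < 0.6 * control$t_halfmax_width)
        tags <- c(tags, "late_pointed")
    }
    tags
  })
}
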