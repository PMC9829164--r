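#' Analysis thresholds
#'
#' Single configuration block for every operational constant of the
#' detection and classification layer. The defaults are the package's
#' documented choices (see the methods vignette for rationale):
#'
#' * `a_min` (mV): minimum net rise of a secondary upstroke (1 mV);
#' * `min_slope` (mV/ms) over `sustain_ms` (ms): slope qualification of the
#'   rise (0.05 mV/ms over >= 2 ms);
#' * `onset_blank_ms`: events starting within this window after the primary
#'   AP peak are ignored (50 ms) so the spike-notch-dome morphology of a
#'   normal action potential is not mistaken for an EAD;
#' * `tau_sync` (ms): synchrony span for spatial classification (20 ms);
#' * `n_osc`: successive events per cell that define oscillatory behaviour
#'   (3);
#' * `apd_alternans_ms`: beat-to-beat APD difference for alternans (5 ms);
#' * `prolongation_frac`: QT excess over control for the AP-prolongation
#'   class (0.10);
#' * `v_act`, `v_rep` (mV): activation / repolarization thresholds;
#' * `activation_frac`: fraction of cells that must activate for a beat to
#'   count as excitation (0.90).
#'
#' @param ... Named overrides of individual constants.
#' @return Named list of thresholds.
#' @export
analysis_thresholds <- function(...) {
  th <- list(a_min = 1, min_slope = 0.05, sustain_ms = 2,
             onset_blank_ms = 50, tau_sync = 20, n_osc = 3,
             apd_alternans_ms = 5, prolongation_frac = 0.10,
             v_act = -20, v_rep = -70, activation_frac = 0.90)
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  th[names(ov)] <- ov
  th
}

#' Detect early afterdepolarizations in a single voltage trace
#'
#' An EAD event is a secondary depolarizing upstroke during repolarization:
#' after the primary AP peak (and past a short post-upstroke blanking
#' window) and before final repolarization, every local minimum followed by
#' a net rise of at least `a_min` mV, with dV/dt of at least `min_slope`
#' sustained over `sustain_ms`, spawns one event. Onset is at the local
#' minimum (takeoff), amplitude is measured to the subsequent local maximum.
#' A window without a primary AP (no sample above `v_act`) yields no events.
#'
#' @param v Voltage samples (mV).
#' @param times Sample times (ms), same length as `v`.
#' @param window Length-2 time window to analyse; default the full trace.
#' @param th Thresholds from [analysis_thresholds()].
#' @return Data frame with one row per event: `onset_time`, `takeoff_v`,
#'   `amplitude`.
#' @export
#' @examples
#' t <- seq(0, 500, 0.5)
#' v <- ifelse(t < 300, 10 - 0.2 * t, -85)  # monotone repolarization
#' nrow(detect_eads(v, t))                   # 0
detect_eads <- function(v, times, window = range(times),
                        th = analysis_thresholds()) {
  empty <- data.frame(onset_time = numeric(0), takeoff_v = numeric(0),
                      amplitude = numeric(0))
  w <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(w) < 5) return(empty)
  v <- v[w]; t <- times[w]
  ip <- which.max(v)
  if (v[ip] < th$v_act) return(empty)            # no primary AP
  keep <- seq_along(v) > ip & t >= t[ip] + th$onset_blank_ms
  # analysis stops at final repolarization
  below <- which(keep & v <= th$v_rep)
  if (length(below)) keep[seq_along(v) >= below[1]] <- FALSE
  idx <- which(keep)
  if (length(idx) < 3) return(empty)
  v <- v[idx]; t <- t[idx]
  n <- length(v)
  out <- empty
  i <- 2
  while (i < n) {
    if (v[i] < v[i - 1] && v[i] <= v[i + 1]) {   # local minimum
      j <- i
      while (j < n && v[j + 1] >= v[j]) j <- j + 1
      if (v[j] - v[i] >= th$a_min && j > i) {
        sl <- diff(v[i:j]) / diff(t[i:j])
        ok_run <- rle(sl >= th$min_slope)
        step <- median(diff(t[i:j]))
        if (any(ok_run$values & ok_run$lengths * step >= th$sustain_ms))
          out <- rbind(out, data.frame(onset_time = t[i], takeoff_v = v[i],
                                       amplitude = v[j] - v[i]))
      }
      i <- j + 1
    } else i <- i + 1
  }
  out[order(out$onset_time), , drop = FALSE]
}

# Extended per-cell analysis window for one beat: from the beat's stimulus
# to the next stimulus, extended past it only while the beat's own action
# potential is still depolarized (so EADs of an AP that outlasts its pacing
# interval stay attributed to the beat where the AP began, but the next
# beat's upstroke foot never leaks in).
.cell_beat_window <- function(times, v, stim_time, next_stim, th) {
  i_ns <- which(times >= next_stim - 1e-9)
  if (!length(i_ns)) return(c(stim_time, max(times) + 1e-6))
  if (v[i_ns[1]] <= th$v_rep) return(c(stim_time, next_stim))
  t_end <- max(times) + 1e-6
  vv <- v[i_ns]
  down <- which(vv[-length(vv)] > th$v_rep & vv[-1] <= th$v_rep)
  up <- which(vv[-length(vv)] < th$v_act & vv[-1] >= th$v_act)
  stopt <- c(if (length(down)) times[i_ns[down[1] + 1]],
             if (length(up)) times[i_ns[up[1]]])
  if (length(stopt)) t_end <- min(stopt)
  c(stim_time, t_end)
}

#' Detect EADs in every cell and recorded beat of a simulation
#'
#' Applies [detect_eads()] per cell with per-beat analysis windows running
#' from each stimulus to the cell's next primary upstroke, so events of an
#' action potential that outlasts its pacing interval are attributed to the
#' beat where the AP began.
#'
#' Events whose onset coincides with a stimulus edge (within 1 ms before to
#' `stim_duration + 2` ms after any stimulus) are discarded: during an
#' action potential that spans its pacing interval, the next stimulus
#' produces a small forced depolarizing bump that is an artifact of the
#' pacing, not an EAD.
#'
#' @param result A `pvs_simulation`.
#' @param th Thresholds from [analysis_thresholds()].
#' @return Data frame: `cell_index`, `beat_index`, `onset_time` (relative to
#'   the beat's stimulus), `takeoff_v`, `amplitude`.
#' @export
detect_all_eads <- function(result, th = analysis_thresholds()) {
  stopifnot(inherits(result, "pvs_simulation"))
  bw <- beat_windows(result)
  stim_dur <- if (!is.null(result$config$stim_duration))
    result$config$stim_duration else 1
  all_stims <- result$stim_times
  out <- list()
  for (b in bw$beat) {
    stim <- bw$stim_time[b]
    nxt <- if (b < nrow(bw)) bw$stim_time[b + 1] else bw$t_end[b]
    for (i in seq_len(nrow(result$v))) {
      win <- .cell_beat_window(result$times, result$v[i, ], stim, nxt, th)
      ev <- detect_eads(result$v[i, ], result$times, win, th)
      if (nrow(ev)) {
        near_stim <- vapply(ev$onset_time, function(t0)
          any(t0 > all_stims - 1 & t0 < all_stims + stim_dur + 2),
          logical(1))
        ev <- ev[!near_stim, , drop = FALSE]
      }
      if (nrow(ev)) {
        ev$cell_index <- i; ev$beat_index <- b
        ev$onset_time <- ev$onset_time - stim
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (!length(out))
    return(data.frame(cell_index = integer(0), beat_index = integer(0),
                      onset_time = numeric(0), takeoff_v = numeric(0),
                      amplitude = numeric(0)))
  ev <- do.call(rbind, out)
  ev[, c("cell_index", "beat_index", "onset_time", "takeoff_v", "amplitude")]
}

#' Detect beat-to-beat alternans
#'
#' Alternans is flagged when (a) any cell's action-potential duration
#' differs by at least `apd_alternans_ms` between the last two beats
#' (APD-alternans), or (b) conduction alternates: a beat that reaches the
#' epicardial end followed by one that does not, the 2:1
#' stimulus-to-response pattern (conduction-alternans).
#'
#' @param apd Matrix of per-cell APD (cells x beats, ms; `NA` = no AP).
#' @param reached_end Logical vector per beat: did the beat activate the
#'   epicardial end?
#' @param th Thresholds.
#' @return List: `alternans` (logical), `type` (`"apd"`, `"conduction"` or
#'   `NA`), `max_delta_apd`.
#' @export
detect_alternans <- function(apd, reached_end, th = analysis_thresholds()) {
  if (is.null(dim(apd)) || ncol(apd) < 2)
    stop("alternans detection needs at least 2 recorded beats", call. = FALSE)
  nb <- ncol(apd)
  cond <- any(reached_end[-1] != reached_end[-length(reached_end)])
  d <- abs(apd[, nb] - apd[, nb - 1])
  max_d <- if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
  apd_alt <- isTRUE(max_d >= th$apd_alternans_ms)
  type <- if (cond) "conduction" else if (apd_alt) "apd" else NA_character_
  list(alternans = cond || apd_alt, type = type, max_delta_apd = max_d)
}

# per-beat, per-cell activation + APD summary used by the classifier
.beat_summary <- function(result, th) {
  bw <- beat_windows(result)
  n <- nrow(result$v)
  act <- matrix(NA_real_, n, nrow(bw))
  rep_ <- matrix(NA_real_, n, nrow(bw))
  for (b in bw$beat) {
    act[, b] <- activation_times(result, b, v_act = th$v_act)
    rep_[, b] <- repolarization_times(result, b, v_rep = th$v_rep)
  }
  apd <- rep_ - act
  reached_end <- !is.na(act[n, ])
  frac_act <- colMeans(!is.na(act))
  list(windows = bw, act = act, rep = rep_, apd = apd,
       reached_end = reached_end, frac_act = frac_act)
}

#' Classify a run into the five excitation-pattern categories
#'
#' Deterministic precedence: `no_excitation` (no recorded beat activates at
#' least 90% of cells) > `ead` (any detected EAD event) > `ap_alternans` >
#' `ap_prolongation` (QT exceeding the control QT at the same CL by more
#' than 10%) > `control`.
#'
#' @param result A `pvs_simulation`.
#' @param control_qt Control QT (ms) at the same cycle length.
#' @param events Optional precomputed [detect_all_eads()] table.
#' @param th Thresholds.
#' @return List: `category` (character), plus the underlying `events`,
#'   `alternans` detail, and per-beat `qt`.
#' @export
classify_run <- function(result, control_qt, events = NULL,
                         th = analysis_thresholds()) {
  stopifnot(inherits(result, "pvs_simulation"))
  if (missing(control_qt) || is.null(control_qt) || is.na(control_qt))
    stop("a control QT reference is required", call. = FALSE)
  sm <- .beat_summary(result, th)
  if (all(sm$frac_act < th$activation_frac))
    return(list(category = "no_excitation", events = NULL, alternans = NULL,
                qt = rep(NA_real_, nrow(sm$windows))))
  if (is.null(events)) events <- detect_all_eads(result, th)
  qt <- vapply(sm$windows$beat,
               function(b) compute_qt_tpe(result, b, v_rep = th$v_rep)$qt,
               numeric(1))
  alt <- detect_alternans(sm$apd, sm$reached_end, th)
  category <-
    if (nrow(events) > 0) "ead"
    else if (alt$alternans) "ap_alternans"
    else {
      qt_run <- qt[length(qt)]
      if (!is.na(qt_run) && qt_run > (1 + th$prolongation_frac) * control_qt)
        "ap_prolongation"
      else "control"
    }
  list(category = category, events = events, alternans = alt, qt = qt)
}

# contiguous groups of EAD-bearing cells
.cell_groups <- function(cells) {
  cells <- sort(unique(cells))
  if (!length(cells)) return(list())
  br <- c(0, which(diff(cells) > 1), length(cells))
  lapply(seq_len(length(br) - 1),
         function(k) cells[(br[k] + 1):br[k + 1]])
}

#' Classify the spatial pattern of EAD events
#'
#' Per-beat rules, evaluated with precedence
#' oscillatory > unidirectional > discordant > synchronized > localized:
#'
#' * `oscillatory_*`: any cell carries >= `n_osc` successive events; the
#'   pattern is `oscillatory_sustained` when that cell has not repolarized
#'   by the end of the recording, `oscillatory_self_terminated` otherwise;
#' * `unidirectional_antegrade` / `_retrograde`: first-event onset times are
#'   strictly monotone across the EAD-bearing region (>= 4 cells); direction
#'   is toward the epicardium (antegrade) or toward the Purkinje end;
#'   `ead_cv` is the 25%-75% probe velocity over that region (m/s);
#' * `discordant`: >= 2 separated cell groups whose median onsets differ by
#'   more than `tau_sync`;
#' * `synchronized`: all four tissue types carry events and the span of
#'   per-type median onsets is <= `tau_sync`;
#' * `localized`: events confined to a contiguous subset of layers with no
#'   onset-time spatial gradient.
#'
#' The run-level label is the highest-precedence per-beat label.
#'
#' @param events [detect_all_eads()] table (must be non-empty).
#' @param result The `pvs_simulation` the events came from.
#' @param th Thresholds.
#' @return List: `subtype`, `ead_cv` (m/s or `NA`), `per_beat`.
#' @export
classify_spatial_pattern <- function(events, result,
                                     th = analysis_thresholds()) {
  stopifnot(inherits(result, "pvs_simulation"))
  if (is.null(events) || nrow(events) == 0)
    stop("spatial classification requires category = ead (non-empty events)",
         call. = FALSE)
  types <- result$cell_types
  dx <- result$dx
  rank_of <- c(oscillatory_sustained = 7, oscillatory_self_terminated = 6,
               unidirectional_antegrade = 5, unidirectional_retrograde = 5,
               discordant = 4, synchronized = 3, localized = 2)
  per_beat <- list()
  for (b in sort(unique(events$beat_index))) {
    ev <- events[events$beat_index == b, ]
    label <- NULL; cv <- NA_real_
    # oscillatory: any cell with n_osc successive events
    osc_cells <- as.integer(names(which(table(ev$cell_index) >= th$n_osc)))
    if (length(osc_cells)) {
      end_v <- result$v[osc_cells, ncol(result$v)]
      label <- if (any(end_v > th$v_rep)) "oscillatory_sustained"
               else "oscillatory_self_terminated"
    }
    first <- stats::aggregate(onset_time ~ cell_index, data = ev, FUN = min)
    first <- first[order(first$cell_index), ]
    if (is.null(label) && nrow(first) >= 4) {
      d <- diff(first$onset_time)
      contiguous <- all(diff(first$cell_index) == 1)
      if (contiguous && all(d > 0)) {
        label <- "unidirectional_antegrade"
      } else if (contiguous && all(d < 0)) {
        label <- "unidirectional_retrograde"
      }
      if (!is.null(label)) {
        n <- nrow(first)
        i25 <- 1 + round(0.25 * (n - 1)); i75 <- 1 + round(0.75 * (n - 1))
        cv <- abs((first$cell_index[i75] - first$cell_index[i25]) * dx /
                  (first$onset_time[i75] - first$onset_time[i25])) * 10
      }
    }
    if (is.null(label)) {
      groups <- .cell_groups(first$cell_index)
      if (length(groups) >= 2) {
        med <- vapply(groups, function(g)
          median(first$onset_time[first$cell_index %in% g]), numeric(1))
        if (diff(range(med)) > th$tau_sync) label <- "discordant"
      }
    }
    if (is.null(label)) {
      ty <- types[first$cell_index]
      if (all(.CELL_TYPES %in% ty)) {
        med <- vapply(.CELL_TYPES, function(k)
          median(first$onset_time[ty == k]), numeric(1))
        if (diff(range(med)) <= th$tau_sync) label <- "synchronized"
      }
    }
    if (is.null(label)) label <- "localized"
    per_beat[[as.character(b)]] <- list(subtype = label, ead_cv = cv)
  }
  ranks <- vapply(per_beat, function(x) rank_of[[x$subtype]], numeric(1))
  top <- per_beat[[which.max(ranks)]]
  list(subtype = top$subtype, ead_cv = top$ead_cv, per_beat = per_beat)
}
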