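# Programmatic fixtures: synthetic voltage traces and minimal simulation
# objects used across the suite. Everything is built in code at test time.

# Wrap a voltage matrix into the simulation container the analysis layer
# consumes (cells x times; stimulus at t = 0 of each beat).
fake_simulation <- function(v, times, cl, stim_times = NULL,
                            cell_types = NULL, dx = 0.01, face_d = NULL,
                            record_last = NULL, stim_duration = 1) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (is.null(stim_times)) stim_times <- seq(0, max(times), by = cl)
  if (is.null(cell_types)) cell_types <- rep("M", nrow(v))
  if (is.null(face_d)) face_d <- rep(1, max(0, nrow(v) - 1))
  if (is.null(record_last))
    record_last <- sum(stim_times >= min(times) - 1e-9)
  pvscable:::new_pvs_simulation(
    list(times = times, v = v, stim_times = stim_times, final_state = NULL),
    cl = cl, cell_types = cell_types, face_d = face_d, dx = dx,
    record_last = max(1L, record_last),
    config = list(synthetic = TRUE, stim_duration = stim_duration))
}

# Square-pulse action potential: rest -85, plateau v_peak until apd, then
# rest again. Sampled every `dt` ms over one beat window of length cl.
square_ap <- function(cl = 1000, apd = 300, v_peak = 20, v_rest = -85,
                      dt = 0.5, upstroke_at = 1) {
  t <- seq(0, cl - dt, by = dt)
  v <- ifelse(t >= upstroke_at & t < upstroke_at + apd, v_peak, v_rest)
  list(t = t, v = v)
}

# Triangular AP with optional EAD bumps. Bumps are (onset, takeoff, peak,
# width) specifications inserted on the repolarization limb as piecewise
# linear deflections.
ramp_ap <- function(cl = 1000, apd = 350, v_peak = 30, v_rest = -85,
                    dt = 0.5, bumps = NULL) {
  t <- seq(0, cl - dt, by = dt)
  v <- rep(v_rest, length(t))
  up <- t >= 1 & t < 5
  v[up] <- v_rest + (v_peak - v_rest) * (t[up] - 1) / 4
  rep_ <- t >= 5 & t < apd
  v[rep_] <- v_peak - (v_peak - v_rest) * (t[rep_] - 5) / (apd - 5)
  if (!is.null(bumps)) {
    for (b in seq_len(nrow(bumps))) {
      on <- bumps$onset[b]; pk <- bumps$peak[b]; wd <- bumps$width[b]
      seg <- t >= on & t < on + wd
      tri <- 1 - abs((t[seg] - on - wd / 2) / (wd / 2))
      v[seg] <- pmax(v[seg], v[seg] + (pk - v[seg]) * tri)
    }
  }
  list(t = t, v = v)
}

# Independent brute-force EAD oracle: enumerate all strict local extrema of
# the post-peak, pre-repolarization segment and pair each minimum with the
# following maximum; keep pairs by amplitude and mean-slope rules. Shares no
# code with the production detector.
brute_force_eads <- function(v, times, th = analysis_thresholds()) {
  ip <- which.max(v)
  if (v[ip] < th$v_act) return(0L)
  sel <- seq_along(v) > ip & times >= times[ip] + th$onset_blank_ms
  below <- which(sel & v <= th$v_rep)
  if (length(below)) sel[below[1]:length(v)] <- FALSE
  v <- v[sel]; t <- times[sel]
  n <- length(v)
  if (n < 3) return(0L)
  d <- diff(v)
  mins <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  maxs <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cnt <- 0L
  for (i in mins) {
    j <- maxs[maxs > i]
    if (!length(j)) next
    j <- j[1]
    amp <- v[j] - v[i]
    if (amp < th$a_min) next
    sl <- diff(v[i:j]) / diff(t[i:j])
    runs <- rle(sl >= th$min_slope)
    dt <- t[2] - t[1]
    if (any(runs$values & runs$lengths * dt >= th$sustain_ms)) cnt <- cnt + 1L
  }
  cnt
}

# Small strand used by the heavier integration tests.
test_strand <- function(...) tissue_config(cells_per_layer = 10, ...)

# -- classification fixtures ------------------------------------------------

# strand-like fixture: 20 cells (5 per layer), two beats, constructed APs
fixture_strand <- function(apd_by_cell_beat, bumps_by_cell = NULL,
                           cl = 1000) {
  n <- nrow(apd_by_cell_beat)
  t <- seq(0, 2 * cl - 0.5, 0.5)
  v <- matrix(-85, n, length(t))
  for (b in 1:2) {
    off <- (b - 1) * cl
    for (i in 1:n) {
      apd <- apd_by_cell_beat[i, b]
      if (is.na(apd)) next
      seg <- t >= off + 1 & t < off + 1 + apd
      v[i, seg] <- 15 - 60 * (t[seg] - off - 1) / apd   # 15 -> -45 ramp
      v[i, t >= off + 1 + apd & t < off + 1 + apd + 4] <- -80
    }
  }
  if (!is.null(bumps_by_cell)) {
    for (r in seq_len(nrow(bumps_by_cell))) {
      i <- bumps_by_cell$cell[r]; on <- bumps_by_cell$onset[r]
      b <- bumps_by_cell$beat[r]
      off <- (b - 1) * cl
      seg <- t >= off + on & t < off + on + 30
      v[i, seg] <- v[i, seg] +
        12 * sin(pi * (t[seg] - off - on) / 30)
    }
  }
  fake_simulation(v, t, cl, cell_types = rep(c("P", "Endo", "M", "Epi"),
                                             each = n / 4))
}

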