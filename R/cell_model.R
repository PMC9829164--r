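#' @title Reference membrane model: parameters and state layout
#' @name cell-model
#' @description
#' The package ships a self-contained mammalian ventricular action-potential
#' model of Hodgkin-Huxley type. Membrane currents (all in uA/uF, V in mV,
#' time in ms):
#'
#' * `i_na`   fast sodium, `g_na * m^3 * h * j * (V - E_Na)`
#' * `i_nal`  late sodium, instantaneous activation, slow inactivation `h_l`
#' * `i_cal`  L-type calcium, gates `d` (activation) and `f` (slow
#'            voltage-dependent inactivation), driving force toward a
#'            Ca-dependent reversal `E_si = 7.7 - 13.0287 log(Ca_i)`
#' * `i_kr`   rapid delayed rectifier with activation `x_r` and an
#'            instantaneous inward-rectification factor
#' * `i_ks`   slow delayed rectifier, `g_ks * x_s^2 * (V - E_K)`
#' * `i_k1`   inward rectifier (instantaneous)
#' * `i_to`   transient outward, activation `r`, inactivation `s`
#' * `i_kp`   plateau potassium with slow inactivation gate `kp`; opposes
#'            early depolarizing domes and has largely inactivated by the
#'            time late repolarization failure (EADs) can develop
#' * `i_pump` electrogenic pump tracking a slow intracellular Ca pool
#'            (`ca_s`, relaxation time 1.5 s), i.e. recent pacing rate;
#'            supplies extra repolarizing drive at fast rates
#' * `i_naca` simple Na/Ca exchange term (inward, Ca-dependent)
#' * `i_b`    linear background current
#'
#' The state vector has 14 named components:
#' `v, m, h, j, d, f, xr, xs, r, s, hl, kp, cai, cas`
#' (11 gates in `[0,1]`, two Ca pools in mM, membrane potential in mV).
#'
#' Channel block enters through two multiplicative factors: `s_kr` and
#' `s_cal` are the fractions of IKr and ICaL conductance *remaining*
#' (1 = unblocked, 0 = complete block).
NULL

# Parameter vector layout; order must match the compiled kernel.
.PAR_NAMES <- c("g_na", "g_nal", "g_cal", "g_kr", "g_ks", "g_k1", "g_to",
                "k_naca", "g_b", "s_kr", "s_cal", "e_na", "e_k", "e_b",
                "tau_f_scale", "tau_xs_scale", "g_kp", "g_pump")

.STATE_NAMES <- c("v", "m", "h", "j", "d", "f", "xr", "xs", "r", "s",
                  "hl", "kp", "cai", "cas")

.GATE_NAMES <- .STATE_NAMES[2:12]

.CELL_TYPES <- c("P", "Endo", "M", "Epi")

#' Baseline parameter set of the reference ventricular model
#'
#' Maximal conductances (mS/uF), reversal potentials (mV) and kinetic scale
#' factors shared by all four tissue-type variants before transmural
#' multipliers are applied.
#'
#' @return Named numeric vector of model parameters.
#' @export
#' @examples
#' cell_parameters()["g_kr"]
cell_parameters <- function() {
  c(g_na = 2.8, g_nal = 0.0205, g_cal = 0.50, g_kr = 0.20, g_ks = 0.22,
    g_k1 = 0.45, g_to = 0.3, k_naca = 0.05, g_b = 0.01,
    s_kr = 1, s_cal = 1, e_na = 65, e_k = -87, e_b = -59.87,
    tau_f_scale = 2, tau_xs_scale = 1, g_kp = 0.24, g_pump = 2.5)
}

#' Transmural parameter multipliers
#'
#' Documented multipliers applied to the conductance block
#' `(g_na, g_nal, g_cal, g_kr, g_ks, g_k1, g_to)` of [cell_parameters()] to
#' produce the four tissue-type variants. The four variants differ only by
#' these factors, never by equations. The profile realizes: M cells with
#' elevated late sodium and reduced IKs (longest action potential),
#' epicardium with the largest transient-outward current, and a Purkinje
#' variant with stronger late sodium, reduced IK1 and a distinct Ito/IKs
#' balance. Na/Ca exchange is transmurally uniform (scaling 1).
#'
#' @return Numeric matrix, one row per cell type.
#' @export
transmural_multipliers <- function() {
  m <- rbind(
    P    = c(1.0, 1.2, 0.9, 1.1, 0.50, 0.6, 1.0),
    Endo = c(1.0, 1.0, 1.0, 1.0, 1.00, 1.0, 0.3),
    M    = c(1.0, 2.8, 1.0, 1.0, 0.35, 1.0, 0.6),
    Epi  = c(1.0, 0.6, 1.0, 1.7, 1.40, 1.0, 1.2))
  colnames(m) <- .PAR_NAMES[1:7]
  m
}

#' Channel-block scaling factors
#'
#' @param s_kr Fraction of IKr conductance remaining, in `[0, 1]`
#'   (`s_kr = 1 - S_Kr_block`).
#' @param s_cal Fraction of ICaL conductance remaining, in `[0, 1]`.
#' @return An object of class `channel_scaling`.
#' @export
#' @examples
#' channel_scaling(s_kr = 0.2, s_cal = 1)  # 80% IKr block
channel_scaling <- function(s_kr = 1, s_cal = 1) {
  for (nm in c("s_kr", "s_cal")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a single number in [0, 1], got %s",
                   nm, format(x)), call. = FALSE)
  }
  structure(list(s_kr = s_kr, s_cal = s_cal), class = "channel_scaling")
}

#' @export
print.channel_scaling <- function(x, ...) {
  cat(sprintf("<channel_scaling> s_kr = %g (%.0f%% IKr block), s_cal = %g (%.0f%% ICaL block)\n",
              x$s_kr, 100 * (1 - x$s_kr), x$s_cal, 100 * (1 - x$s_cal)))
  invisible(x)
}

#' Construct a cell model variant
#'
#' Builds the parameter set for one of the four tissue types by applying the
#' documented transmural multipliers and channel-block scalings to the
#' baseline parameters. Repeated calls with equal arguments yield identical
#' parameter sets.
#'
#' @param cell_type One of `"P"`, `"Endo"`, `"M"`, `"Epi"`.
#' @param scaling A [channel_scaling()] object.
#' @return An object of class `cell_model` with elements `cell_type`,
#'   `parameters` (named vector) and `scaling`.
#' @export
#' @examples
#' m <- make_cell("M", channel_scaling(s_kr = 0.5))
#' m$parameters[["g_kr"]]
make_cell <- function(cell_type, scaling = channel_scaling()) {
  if (!is.character(cell_type) || length(cell_type) != 1 ||
      !cell_type %in% .CELL_TYPES)
    stop(sprintf("unknown cell_type %s; must be one of %s",
                 deparse(cell_type), paste(.CELL_TYPES, collapse = ", ")),
         call. = FALSE)
  if (!inherits(scaling, "channel_scaling"))
    scaling <- do.call(channel_scaling, as.list(scaling))
  p <- cell_parameters()
  mult <- transmural_multipliers()[cell_type, ]
  p[names(mult)] <- p[names(mult)] * mult
  p["s_kr"] <- scaling$s_kr
  p["s_cal"] <- scaling$s_cal
  structure(list(cell_type = cell_type, parameters = p, scaling = scaling),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> type %s, s_kr = %g, s_cal = %g\n",
              x$cell_type, x$scaling$s_kr, x$scaling$s_cal))
  invisible(x)
}

#' Default initial state for paced simulations
#'
#' Gates at their resting values, diastolic Ca of 1e-4 mM, and the slow Ca
#' pool pre-set to a typical working-myocardium diastolic average (4e-3 mM)
#' so that paced simulations approach their rate-appropriate steady state
#' from a common reference (see the package vignette).
#'
#' @param v Initial membrane potential (mV).
#' @return Named numeric state vector.
#' @export
initial_state <- function(v = -85) {
  st <- c(v = v, m = 0, h = 1, j = 1, d = 0, f = 1, xr = 0, xs = 0,
          r = 0, s = 1, hl = 1, kp = 1, cai = 1e-4, cas = 4e-3)
  st
}

#' Documented resting state of the reference model
#'
#' The quiescent steady state reached by 20 s of unstimulated integration
#' (total ionic current < 1e-12 uA/uF at these values). Ventricular variants
#' rest at about -86.35 mV, the Purkinje variant at -85.94 mV.
#'
#' @param cell_type One of `"P"`, `"Endo"`, `"M"`, `"Epi"`.
#' @return Named numeric state vector.
#' @export
rest_state <- function(cell_type = "Endo") {
  cell_type <- match.arg(cell_type, .CELL_TYPES)
  tab <- list(
    P    = c(-85.935083, 1.32226e-03, 0.987744, 0.992181, 2.25840e-05, 1,
             1.85672e-04, 5.29526e-03, 2.14864e-08, 0.999991, 0.303579,
             0.999983, 1.03096e-04, 1.03102e-04),
    Endo = c(-86.352896, 1.23308e-03, 0.988837, 0.992827, 2.15008e-05, 1,
             1.75613e-04, 5.16510e-03, 2.00411e-08, 0.999991, 0.318251,
             0.999984, 1.03281e-04, 1.03287e-04),
    M    = c(-86.350144, 1.23365e-03, 0.988830, 0.992823, 2.15077e-05, 1,
             1.75677e-04, 5.16595e-03, 2.00503e-08, 0.999991, 0.318153,
             0.999984, 1.03282e-04, 1.03288e-04),
    Epi  = c(-86.353509, 1.23296e-03, 0.988838, 0.992828, 2.14992e-05, 1,
             1.75599e-04, 5.16491e-03, 2.00390e-08, 0.999991, 0.318273,
             0.999984, 1.03281e-04, 1.03287e-04))
  st <- tab[[cell_type]]
  names(st) <- .STATE_NAMES
  st
}

.check_state <- function(state) {
  if (length(state) != length(.STATE_NAMES))
    stop(sprintf("state must have %d components", length(.STATE_NAMES)),
         call. = FALSE)
  bad <- which(!is.finite(state))
  if (length(bad)) {
    nm <- if (!is.null(names(state))) names(state)[bad[1]]
          else .STATE_NAMES[bad[1]]
    stop(sprintf("invalid state: component `%s` is not finite", nm),
         call. = FALSE)
  }
  gates <- state[2:12]
  if (any(gates < 0 | gates > 1))
    stop("invalid state: gating variable outside [0, 1]", call. = FALSE)
  if (any(state[13:14] <= 0))
    stop("invalid state: ion concentration must be strictly positive",
         call. = FALSE)
  invisible(TRUE)
}

#' Evaluate membrane currents at a fixed state
#'
#' Deterministic and side-effect free. The IKr and ICaL entries scale
#' exactly linearly with the model's `s_kr` and `s_cal` factors.
#'
#' @param model A [make_cell()] model.
#' @param state Named state vector (see [initial_state()]).
#' @return List with `total` (uA/uF) and `currents`, a named vector with
#'   the per-current breakdown (`i_na`, `i_nal`, `i_cal`, `i_kr`, `i_ks`,
#'   `i_k1`, `i_to`, `i_kp`, `i_naca`, `i_pump`, `i_b`).
#' @export
#' @examples
#' m <- make_cell("Epi")
#' evaluate_currents(m, rest_state("Epi"))$total
evaluate_currents <- function(model, state) {
  stopifnot(inherits(model, "cell_model"))
  .check_state(state)
  out <- cell_currents_cpp(as.numeric(state), as.numeric(model$parameters))
  list(total = unname(out[["i_total"]]), currents = out[-1])
}

#' Advance the membrane state by one time step
#'
#' Gating variables use the exponential (Rush-Larsen) closed-form update and
#' are clamped to `[0, 1]`; concentrations use forward Euler. In single-cell
#' use the membrane potential is advanced too (`update_v = TRUE`); the
#' tissue solver owns the voltage update in coupled mode and calls this with
#' `update_v = FALSE`.
#'
#' @param model A [make_cell()] model.
#' @param state Named state vector.
#' @param dt Time step (ms); must be positive and at most 0.05 ms.
#' @param i_stim Stimulus current (uA/uF; negative = depolarizing).
#' @param update_v Advance `v` as well? Default `TRUE`.
#' @return The advanced state vector.
#' @export
step_state <- function(model, state, dt, i_stim = 0, update_v = TRUE) {
  stopifnot(inherits(model, "cell_model"))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (ms)", call. = FALSE)
  if (dt > 0.05)
    stop("`dt` exceeds the admissible step of 0.05 ms", call. = FALSE)
  .check_state(state)
  out <- cell_step_cpp(as.numeric(state), as.numeric(model$parameters),
                       dt, i_stim, update_v)
  names(out) <- .STATE_NAMES
  out
}

#' Pace a single cell
#'
#' Runs an isolated cell (no diffusion) under periodic stimulation and
#' returns the recorded trace as a one-cell simulation result, so all
#' tissue-level analysis functions apply unchanged.
#'
#' The single-cell standard stimulus is -80 uA/uF for 0.5 ms (about a 40 mV
#' displacement from rest).
#'
#' @param model A [make_cell()] model.
#' @param protocol A [pacing_protocol()].
#' @param stim_amplitude,stim_duration Stimulus current (uA/uF) and duration
#'   (ms).
#' @param output_dt Output sampling interval (ms).
#' @param state Initial state; defaults to [initial_state()].
#' @param dt_min,dt_max Adaptive time-step bounds (ms).
#' @return A `pvs_simulation` object (see [simulate_tissue()]).
#' @export
#' @examples
#' m <- make_cell("M")
#' res <- run_cell(m, pacing_protocol(cl = 1000, n_beats = 2))
#' max(res$v)  # AP peak
run_cell <- function(model, protocol, stim_amplitude = -80,
                     stim_duration = 0.5, output_dt = 0.5,
                     state = initial_state(), dt_min = 0.001, dt_max = 0.05) {
  stopifnot(inherits(model, "cell_model"), inherits(protocol, "pacing_protocol"))
  .check_state(state)
  out <- run_cable_cpp(matrix(as.numeric(state), ncol = 1),
                       matrix(as.numeric(model$parameters), ncol = 1),
                       numeric(0), 0.1, 0L, stim_amplitude, stim_duration,
                       protocol$cl, as.integer(protocol$n_beats),
                       as.integer(protocol$record_last),
                       output_dt, dt_min, dt_max)
  new_pvs_simulation(out, cl = protocol$cl, cell_types = model$cell_type,
                     face_d = numeric(0), dx = 0.1,
                     record_last = protocol$record_last,
                     config = list(single_cell = TRUE,
                                   scaling = model$scaling,
                                   stim_amplitude = stim_amplitude,
                                   stim_duration = stim_duration))
}
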