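---
title: "A one-dimensional Purkinje-ventricular strand: model, calibration and repolarization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A one-dimensional Purkinje-ventricular strand: model, calibration and repolarization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system

`pvscable` simulates electrical propagation along a 2 cm strand of the
Purkinje-ventricular system: 50 Purkinje (P), 50 endocardial (Endo), 50
midmyocardial (M) and 50 epicardial (Epi) cells coupled by gap junctions on
a cell-centred grid (dx = 100 um), governed by the monodomain cable
equation

$$\partial V/\partial t = \nabla (D \nabla V) - I_{ion},$$

with no-flux (sealed) ends. The diffusion coefficient is piecewise
constant per inter-cell face: `d_p` inside the Purkinje layer, `d_v` inside
and between the ventricular layers, and `e_r * d_v` on the single
Purkinje-ventricular junction (PVJ) face, the classical phenomenological
account of the abrupt source-load mismatch where a thin fiber meets the
ventricular wall. Stimuli are applied at the Purkinje end (default
-80 uA/uF for 1 ms over the first millimetre of tissue; a fixed physical
stimulus length excites the strand at any grid resolution).

Two block factors enter every simulation: `s_kr` and `s_cal`, the fraction
of rapid delayed-rectifier (IKr) and L-type calcium (ICaL) conductance
remaining. The package's central experiment is the map of excitation
patterns over (IKr block, ICaL block, pacing cycle length).

## The membrane model

The cited canine Purkinje and ventricular formulations are not
redistributed here; the package ships its own Hodgkin-Huxley-type
ventricular model (14 state variables) whose equations live in
`src/kernel.cpp` and whose parameters are printed by `cell_parameters()`.
Design intents, in order of priority:

* graded IKr block must produce early afterdepolarizations (EADs) in a
  rate-dependent way: present at slow pacing (CL >= 750 ms) under >= 50%
  block in an isolated midmyocardial cell, absent in control and at fast
  pacing;
* major ICaL block (>= 70%) must abolish the regenerative overshoot of a
  standard stimulated beat and, in tissue, excitation altogether;
* the M-cell variant repolarizes last (largest late sodium, smallest IKs);
  the epicardial variant repolarizes first, which makes the control T-wave
  of the pseudo-ECG upright;
* all four variants share one equation set and differ only by the
  multipliers in `transmural_multipliers()`.

The mechanistic skeleton: a deliberately small fast sodium current
(`g_na = 2.8 mS/uF`) together with the late sodium current carries the
foot of the wave, while the L-type current - activation centred at +5 mV,
slow voltage-dependent inactivation `f` - carries the upstroke dome and
the plateau. Because the dome is calcium-driven, removing 70% of ICaL
leaves a stimulated cell unable to cross 0 mV, and a propagating wave
without most of its ICaL dies mid-strand; this realizes the excitability
collapse under strong calcium block as an emergent property rather than a
threshold rule.

EADs arise as plateau oscillations of the fast (V, d) subsystem modulated
by slow `f`: during slowed repolarization V lingers near -10 mV where `f`
recovers faster than the declining plateau loses it, and the reactivated
window current re-depolarizes the cell. Three repolarizing mechanisms
decide whether that reignition wins:

* IKr, whose inward-rectification peak sits exactly in the reignition
  band - the reason graded IKr block is the principal EAD switch;
* a plateau potassium current (IKp) with a slow inactivation gate, strong
  early in the beat (opposing stimulated domes) and gone by the time EADs
  can develop;
* an electrogenic pump current tracking a slow intracellular calcium pool
  (`cas`, relaxation time 1.5 s). The pool integrates calcium influx over
  the preceding seconds and is therefore a beat-rate sensor: at short
  cycle lengths the pump supplies extra late repolarizing drive (EAD
  protection, APD shortening), at long cycle lengths it idles. Its early-
  and late-beat components are gated by the IKp inactivation state so that
  neither interferes with dome ignition.

The slow-pool initial value (4e-3 mM, `initial_state()`) corresponds to a
working-myocardium diastolic average rather than the quiescent limit, so
paced simulations approach their rate-appropriate steady state from a
common, protected reference instead of spending early beats in a spuriously
EAD-prone low-rate configuration.

`rest_state()` stores the quiescent equilibrium (about -86.35 mV
ventricular, -85.94 mV Purkinje; total membrane current < 1e-12 uA/uF),
computed once by 20 s of unstimulated integration.

## Numerics

Operator splitting with a shared adaptive step: gates use the Rush-Larsen
exponential update (clamped to [0, 1]), concentrations and voltage forward
Euler, diffusion the explicit flux-conservative second difference. The
step is `dt = min(dt_max, 0.5 / max|dV/dt|)` bounded to [0.001, 0.05] ms
and additionally capped by 80% of the explicit diffusion stability bound
`dx^2 / (2 max D)`. Output is sampled on a uniform grid (0.5 ms default;
calibration uses 0.05 ms around activation). The recorded window covers
the last `record_last` beats (2 by default, matching the convention of
analysing the final two beats of each run).

Determinism: identical inputs produce bit-identical trajectories; the
sweep's provenance hash witnesses this across reruns.

## Calibration

`calibrate_diffusion()` bisects D (geometric midpoints over the documented
bracket [0.01, 10] mm^2/ms) until the conduction velocity measured on a
single paced beat of a homogeneous strand - activation = first upward
crossing of -20 mV, probes at 25%/75% of the measurement segment - is
within 2% of the target (Purkinje 2 m/s, ventricular 0.5 m/s).

`calibrate_er()` bisects the junction ratio until the last-P-to-first-Endo
activation delay is within 0.05 ms of 4.364 ms. Junctional safety depends
strongly on the paced steady state (a first beat from rest carries nearly
four times the steady late-sodium availability), so the strand is first
conditioned by four beats at CL 750 ms with a securely conducting junction
and each probe applies one beat from that state. Conduction block at a
probe reads as an infinite delay, consistent with the delay being monotone
non-increasing in `e_r`.

The resulting profile is stored in `default_profile()` per grid
resolution (the coefficient reproducing a given velocity depends on dx on
a discrete cable). At the coarse test resolution (10 cells/layer,
dx = 0.5 mm) the junction is a single face and one carrying a 4.364 ms
delay cannot sustain 4 Hz conduction; the coarse profile therefore pairs
the calibrated velocities with the literature junction ratio E_R = 3.13.
The literature diffusion profile (D_P = 1.2, D_v = 0.1, E_R = 3.13) is
available as `default_profile(name = "paper-canine")`; it does not
reproduce the calibration targets under this membrane model.

## Feature extraction

* Activation: first upward crossing of -20 mV in the beat window (linear
  interpolation between samples).
* Complete repolarization: *last* downward crossing of -70 mV, so EAD
  re-depolarizations postpone it; cells still depolarized at the window
  end, or never activated in the window (subthreshold electrotonic humps
  of blocked beats are not action potentials), are marked unrepolarized.
* QT: stimulus to last repolarization; `t_pe` (the Tpeak-end / transmural
  dispersion index): last minus first repolarization.
* Pseudo-ECG: unipolar potential at an electrode 2 cm beyond the
  epicardial end along the strand axis,
  `phi = -K sum_f D_f (dV/dx)_f d(1/r)/dx dx` with K = 1 (arbitrary
  units). A wavefront travelling toward the electrode deflects phi
  positively; epicardium repolarizing first makes the control T upright.
* T-wave tags operate on the window from 80 ms after the stimulus to the
  next stimulus, baseline-corrected by the trailing diastolic samples:
  polarity from the dominant lobe; `biphasic` if both signed lobes exceed
  5% of the control T-peak amplitude; `notched` if two same-sign peaks
  exceed that floor in prominence; `broad_based` if the half-maximum
  duration exceeds 1.5x control; `late_pointed` if the peak falls after
  70% of QT with width below 0.6x control. The 5%, 1.5x, 70% and 0.6x
  constants are this module's interpretive layer, isolated in one place.

## EAD detection and classification

`analysis_thresholds()` is the single configuration block: a secondary
upstroke counts as an EAD if, after the primary AP peak plus a 50 ms
blanking window and before final repolarization, a local minimum is
followed by a net rise of >= 1 mV at >= 0.05 mV/ms sustained for >= 2 ms.
The blanking window exists because a normal spike-notch-dome morphology -
and the forced bump that an ineffective stimulus inflicts on a
still-depolarized cell - would otherwise satisfy the letter of the rule;
genuine EADs in this model take off hundreds of milliseconds after the
upstroke. Events of an action potential that outlasts its pacing interval
are attributed to the beat where the AP began, but onsets coinciding with
a stimulus edge are discarded as pacing artifacts.

Runs are classified with the precedence `no_excitation` (no recorded beat
activates >= 90% of cells) > `ead` (any event) > `ap_alternans` (any
cell's APD changing >= 5 ms between the last two beats, or 2:1
stimulus-to-response conduction) > `ap_prolongation` (QT > 1.1x control at
the same CL) > `control`. Spatial EAD subtypes follow the precedence
oscillatory (>= 3 successive events in one cell; sustained vs
self-terminated by whether the trace repolarizes before the recording
ends) > unidirectional (strictly monotone onsets across a contiguous
region of >= 4 cells, velocity from the 25%/75% probes) > discordant
(separated groups with median onsets > 20 ms apart) > synchronized (all
four layers within a 20 ms span) > localized (contiguous subset of
layers). Per-layer onset synchrony uses layer medians, robust to edge
cells near the junction.

## The sweep as the study's synthetic-data generator

`sweep_grid()` enumerates the full factorial: block levels 0, 0.1, ...,
1.0 on both channels (121 dual-block settings) by 16 cycle lengths (250 to
1000 ms in 50 ms steps), 1936 runs. The levels are deterministic; random
subsampling with an explicit seed is available but not the default, since
only exhaustive enumeration reproduces the 121-setting count.

`run_sweep()` simulates 10 beats per run and analyses the last two.
Each strand run starts from per-cell-type paced single-cell steady states
(20 conditioning beats per type): isolated cells are cheap to pace, the
coupled strand settles within a few beats, and without this the slow
calcium pool still drifts after ten strand beats at long cycle lengths,
which a two-beat APD comparison would misread as alternans.

The scaled-down reference sweep used by the acceptance checks runs
block levels {0, 0.2, 0.6, 1.0} on both channels by CL {250, 500, 750,
1000} ms on a 40-cell strand (10 cells/layer, same 2 cm length). Under the
shipped model this reproduces the qualitative region layout of the full
study design: EAD labels confined to the complete-IKr-block, long-CL
corner; no-excitation dominating the >= 70% ICaL-block band; alternans
concentrated at short cycle lengths; the control column clean at CL >=
500 ms.

## Known limitations

* The surrogate membrane model's control APD (about 280-300 ms at CL
  500-750 on the coarse strand) is longer than the canine originals', so
  at CL = 250 ms the distal strand conducts 2:1 even in control and the
  control column's fastest-rate entry classifies as conduction alternans
  rather than control.
* At complete IKr block combined with 80% ICaL block the wave limps
  through on alternate beats at long cycle lengths, yielding an alternans
  label where full excitation failure would be expected; and immediately
  below the EAD threshold two settings show beat-to-beat APD alternation
  at CL 750 ms (the period-doubling route to EADs).
* Absolute interval values (QT, Tpe in ms) belong to the surrogate model,
  not to the canine originals; only calibrated conduction quantities,
  combinatorics and qualitative pattern structure transfer.
* One dimension only: no branching Purkinje anatomy, no apicobasal or
  left-right heterogeneity, no bidomain effects; the PVJ ratio acts on a
  single symmetric face, with the conduction delay (not current
  asymmetry) as the calibrated observable.
* Passing the synthetic-sweep checks demonstrates internal consistency of
  solver, detector and classifier under this model; it does not validate
  the surrogate against animal recordings.

## A worked example

```{r example}
library(pvscable)

cfg <- tissue_config(cells_per_layer = 10)        # 40-cell test strand
blocked <- build_tissue(cfg, channel_scaling(s_kr = 0, s_cal = 1))
res <- simulate_tissue(blocked, pacing_protocol(cl = 750, n_beats = 10))

feats <- compute_qt_tpe(res)
events <- detect_all_eads(res)
cls <- classify_run(res, control_qt = 282.4)
pat <- classify_spatial_pattern(events, res)

plot_voltage_map(res)
plot(compute_pseudo_ecg(res)$times, compute_pseudo_ecg(res)$phi,
     type = "l", xlab = "time (ms)", ylab = "pseudo-ECG (a.u.)")
```
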