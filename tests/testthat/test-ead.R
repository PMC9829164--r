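test_that("monotone repolarization and sub-threshold ripples yield no events", {
  ap <- ramp_ap(apd = 350)
  expect_identical(nrow(detect_eads(ap$v, ap$t)), 0L)
  ripples <- ramp_ap(apd = 350, bumps = data.frame(
    onset = c(120, 160, 200), peak = c(NA, NA, NA), width = 20))
  # 0.5 mV ripples: add them explicitly below A_min
  v <- ramp_ap(apd = 350)$v
  for (on in c(120, 160, 200)) {
    seg <- ap$t >= on & ap$t < on + 16
    v[seg] <- v[seg] + 0.5 * sin(seq(0, pi, length.out = sum(seg)))
  }
  expect_identical(nrow(detect_eads(v, ap$t)), 0L)
})

test_that("the detector recovers a constructed takeoff and amplitude", {
  # plateau falling to -22 mV, then a 31.18 mV secondary upstroke
  t <- seq(0, 799.5, 0.5)
  v <- rep(-85, length(t))
  v[t >= 1 & t < 300] <- 30 - 52 * (t[t >= 1 & t < 300] / 300)  # 30 -> -22
  bump <- t >= 300 & t < 360
  v[bump] <- -22 + 31.18 * sin(pi * (t[bump] - 300) / 60)
  v[t >= 360 & t < 420] <- -22 - 63 * (t[t >= 360 & t < 420] - 360) / 60
  ev <- detect_eads(v, t)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$takeoff_v, -22, tolerance = 0.6)      # within one sample
  expect_equal(ev$amplitude, 31.18, tolerance = 0.6)
  expect_gt(ev$onset_time, 250)
})

test_that("detector matches the brute-force extremum-scan oracle", {
  set.seed(314)
  th <- analysis_thresholds()
  for (k in 1:40) {
    nb <- sample(0:3, 1)
    bumps <- if (nb > 0) data.frame(
      onset = sort(runif(nb, 120, 300)),
      peak = runif(nb, -30, 10),
      width = runif(nb, 10, 40)) else NULL
    ap <- ramp_ap(apd = 380, bumps = bumps)
    got <- nrow(detect_eads(ap$v, ap$t, th = th))
    want <- brute_force_eads(ap$v, ap$t, th)
    expect_identical(got, want)
  }
})

test_that("alternans detection separates APD from conduction alternans", {
  th <- analysis_thresholds()
  same <- cbind(c(200, 210), c(200, 210))
  expect_false(detect_alternans(same, c(TRUE, TRUE), th)$alternans)

  apd <- cbind(c(200, 205), c(230, 204))
  out <- detect_alternans(apd, c(TRUE, TRUE), th)
  expect_true(out$alternans)
  expect_identical(out$type, "apd")

  out2 <- detect_alternans(same, c(TRUE, FALSE), th)
  expect_true(out2$alternans)
  expect_identical(out2$type, "conduction")

  expect_error(detect_alternans(matrix(200, 2, 1), TRUE, th), "2 recorded")
})

test_that("classification follows the documented precedence order", {
  th <- analysis_thresholds()
  apd <- matrix(400, 20, 2)
  # no excitation: all traces flat
  flat <- fake_simulation(matrix(-85, 20, 4000), seq(0, 1999.5, 0.5), 1000,
                          cell_types = rep(c("P", "Endo", "M", "Epi"), each = 5))
  expect_identical(classify_run(flat, control_qt = 300, th = th)$category,
                   "no_excitation")
  # EAD beats alternans: one cell with a bump AND alternating APDs
  apd_alt <- cbind(rep(350, 20), rep(420, 20))
  bumps <- data.frame(cell = 11, onset = 200, beat = 2)
  res <- fixture_strand(apd_alt, bumps)
  out <- classify_run(res, control_qt = 400, th = th)
  expect_identical(out$category, "ead")
  # alternans beats prolongation
  res2 <- fixture_strand(apd_alt)
  expect_identical(classify_run(res2, control_qt = 400, th = th)$category,
                   "ap_alternans")
  # prolongation beats control
  res3 <- fixture_strand(matrix(420, 20, 2))
  expect_identical(classify_run(res3, control_qt = 300, th = th)$category,
                   "ap_prolongation")
  res4 <- fixture_strand(matrix(310, 20, 2))
  expect_identical(classify_run(res4, control_qt = 300, th = th)$category,
                   "control")
  expect_error(classify_run(res4, control_qt = NULL), "control")
})

test_that("spatial patterns are recovered from constructed event sets", {
  th <- analysis_thresholds()
  base_apd <- matrix(500, 20, 2)

  # synchronized: all four types, onsets within 10 ms
  bumps <- data.frame(cell = c(2, 7, 12, 17),
                      onset = c(300, 304, 308, 302), beat = 2)
  res <- fixture_strand(base_apd, bumps)
  ev <- detect_all_eads(res, th)
  expect_identical(classify_spatial_pattern(ev, res, th)$subtype,
                   "synchronized")

  # localized: M layer only, common onset
  bumps <- data.frame(cell = 11:14, onset = rep(300, 4), beat = 2)
  res <- fixture_strand(base_apd, bumps)
  ev <- detect_all_eads(res, th)
  expect_identical(classify_spatial_pattern(ev, res, th)$subtype, "localized")

  # unidirectional antegrade at 0.2 m/s: 0.5 ms per 100 um cell
  bumps <- data.frame(cell = 9:16, onset = 300 + 0.5 * (0:7), beat = 2)
  res <- fixture_strand(base_apd, bumps)
  ev <- detect_all_eads(res, th)
  sp <- classify_spatial_pattern(ev, res, th)
  expect_identical(sp$subtype, "unidirectional_antegrade")
  expect_equal(sp$ead_cv, 0.2, tolerance = 0.05 * 0.2)

  # retrograde: onsets decreasing toward the Purkinje end
  bumps <- data.frame(cell = 9:16, onset = 300 + 0.5 * (7:0), beat = 2)
  res <- fixture_strand(base_apd, bumps)
  ev <- detect_all_eads(res, th)
  expect_identical(classify_spatial_pattern(ev, res, th)$subtype,
                   "unidirectional_retrograde")

  # discordant: two separated groups, onsets 60 ms apart
  bumps <- data.frame(cell = c(3, 4, 16, 17), onset = c(300, 300, 360, 360),
                      beat = 2)
  res <- fixture_strand(base_apd, bumps)
  ev <- detect_all_eads(res, th)
  expect_identical(classify_spatial_pattern(ev, res, th)$subtype, "discordant")

  # oscillatory: one cell with three successive bumps, trace repolarizes
  bumps <- data.frame(cell = 12, onset = c(250, 320, 390), beat = 2)
  res <- fixture_strand(base_apd, bumps)
  ev <- detect_all_eads(res, th)
  expect_identical(classify_spatial_pattern(ev, res, th)$subtype,
                   "oscillatory_self_terminated")

  expect_error(classify_spatial_pattern(ev[0, ], res, th), "ead")
})

test_that("labels do not depend on cell processing order", {
  th <- analysis_thresholds()
  bumps <- data.frame(cell = c(2, 7, 12, 17), onset = c(300, 304, 308, 302),
                      beat = 2)
  res <- fixture_strand(matrix(500, 20, 2), bumps)
  ev <- detect_all_eads(res, th)
  set.seed(5)
  for (k in 1:5) {
    perm <- ev[sample(nrow(ev)), ]
    expect_identical(classify_spatial_pattern(perm, res, th)$subtype,
                     classify_spatial_pattern(ev, res, th)$subtype)
  }
})
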