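test_that("pseudo-ECG of a spatially uniform map is identically zero", {
  t <- seq(0, 500, 0.5)
  v <- matrix(rep(-85 + 100 * sin(t / 80), each = 20), nrow = 20, byrow = FALSE)
  res <- fake_simulation(v, t, cl = 500)
  expect_true(all(compute_pseudo_ecg(res)$phi == 0))
})

test_that("mirrored voltage maps flip the pseudo-ECG sign", {
  # reflection with the electrode mirrored flips the lead field's sign; on
  # a two-cell strand the single face makes the identity exact with the
  # same electrode position
  set.seed(7)
  t <- seq(0, 100, 0.5)
  v <- matrix(runif(2 * length(t), -85, 30), nrow = 2)
  a <- compute_pseudo_ecg(fake_simulation(v, t, 100, face_d = 0.4))
  b <- compute_pseudo_ecg(fake_simulation(v[2:1, ], t, 100, face_d = 0.4))
  expect_equal(b$phi, -a$phi, tolerance = 1e-12)
  # for a longer strand, mirror the lead-field weights explicitly
  v2 <- matrix(runif(30 * length(t), -85, 30), nrow = 30)
  fd <- rep(0.4, 29)
  a2 <- compute_pseudo_ecg(fake_simulation(v2, t, 100, face_d = fd))
  dvm <- diff(v2[30:1, ])
  x_face <- seq_len(29) * 0.01
  r <- 30 * 0.01 + 2 - x_face
  manual <- as.numeric(crossprod(dvm, -0.4 / rev(r)^2))
  b2 <- compute_pseudo_ecg(fake_simulation(v2[30:1, ], t, 100, face_d = fd))
  expect_equal(-manual, a2$phi, tolerance = 1e-9)
})

test_that("the pseudo-ECG is linear in the voltage map", {
  set.seed(11)
  t <- seq(0, 50, 0.5)
  v1 <- matrix(runif(10 * length(t), -85, 30), nrow = 10)
  v2 <- matrix(runif(10 * length(t), -85, 30), nrow = 10)
  fd <- runif(9, 0.1, 1)
  phi <- function(v) compute_pseudo_ecg(fake_simulation(v, t, 50,
                                                        face_d = fd))$phi
  expect_equal(phi(2 * v1 - 3 * v2), 2 * phi(v1) - 3 * phi(v2),
               tolerance = 1e-9)
})

test_that("the electrode must lie outside the tissue", {
  res <- fake_simulation(matrix(-85, 5, 10), seq(0, 4.5, 0.5), cl = 10)
  expect_error(compute_pseudo_ecg(res, electrode_distance = 0), "outside")
  expect_error(compute_pseudo_ecg(res, electrode_distance = -1), "outside")
})

test_that("repolarization times follow the last-crossing rule", {
  ap <- square_ap(cl = 1000, apd = 300)
  res <- fake_simulation(ap$v, ap$t, cl = 1000)
  expect_equal(repolarization_times(res, 1), 301, tolerance = 1)

  # an EAD re-crossing -70 at 400 then finally at 520 -> 520
  t <- seq(0, 999.5, 0.5)
  v <- rep(-85, length(t))
  v[t >= 1 & t < 400] <- 20 - 90 * (t[t >= 1 & t < 400] / 400)  # to -70 at 400
  v[t >= 400 & t < 520] <- -50                                  # EAD plateau
  res2 <- fake_simulation(v, t, cl = 1000)
  expect_equal(repolarization_times(res2, 1), 520, tolerance = 1)

  # never repolarizing -> unrepolarized marker, excluded from t_pe
  vkeep <- ifelse(t < 1, -85, 0)
  res3 <- fake_simulation(rbind(v, vkeep), t, cl = 1000,
                          cell_types = c("M", "M"))
  rt <- repolarization_times(res3, 1)
  expect_true(is.na(rt[2]) && !is.na(rt[1]))
  f <- compute_qt_tpe(res3, 1)
  expect_identical(f$n_unrepolarized, 1L)
  expect_equal(f$t_pe, 0)
})

test_that("QT and Tpe are exact on constructed repolarization maps", {
  t <- seq(0, 999.5, 0.5)
  mk_trace <- function(rt) {
    v <- rep(-85, length(t)); v[t >= 1 & t < rt] <- 10; v
  }
  v <- rbind(mk_trace(200), mk_trace(230), mk_trace(260))
  res <- fake_simulation(v, t, cl = 1000, cell_types = rep("M", 3))
  f <- compute_qt_tpe(res, 1)
  expect_equal(f$qt, 260, tolerance = 1)
  expect_equal(f$t_pe, 60, tolerance = 1)
  expect_identical(f$first_repol_cell, 1L)
  expect_identical(f$last_repol_cell, 3L)

  # equal repolarization everywhere -> t_pe = 0
  res_eq <- fake_simulation(rbind(mk_trace(240), mk_trace(240)), t, 1000,
                            cell_types = c("M", "M"))
  expect_equal(compute_qt_tpe(res_eq, 1)$t_pe, 0, tolerance = 1e-9)
})

test_that("per-beat QT captures beat-to-beat alternation on paired beats", {
  t <- seq(0, 1999.5, 0.5)
  v <- rep(-85, length(t))
  v[t >= 1 & t < 320] <- 10        # beat 1 repolarizes at 320
  v[t >= 1001 & t < 1600] <- 10    # beat 2 at stimulus + 600
  res <- fake_simulation(v, t, cl = 1000)
  expect_equal(compute_qt_tpe(res, 1)$qt, 320, tolerance = 1)
  expect_equal(compute_qt_tpe(res, 2)$qt, 600, tolerance = 1)
})

test_that("Tpe is shift-invariant while QT shifts one-for-one", {
  t <- seq(0, 999.5, 0.5)
  mk <- function(rt) { v <- rep(-85, length(t)); v[t >= 1 & t < rt] <- 10; v }
  base <- fake_simulation(rbind(mk(200), mk(260)), t, 1000,
                          cell_types = c("M", "M"))
  shifted <- fake_simulation(rbind(mk(200), mk(260)), t, 1000,
                             stim_times = -40,
                             cell_types = c("M", "M"))
  f0 <- compute_qt_tpe(base, 1)
  # shifting the stimulus reference by -40 ms adds 40 ms to QT only
  f1 <- compute_qt_tpe(shifted, 1)
  expect_equal(f1$qt - f0$qt, 40, tolerance = 1)
  expect_equal(f1$t_pe, f0$t_pe, tolerance = 1e-9)
})

test_that("T-wave tagging recovers constructed morphologies", {
  ctrl <- list(cl = 500, qt = 300, t_peak_amp = 1, t_halfmax_width = 60,
               t_peak_time = 250)
  t <- seq(0, 499.5, 0.5)
  gauss <- function(mu, sd, amp) amp * exp(-((t - mu) / sd)^2)
  mk_ecg <- function(phi) structure(
    list(times = t, phi = phi, electrode_distance = 2, k = 1, cl = 500,
         stim_times = 0, record_last = 1), class = "pseudo_ecg")
  beats <- data.frame(stim_time = 0, t_end = 500, qt = 300)

  tags <- tag_twave_morphology(mk_ecg(-gauss(250, 30, 1)), beats, ctrl)[[1]]
  expect_true("inverted" %in% tags)
  expect_false("biphasic" %in% tags)

  tags <- tag_twave_morphology(mk_ecg(gauss(220, 20, 1) - gauss(300, 20, 1)),
                               beats, ctrl)[[1]]
  expect_true("biphasic" %in% tags)

  tags <- tag_twave_morphology(mk_ecg(gauss(220, 18, 1) + gauss(290, 18, 0.8)),
                               beats, ctrl)[[1]]
  expect_true(all(c("notched", "upright") %in% tags))

  # duration above half max ~ 2.35 sd: sd 60 -> width ~141 > 1.5 x 60
  tags <- tag_twave_morphology(mk_ecg(gauss(250, 60, 1)), beats, ctrl)[[1]]
  expect_true("broad_based" %in% tags)

  # late, narrow peak: after 70% of QT and width < 0.6 x control
  tags <- tag_twave_morphology(mk_ecg(gauss(260, 10, 1)), beats, ctrl)[[1]]
  expect_true("late_pointed" %in% tags)

  expect_error(tag_twave_morphology(mk_ecg(gauss(250, 30, 1)), beats, NULL),
               "control")
})

test_that("tagging is a pure function of its window and reference", {
  ctrl <- list(cl = 500, qt = 300, t_peak_amp = 1, t_halfmax_width = 60,
               t_peak_time = 250)
  t <- seq(0, 499.5, 0.5)
  phi <- exp(-((t - 240) / 25)^2) - 0.4 * exp(-((t - 320) / 25)^2)
  ecg <- structure(list(times = t, phi = phi, electrode_distance = 2, k = 1,
                        cl = 500, stim_times = 0, record_last = 1),
                   class = "pseudo_ecg")
  beats <- data.frame(stim_time = 0, t_end = 500, qt = 300)
  expect_identical(tag_twave_morphology(ecg, beats, ctrl),
                   tag_twave_morphology(ecg, beats, ctrl))
})

test_that("the control T-wave of the strand is upright", {
  res <- simulate_tissue(build_tissue(test_strand()),
                         pacing_protocol(cl = 750, n_beats = 6))
  cr <- control_reference(res)
  ecg <- compute_pseudo_ecg(res)
  bw <- beat_windows(res)
  beats <- data.frame(stim_time = bw$stim_time[2], t_end = bw$t_end[2],
                      qt = compute_qt_tpe(res, 2)$qt)
  tags <- tag_twave_morphology(ecg, beats, cr)[[1]]
  expect_true("upright" %in% tags)
  expect_false("inverted" %in% tags)
})

test_that("80% IKr block prolongs QT beyond control at CL 750", {
  cfg <- test_strand()
  ctrl <- simulate_tissue(build_tissue(cfg), pacing_protocol(750, 6))
  blocked <- simulate_tissue(build_tissue(cfg, channel_scaling(s_kr = 0.2)),
                             pacing_protocol(750, 6))
  # under strong block some beats fail distally (2:1); compare the captured
  # beat of the recorded pair against control
  qt_blocked <- max(compute_qt_tpe(blocked, 1)$qt,
                    compute_qt_tpe(blocked, 2)$qt, na.rm = TRUE)
  expect_gt(qt_blocked, compute_qt_tpe(ctrl)$qt)
})
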