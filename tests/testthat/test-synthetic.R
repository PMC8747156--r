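noiseless_config <- function(...) {
  scenario_config(noise = list(force_sd = 0, quat_deg_sd = 0,
                               angle_deg_sd = 0, garment_sd = 0), ...)
}

test_that("generated force pulses round-trip through event detection", {
  # rectangular: duration within one sample, peak exact, below-threshold none
  f <- simulate_force_pulse(50, 0.3, "rectangular", t0 = 1)
  ev <- detect_events(f)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$peak_magnitude, 50)
  expect_lt(abs(ev$duration - 0.3), 1 / 30 + 1e-9)

  expect_identical(nrow(detect_events(simulate_force_pulse(4, 0.3))), 0L)

  # raised-cosine: the full-pulse impulse is peak * duration / 2 and the
  # extended trapezoid recovers it within 1%
  f2 <- simulate_force_pulse(47, 0.35, "raised-cosine", t0 = 1)
  ev2 <- detect_events(f2)
  expect_identical(nrow(ev2), 1L)
  expect_equal(ev2$peak_magnitude, 47, tolerance = 0.01)
  expect_equal(ev2$impulse, 47 * 0.35 / 2, tolerance = 0.01)
})

test_that("simulated responses have the analytic peak and scale linearly", {
  seg <- test_seg()
  model <- response_model()
  # zero impulse: identically zero angles
  j0 <- simulate_response(0, model, seg, plane = "AP")
  expect_identical(max(abs(j0$q_ankle)), 0)

  j1 <- simulate_response(10, model, seg, plane = "AP", t0 = 1, t_end = 8)
  qs1 <- compute_qsway(sagittal_com(j1, seg))
  expect_equal(max(qs1$q_sway), response_peak(10, model), tolerance = 0.02)
  j2 <- simulate_response(20, model, seg, plane = "AP", t0 = 1, t_end = 8)
  qs2 <- compute_qsway(sagittal_com(j2, seg))
  expect_equal(max(qs2$q_sway), 2 * max(qs1$q_sway), tolerance = 1e-9)

  # the frontal inversion reproduces the target sway through the hip
  j3 <- simulate_response(15, model, seg, plane = "ML", direction = -1,
                          t0 = 1, t_end = 8)
  qs3 <- compute_qsway(frontal_com(j3, seg))
  expect_equal(min(qs3$q_sway), -response_peak(15, model), tolerance = 0.02)
  expect_identical(max(abs(j3$q_ankle)), 0)

  expect_error(response_model(zeta = 1.4), "zeta")
  expect_error(response_model(omega_n = -1), "positive")
})

test_that("underdamped responses match a numerically located peak", {
  model <- response_model(gain = 0.1, omega_n = 6, zeta = 0.4)
  tt <- seq(0, 10, by = 1e-4)
  num_peak <- max(response_curve(tt, 12, model)$q_sway)
  expect_equal(response_peak(12, model), num_peak, tolerance = 1e-6)
  # closed-form velocity is the derivative of the closed-form angle
  q <- response_curve(tt, 12, model)$q_sway
  v <- response_curve(tt, 12, model)$velocity
  expect_equal(v[2:1000], diff(q[1:1000]) / 1e-4, tolerance = 1e-2)
})

test_that("garment simulation drives the target zone's sensors", {
  t <- (0:89) / 30
  ev <- data.frame(onset_t = 1, offset_t = 1.35, zone = "mid back",
                   bleed = TRUE)
  g <- simulate_garment(t, ev, noise_sd = 0)
  cal <- data.frame(t = (1:200) / 30,
                    matrix(rep(100 + 0.2 * (1:30), each = 200), nrow = 200))
  names(cal) <- c("t", paste0("s", 1:30))
  thr <- calibrate_garment(cal)
  r <- resolve_location(g, thr, 1, 1.35)
  expect_identical(r$zone, "mid back")
  # bleed leaves at least one in-zone sensor among the four most active
  expect_true(any(r$active_ids %in% c(1L, 2L, 29L, 30L)))

  # outside the event nothing is active
  r_pre <- resolve_location(g, thr, 0, 0.9)
  expect_identical(r_pre$zone, NA_character_)
  expect_error(simulate_garment(t, data.frame(onset_t = 1, offset_t = 2,
                                              zone = "nowhere",
                                              bleed = FALSE)),
               "unknown zone")
})

test_that("session generation is deterministic under a seed", {
  cfg <- scenario_config(protocol = build_protocol()[1:2, ])
  s1 <- generate_session(cfg, seed = 99)
  s2 <- generate_session(cfg, seed = 99)
  expect_identical(s1, s2)
  s3 <- generate_session(cfg, seed = 100)
  expect_false(identical(s1$streams$force, s3$streams$force))

  d1 <- file.path(tempdir(), "sess_a"); d2 <- file.path(tempdir(), "sess_b")
  write_session(s1, d1); write_session(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("noiseless generated events are recovered faithfully", {
  cfg <- noiseless_config(protocol = build_protocol()[c(1, 9), ],
                          invalid_fraction = 0)
  s <- generate_session(cfg, seed = 7)
  a <- analyze_session(s)
  expect_identical(nrow(a$log), nrow(s$truth))
  expect_true(all(a$log$valid))
  # grid-measured duration of a smooth pulse loses up to one sample at each
  # threshold crossing: within two samples of the planned supra-threshold time
  expect_true(all(abs(a$log$duration - s$truth$duration) <= 2 / 30 + 1e-9))
  # peak within the sampling of the raised-cosine profile near its maximum
  expect_true(all(abs(a$log$peak_magnitude - s$truth$peak_magnitude) /
                    s$truth$peak_magnitude < 0.01))
  # zone exact, orientation within 0.1 degree
  expect_identical(a$log$zone, s$truth$zone)
  expect_true(all(abs(angle_diff_deg(a$log$mean_yaw, s$truth$yaw)) < 0.1))
  expect_true(all(abs(a$log$mean_pitch - s$truth$pitch) < 0.1))
})

test_that("injected violations are rejected for their labelled reason only", {
  cfg <- noiseless_config(invalid_fraction = 0.15)
  s <- generate_session(cfg, seed = 31)
  a <- analyze_session(s)
  expect_identical(a$log$valid, s$truth$valid)  # no false rejections either
  flags <- c(magnitude = "magnitude_ok", duration = "duration_ok",
             orientation = "orientation_ok", location = "location_ok")
  for (k in which(!s$truth$valid)) {
    cv <- s$truth$violated_cv[k]
    expect_false(a$log[[flags[[cv]]]][k])
    expect_true(all(unlist(a$log[k, setdiff(flags, flags[[cv]])])))
  }
  # the full protocol terminated with exactly 16 x 5 accepted events
  expect_identical(sum(a$log$valid), 80L)
  expect_true(a$state$complete)
})
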