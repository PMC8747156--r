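test_that("segment masses conserve total body mass and match direct multiplication", {
  seg <- derive_segment_parameters(anthro_profile(1.70, 60, 0.43, 0.44, 0.78))
  expect_equal(2 * seg$masses[["shank"]] + 2 * seg$masses[["thigh"]] +
                 seg$masses[["hat"]], 60, tolerance = 1e-12)
  expect_true(all(seg$masses < 60))
  expect_true(all(seg$masses > 0))

  # independent spreadsheet-style multiplication with bare constants
  # (foot excluded from the shank here: the fractions are an argument)
  seg2 <- derive_segment_parameters(
    anthro_profile(1.70, 60, 0.43, 0.44, 0.78),
    mass_fractions = c(shank = 0.0465, thigh = 0.100))
  expect_equal(seg2$masses[["shank"]], 0.0465 * 60, tolerance = 1e-12)
  expect_equal(seg2$masses[["thigh"]], 0.100 * 60, tolerance = 1e-12)
  expect_equal(seg2$masses[["hat"]], 60 * (1 - 2 * (0.0465 + 0.100)),
               tolerance = 1e-12)
})

test_that("study-subject profile yields valid segment parameters", {
  seg <- test_seg()  # 60 kg, 1.76 m subject
  expect_true(all(seg$masses > 0 & seg$masses < 60))
  expect_true(all(seg$com_fractions > 0 & seg$com_fractions < 1))
})

test_that("invalid anthropometrics are rejected", {
  expect_error(anthro_profile(1.7, -5, 0.4, 0.4, 0.7), "positive")
  expect_error(anthro_profile(1.2, 60, 0.45, 0.45, 0.80), "exceed")
  expect_error(derive_segment_parameters(test_profile(),
                                         mass_fractions = c(shank = 0.3,
                                                            thigh = 0.3)),
               "mass fractions")
})

test_that("upright posture puts the CoM vertically above the ankle", {
  ang <- data.frame(t = 0, q_ankle = 0, q_knee = 0, q_hip = 0, q_addabd = 0)
  seg <- test_seg()
  com_s <- sagittal_com(ang, seg)
  expect_identical(com_s$com_x, 0)
  expect_gt(com_s$com_y, 0)
  com_f <- frontal_com(ang, seg)
  expect_identical(com_f$com_z, 0)
  qs <- compute_qsway(com_s)
  expect_identical(qs$q_sway, 0)
})

test_that("forward trunk flexion moves the CoM forward, monotonically", {
  seg <- test_seg()
  q_hip <- seq(0.01, pi / 4, length.out = 30)
  ang <- data.frame(t = seq_along(q_hip), q_ankle = 0, q_knee = 0,
                    q_hip = q_hip, q_addabd = 0)
  com <- sagittal_com(ang, seg)
  expect_true(all(com$com_x > 0))
  expect_true(all(diff(com$com_x) > 0))
  qs <- compute_qsway(com)
  expect_true(all(diff(qs$q_sway) > 0))
})

test_that("analytic CoM matches the point-mass discretization oracle", {
  set.seed(101)
  seg <- test_seg()
  exo <- test_exo()
  for (i in 1:20) {
    q <- runif(3, -0.5, 0.5)
    ang <- data.frame(t = 0, q_ankle = q[1], q_knee = q[2], q_hip = q[3],
                      q_addabd = 0)
    com <- sagittal_com(ang, seg)
    oracle <- brute_force_com(q[1], q[1] + q[2], q[1] + q[2] + q[3],
                              seg$lengths, seg$masses, seg$com_fractions)
    expect_equal(com$com_x, oracle[["h"]], tolerance = 1e-6)
    expect_equal(com$com_y, oracle[["v"]], tolerance = 1e-6)

    # combined with exoskeleton: mass-weighted oracle over both chains
    come <- sagittal_com(ang, seg, exo)
    oe <- brute_force_com(q[1], q[1] + q[2], q[1] + q[2] + q[3], seg$lengths,
                          c(shank = exo$link_masses[["shank"]],
                            thigh = exo$link_masses[["thigh"]],
                            hat = exo$link_masses[["trunk"]]),
                          c(shank = 0.5, thigh = 0.5, hat = 0.5))
    comb_h <- (oracle[["h"]] * 60 + oe[["h"]] * 12) / 72
    expect_equal(come$com_x, comb_h, tolerance = 1e-6)
  }
})

test_that("frontal model mirrors and matches the oracle", {
  seg <- test_seg()
  q <- 0.3
  ang_p <- data.frame(t = 0, q_addabd = q)
  ang_n <- data.frame(t = 0, q_addabd = -q)
  com_p <- frontal_com(ang_p, seg)
  com_n <- frontal_com(ang_n, seg)
  expect_equal(com_p$com_z, -com_n$com_z, tolerance = 1e-14)
  expect_equal(com_p$com_y, com_n$com_y, tolerance = 1e-14)
  # legs vertical, HAT rotated about the hip: oracle with th1 = th2 = 0
  oracle <- brute_force_com(0, 0, q, seg$lengths, seg$masses,
                            seg$com_fractions)
  expect_equal(com_p$com_z, oracle[["h"]], tolerance = 1e-6)
  expect_equal(com_p$com_y, oracle[["v"]], tolerance = 1e-6)
})

test_that("negating all sagittal angles negates com_x", {
  seg <- test_seg()
  q <- c(0.2, -0.15, 0.3)
  a1 <- data.frame(t = 0, q_ankle = q[1], q_knee = q[2], q_hip = q[3])
  a2 <- data.frame(t = 0, q_ankle = -q[1], q_knee = -q[2], q_hip = -q[3])
  expect_equal(sagittal_com(a1, seg)$com_x, -sagittal_com(a2, seg)$com_x,
               tolerance = 1e-14)
})

test_that("combined CoM is the exact mass-weighted average", {
  com_h <- data.frame(t = 0, com_x = 0, com_y = 1)
  com_e <- data.frame(t = 0, com_x = 0.2, com_y = 1)
  out <- combine_com(com_h, 50, com_e, 50)
  expect_equal(out$com_x, 0.1)
  expect_equal(out$com_y, 1)
  set.seed(42)
  for (i in 1:10) {
    mh <- runif(1, 40, 90); me <- runif(1, 5, 25)
    ch <- data.frame(t = 1:3, com_x = rnorm(3), com_y = runif(3, 0.8, 1.2))
    ce <- data.frame(t = 1:3, com_x = rnorm(3), com_y = runif(3, 0.8, 1.2))
    out <- combine_com(ch, mh, ce, me)
    expect_equal(out$com_x, (ch$com_x * mh + ce$com_x * me) / (mh + me),
                 tolerance = 1e-12)
  }
  expect_error(combine_com(com_h, 0, com_e, 0), "positive")
})

test_that("absent exoskeleton reproduces the human CoM bit-identically", {
  seg <- test_seg()
  set.seed(5)
  ang <- data.frame(t = 1:50, q_ankle = rnorm(50, 0, 0.1),
                    q_knee = rnorm(50, 0, 0.1), q_hip = rnorm(50, 0, 0.1),
                    q_addabd = rnorm(50, 0, 0.1))
  com_h <- sagittal_com(ang, seg, exo = NULL, component = "human")
  com_t <- sagittal_com(ang, seg, exo = exo_spec(FALSE))
  expect_identical(com_t$com_x, com_h$com_x)
  expect_identical(com_t$com_y, com_h$com_y)
  expect_identical(combine_com(com_h, 60, com_h, 0), com_h)
})

test_that("sway angle equals the independent arctangent in degrees", {
  com <- data.frame(t = 0, com_x = 0.3, com_y = 0.3)
  expect_equal(compute_qsway(com)$q_sway, 45)
  set.seed(9)
  x <- rnorm(20, 0, 0.1); y <- runif(20, 0.8, 1.2)
  qs <- compute_qsway(data.frame(t = 1:20, com_x = x, com_y = y))
  expect_equal(qs$q_sway, atan2(x, y) * 180 / pi, tolerance = 1e-12)
  expect_error(compute_qsway(data.frame(t = 0, com_x = 0, com_y = -1)),
               "positive")
})
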