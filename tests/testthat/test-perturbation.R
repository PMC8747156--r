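make_force <- function(mag, fs = 30, t0 = 0) {
  data.frame(t = t0 + (seq_along(mag) - 1) / fs, fx = mag, fy = 0, fz = 0)
}

test_that("force calibration averages exactly the first 2000 samples", {
  n <- 2500
  df <- data.frame(t = (1:n) / 30, fx = 1, fy = 2, fz = 3)
  # put an outlier after the calibration block: it must not affect offsets
  df$fx[2200] <- 1000
  off <- calibrate_force(df)
  expect_equal(unname(off), c(1, 2, 3))
  expect_error(calibrate_force(df[1:1999, ]), "2000")

  set.seed(3)
  dfn <- data.frame(t = (1:2000) / 30, fx = rnorm(2000), fy = rnorm(2000),
                    fz = rnorm(2000))
  offn <- calibrate_force(dfn)
  expect_true(all(abs(offn) < 4 / sqrt(2000)))  # CLT bound on the mean
  cal <- apply_force_calibration(dfn, offn)
  expect_equal(unname(calibrate_force(cal)), c(0, 0, 0), tolerance = 1e-12)
})

test_that("garment calibration produces one threshold per sensor", {
  df <- data.frame(t = (1:200) / 30,
                   matrix(rep(10 + seq_len(30), each = 200), nrow = 200))
  names(df) <- c("t", paste0("s", 1:30))
  thr <- calibrate_garment(df, margin = 0.5)
  expect_length(thr, 30)
  expect_true(all(thr >= 10 + seq_len(30)))
  expect_equal(unname(thr), 10 + seq_len(30) + 0.5, tolerance = 1e-12)
  # a level one unit above a flat baseline counts as active
  expect_true(11 + 1 > thr[["s1"]])
  expect_error(calibrate_garment(df[, 1:20]), "s30")
  expect_error(calibrate_garment(df[1:100, ]), "200")
})

test_that("resultant magnitude is the Euclidean norm", {
  expect_equal(resultant_magnitude(data.frame(fx = 3, fy = 4, fz = 0)), 5)
  expect_equal(resultant_magnitude(data.frame(fx = 0, fy = 0, fz = 0)), 0)
  set.seed(11)
  df <- data.frame(fx = rnorm(50), fy = rnorm(50), fz = rnorm(50))
  expect_equal(resultant_magnitude(df),
               sqrt(df$fx^2 + df$fy^2 + df$fz^2), tolerance = 1e-12)
})

test_that("event detection partitions supra-threshold runs", {
  # sub-threshold pulse: no event
  mag <- c(rep(0, 10), rep(4, 10), rep(0, 10))
  expect_identical(nrow(detect_events(make_force(mag))), 0L)

  # rectangular 50 N pulse spanning t = 1.00..1.33 s on the 30 Hz grid
  t <- (0:120) / 30
  mag <- ifelse(t >= 1 & t <= 4 / 3 + 1e-9, 50, 0)
  ev <- detect_events(make_force(mag))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$onset_t, 1, tolerance = 1e-9)
  expect_equal(ev$duration, 1 / 3, tolerance = 1e-9)
  expect_equal(ev$peak_magnitude, 50)

  # two pulses split by a sub-threshold gap stay distinct, and the total
  # impulse is unchanged by splitting the series at the gap
  mag2 <- c(rep(0, 5), rep(30, 8), rep(0, 6), rep(40, 8), rep(0, 5))
  f2 <- make_force(mag2)
  ev2 <- detect_events(f2)
  expect_identical(nrow(ev2), 2L)
  half1 <- detect_events(f2[1:16, ])
  half2 <- detect_events(f2[17:32, ])
  expect_equal(sum(ev2$impulse), half1$impulse + half2$impulse,
               tolerance = 1e-9)

  expect_error(detect_events(data.frame(t = c(1, 1, 2), fx = 10, fy = 0,
                                        fz = 0)), "increasing")
})

test_that("minimal detectable rectangular pulse converges to the 5 N threshold", {
  min_detectable <- function() {
    lo <- 1; hi <- 10
    while (hi - lo > 0.001) {
      mid <- (lo + hi) / 2
      mag <- c(rep(0, 5), rep(mid, 10), rep(0, 5))
      if (nrow(detect_events(make_force(mag))) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(min_detectable(), 5, tolerance = 0.01)
})

test_that("quaternion Euler decomposition matches the rotation-matrix oracle", {
  # identity
  expect_equal(unlist(quat_to_euler(c(1, 0, 0, 0))), c(yaw = 0, pitch = 0,
                                                       roll = 0))
  # pure 45-degree yaw
  q45 <- quat_from_euler(45, 0, 0)
  expect_equal(quat_to_euler(q45)$yaw, 45, tolerance = 1e-9)
  expect_equal(quat_to_matrix(q45), rotmat_zyx(45, 0, 0), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    e <- c(runif(1, -170, 170), runif(1, -80, 80), runif(1, -170, 170))
    q <- quat_from_euler(e[1], e[2], e[3])
    expect_equal(quat_to_matrix(q), rotmat_zyx(e[1], e[2], e[3]),
                 tolerance = 1e-9)
    back <- quat_to_euler(q)
    expect_equal(unlist(back[c("yaw", "pitch", "roll")]),
                 c(yaw = e[1], pitch = e[2], roll = e[3]), tolerance = 1e-9)
    # composition of two rotations agrees with the matrix product
    e2 <- c(runif(1, -90, 90), runif(1, -60, 60), runif(1, -90, 90))
    q2 <- quat_from_euler(e2[1], e2[2], e2[3])
    expect_equal(quat_to_matrix(quat_multiply(q, q2)),
                 rotmat_zyx(e[1], e[2], e[3]) %*% rotmat_zyx(e2[1], e2[2], e2[3]),
                 tolerance = 1e-9)
  }
  expect_error(quat_normalize(c(0, 0, 0, 0)), "zero-norm")
})

test_that("relative orientation recovers the garment->perturbator rotation", {
  t <- (0:9) / 30
  idq <- data.frame(t = t, qw = 1, qx = 0, qy = 0, qz = 0)
  # identical quaternions -> zero relative angles
  rel0 <- relative_orientation(idq, idq)
  expect_equal(max(abs(c(rel0$pitch, rel0$yaw, rel0$roll))), 0)

  # perturbator rotated 45 degrees about vertical relative to the garment
  q <- quat_from_euler(45, 10, -5)
  qp <- data.frame(t = t, qw = q[1], qx = q[2], qy = q[3], qz = q[4])
  rel <- relative_orientation(qp, idq)
  expect_equal(rel$yaw, rep(45, 10), tolerance = 1e-9)
  expect_equal(rel$pitch, rep(10, 10), tolerance = 1e-9)
  expect_equal(rel$roll, rep(-5, 10), tolerance = 1e-9)

  # garment rotated too: relative rotation is q_g^-1 * q_p (matrix oracle)
  qg1 <- quat_from_euler(30, 5, 0)
  qg <- data.frame(t = t, qw = qg1[1], qx = qg1[2], qy = qg1[3], qz = qg1[4])
  rel2 <- relative_orientation(qp, qg)
  Rrel <- t(rotmat_zyx(30, 5, 0)) %*% rotmat_zyx(45, 10, -5)
  e <- euler_zyx_from_matrix(Rrel)
  expect_equal(rel2$yaw[1], e[["yaw"]], tolerance = 1e-9)
  expect_equal(rel2$pitch[1], e[["pitch"]], tolerance = 1e-9)
})

test_that("event orientation is the circular mean over the event window", {
  ev <- data.frame(event_id = 1L, onset_t = 0.1, offset_t = 0.3,
                   duration = 0.2, peak_magnitude = 50, impulse = 10)
  ori <- data.frame(t = (0:11) / 30,
                    pitch = rep(5, 12), yaw = c(rep(179, 6), rep(-179, 6)),
                    roll = 0)
  out <- event_orientation(ev, ori)
  expect_equal(out$mean_pitch, 5)
  # yaw values wrap across 180: the circular mean stays near +/-180, never 0
  expect_gt(abs(out$mean_yaw), 179)
})

test_that("location resolution follows the zone map with deterministic ties", {
  thr <- setNames(rep(10, 30), paste0("s", 1:30))
  g <- function(ids, lvls, t = c(0.1, 0.2)) {
    df <- data.frame(t = t)
    for (k in 1:4) {
      df[[paste0("id", k)]] <- ids[k]
      df[[paste0("lvl", k)]] <- lvls[k]
    }
    df
  }
  # sensors 1 and 2 active -> mid back
  r <- resolve_location(g(c(1, 2, 5, 9), c(60, 55, 9, 8)), thr, 0, 0.3)
  expect_identical(r$zone, "mid back")
  expect_setequal(r$active_ids, c(1L, 2L))
  # sensors 25, 26 -> left side shoulder
  r2 <- resolve_location(g(c(25, 26, 1, 2), c(60, 55, 9, 8)), thr, 0, 0.3)
  expect_identical(r2$zone, "left side shoulder")
  # tie between mid back (1) and upper back (3): first protocol zone wins
  r3 <- resolve_location(g(c(1, 3, 7, 8), c(60, 60, 9, 8)), thr, 0, 0.3)
  expect_identical(r3$zone, "mid back")
  expect_error(resolve_location(g(c(1, 2, 3, 4), rep(60, 4)), thr, 5, 6),
               "window")
})
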