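# Synthetic session generator. Emulates the four 30 Hz sensor streams of a
# perturbed-stance assessment (perturbator force + IMU, garment IMU +
# pressure activations, joint angles) together with exact ground-truth labels
# so the processing, protocol and indicator modules can be exercised
# end-to-end without hardware.

#' Second-order sway response model
#'
#' The postural response to a push is modelled as the impulse response of a
#' linear second-order system: `q_sway(t) = gain * impulse * h(t)` with
#' `h(t) = omega_n^2 t exp(-omega_n t)` when critically damped (`zeta = 1`,
#' the default) or the damped sinusoid for `0 < zeta < 1`. The model is the
#' minimal one with a closed-form peak and decay, which makes analytic
#' ground truth available for every simulated trial; it represents an
#' ankle-strategy response (all sway at the ankle in the sagittal plane, at
#' the hip in the frontal plane).
#'
#' @param gain Sway gain in degrees per newton-second of impulse (per unit
#'   normalized impulse response).
#' @param omega_n Natural frequency, rad/s.
#' @param zeta Damping ratio in (0, 1]; values outside error.
#' @return An object of class `response_model`.
#' @export
response_model <- function(gain = 0.1, omega_n = 4, zeta = 1) {
  if (!is.finite(gain) || gain <= 0) stop("gain must be positive",
                                          call. = FALSE)
  if (!is.finite(omega_n) || omega_n <= 0) {
    stop("omega_n must be positive", call. = FALSE)
  }
  if (!is.finite(zeta) || zeta <= 0 || zeta > 1) {
    stop("response must be underdamped or critically damped: 0 < zeta <= 1",
         call. = FALSE)
  }
  structure(list(gain = gain, omega_n = omega_n, zeta = zeta),
            class = "response_model")
}

#' Closed-form sway response and its velocity
#'
#' Evaluate the modelled sway angle (degrees) and sway velocity (deg/s) at
#' times `t` (seconds since perturbation onset; zero before onset).
#'
#' @param t Time since onset, seconds (vectorized).
#' @param impulse Perturbation impulse, N s.
#' @param model A [response_model()].
#' @return Data frame with columns `q_sway` and `velocity`.
#' @export
response_curve <- function(t, impulse, model) {
  wn <- model$omega_n; z <- model$zeta; a <- model$gain * impulse
  tp <- pmax(t, 0)
  if (z == 1) {
    q <- a * wn^2 * tp * exp(-wn * tp)
    v <- a * wn^2 * (1 - wn * tp) * exp(-wn * tp)
  } else {
    lam <- z * wn
    wd <- wn * sqrt(1 - z^2)
    e <- exp(-lam * tp)
    q <- a * wn / sqrt(1 - z^2) * e * sin(wd * tp)
    v <- a * wn / sqrt(1 - z^2) * e * (wd * cos(wd * tp) - lam * sin(wd * tp))
  }
  q[t < 0] <- 0
  v[t < 0] <- 0
  data.frame(q_sway = q, velocity = v)
}

#' Analytic peak sway of the response model
#'
#' @inheritParams response_curve
#' @return Peak `q_sway` in degrees (positive; apply the push direction sign
#'   externally).
#' @export
response_peak <- function(impulse, model) {
  wn <- model$omega_n; z <- model$zeta; a <- model$gain * impulse
  if (z == 1) return(a * wn * exp(-1))
  lam <- z * wn
  wd <- wn * sqrt(1 - z^2)
  tp <- atan2(wd, lam) / wd
  a * wn / sqrt(1 - z^2) * exp(-lam * tp) * sin(wd * tp)
}

#' Ground-truth recovery time of the response model
#'
#' Applies the quiescence criterion (|velocity| below `threshold` for at
#' least `quiet_s`) to the closed-form velocity on a fine time grid,
#' independent of any sampled stream.
#'
#' @inheritParams response_curve
#' @param threshold Velocity threshold, deg/s.
#' @param quiet_s Quiescence window, seconds.
#' @param horizon Search horizon after onset, seconds.
#' @param dt Fine-grid resolution, seconds.
#' @return Recovery time in seconds (`NA` if not reached within `horizon`).
#' @export
response_recovery <- function(impulse, model, threshold = 0.86,
                              quiet_s = 0.5, horizon = 10, dt = 1e-3) {
  t <- seq(0, horizon, by = dt)
  v <- response_curve(t, impulse, model)$velocity
  quiescence_start(t, abs(v) < threshold, quiet_s)
}

# Force profile of one push on a time grid (N; zero outside the pulse).
pulse_profile <- function(t, t0, peak, duration, shape) {
  s <- (t - t0) / duration
  inside <- s >= 0 & s <= 1
  out <- numeric(length(t))
  if (shape == "rectangular") {
    out[inside] <- peak
  } else if (shape == "raised-cosine") {
    out[inside] <- peak / 2 * (1 - cos(2 * pi * s[inside]))
  } else {
    stop(sprintf("unknown pulse shape '%s'", shape), call. = FALSE)
  }
  out
}

#' Simulate a force pulse stream
#'
#' One push of given peak and duration on the 30 Hz grid, oriented along the
#' perturbator push axis (`fx`), with optional zero-mean Gaussian noise on
#' all three axes.
#'
#' @param peak Peak force, N.
#' @param duration Pulse duration, s.
#' @param shape "rectangular" or "raised-cosine".
#' @param t0 Pulse onset, s.
#' @param t_end Stream end time, s (stream starts at 0).
#' @param fs Sampling frequency, Hz.
#' @param noise_sd Per-axis force noise SD, N.
#' @return Force data frame (`t`, `fx`, `fy`, `fz`).
#' @export
simulate_force_pulse <- function(peak, duration, shape = "rectangular",
                                 t0 = 1, t_end = t0 + duration + 1, fs = 30,
                                 noise_sd = 0) {
  if (peak <= 0 || duration <= 0) stop("peak and duration must be positive",
                                       call. = FALSE)
  t <- seq(0, t_end, by = 1 / fs)
  fx <- pulse_profile(t, t0, peak, duration, shape)
  df <- data.frame(t = t, fx = fx, fy = 0, fz = 0)
  if (noise_sd > 0) {
    for (ax in c("fx", "fy", "fz")) {
      df[[ax]] <- df[[ax]] + rnorm(length(t), 0, noise_sd)
    }
  }
  df
}

# Inverse map from a target mediolateral sway angle (degrees) to the hip
# add/abduction angle (radians) that reproduces it through the frontal-plane
# CoM model, built once per configuration on a fine grid.
ml_inverse_map <- function(seg, exo = NULL, max_deg = 45, n = 4001) {
  q_add <- deg2rad(seq(-max_deg, max_deg, length.out = n))
  ang <- data.frame(t = seq_along(q_add), q_addabd = q_add)
  qs <- compute_qsway(frontal_com(ang, seg, exo))$q_sway
  approxfun(qs, q_add, rule = 2)
}

#' Simulate the joint-angle response to one perturbation
#'
#' Generates a joint-angle stream whose sway angle, as reconstructed by the
#' planar CoM model, follows the second-order response exactly: the whole
#' response is placed at the ankle for antero-posterior pushes (a pure ankle
#' rotation leaves the ankle-to-CoM line at exactly the ankle angle) and at
#' the hip add/abduction for mediolateral pushes (numerically inverted
#' through the frontal model).
#'
#' @param impulse Perturbation impulse, N s (zero gives identically zero
#'   angles).
#' @param model A [response_model()].
#' @param seg Segment parameters, [derive_segment_parameters()].
#' @param exo Optional [exo_spec()].
#' @param plane "AP" or "ML".
#' @param direction +1 or -1 sway sign (pushes from the front or the right
#'   side drive negative sway).
#' @param t0 Perturbation onset, s.
#' @param t_end Stream end, s.
#' @param fs Sampling frequency, Hz.
#' @param angle_noise_sd_deg White Gaussian noise SD added to each joint
#'   angle, degrees.
#' @return Joint-angle data frame (`t`, `q_ankle`, `q_knee`, `q_hip`,
#'   `q_addabd`, radians) with attributes `q_sway_max_true` and
#'   `recovery_time_true`.
#' @export
simulate_response <- function(impulse, model, seg, exo = NULL,
                              plane = c("AP", "ML"), direction = 1,
                              t0 = 1, t_end = 6, fs = 30,
                              angle_noise_sd_deg = 0) {
  plane <- match.arg(plane)
  t <- seq(0, t_end, by = 1 / fs)
  qs_deg <- direction * response_curve(t - t0, impulse, model)$q_sway
  out <- data.frame(t = t, q_ankle = 0, q_knee = 0, q_hip = 0, q_addabd = 0)
  if (plane == "AP") {
    out$q_ankle <- deg2rad(qs_deg)
  } else {
    inv <- ml_inverse_map(seg, exo)
    out$q_addabd <- inv(qs_deg)
  }
  if (angle_noise_sd_deg > 0) {
    for (cc in c("q_ankle", "q_knee", "q_hip", "q_addabd")) {
      out[[cc]] <- out[[cc]] + deg2rad(rnorm(length(t), 0, angle_noise_sd_deg))
    }
  }
  attr(out, "q_sway_max_true") <- direction * response_peak(impulse, model)
  attr(out, "recovery_time_true") <- response_recovery(impulse, model)
  out
}

# Deterministic per-sensor raw baselines for the garment simulator.
garment_baselines <- function(n_sensors = 30, base = 100) {
  base + 0.2 * seq_len(n_sensors)
}

#' Simulate the garment activation stream
#'
#' Produces the "four most active sensors" stream the garment reports.
#' Outside events every sensor sits at its baseline plus sub-threshold noise;
#' inside an event window the target zone's sensors are driven well above
#' threshold, optionally with a weaker bleed activation of one sensor in an
#' adjacent zone.
#'
#' @param t Time grid, seconds.
#' @param events Data frame with columns `onset_t`, `offset_t`, `zone` and
#'   logical `bleed`.
#' @param baselines Per-sensor raw baselines.
#' @param noise_sd Baseline noise SD, raw units.
#' @param activation Activation amplitude added to in-zone sensors during an
#'   event, raw units.
#' @param bleed_level Fraction of `activation` applied to the bleed sensor.
#' @param zone_map Zone definition, defaults to [garment_zone_map()].
#' @return Garment data frame (`t`, `id1`..`id4`, `lvl1`..`lvl4`).
#' @export
simulate_garment <- function(t, events, baselines = garment_baselines(),
                             noise_sd = 0.1, activation = 60,
                             bleed_level = 0.3,
                             zone_map = garment_zone_map()) {
  n_sensors <- length(baselines)
  lv <- matrix(rep(baselines, each = length(t)), nrow = length(t))
  if (noise_sd > 0) {
    lv <- lv + matrix(rnorm(length(lv), 0, noise_sd), nrow = length(t))
  }
  for (k in seq_len(nrow(events))) {
    zone <- events$zone[k]
    if (!zone %in% names(zone_map)) {
      stop(sprintf("unknown zone '%s'", zone), call. = FALSE)
    }
    sensors <- zone_map[[zone]]
    w <- t >= events$onset_t[k] - 1e-9 & t <= events$offset_t[k] + 1e-9
    # strongest activation on the first two zone sensors, weaker on the rest
    amp <- activation * c(1, 0.9, rep(0.5, length(sensors) - 2))[
      seq_along(sensors)]
    lv[w, sensors] <- lv[w, sensors] +
      matrix(rep(amp, each = sum(w)), nrow = sum(w))
    if (isTRUE(events$bleed[k])) {
      other <- setdiff(seq_len(n_sensors), sensors)
      lv[w, other[1]] <- lv[w, other[1]] + activation * bleed_level
    }
  }
  top4 <- t(apply(lv, 1, function(row) {
    o <- order(row, decreasing = TRUE)[1:4]
    c(o, row[o])
  }))
  out <- data.frame(t, top4)
  names(out) <- c("t", paste0("id", 1:4), paste0("lvl", 1:4))
  out
}

#' Scenario configuration for a synthetic session
#'
#' Defines the study conditions a synthetic session emulates: the subject,
#' the (optional) exoskeleton, the protocol and tolerances, the pulse and
#' response models, per-stream noise levels, and the fraction of deliberately
#' invalid perturbations injected for flag testing.
#'
#' @param subject An [anthro_profile()]; the default is the study subject
#'   (60 kg, 1.76 m).
#' @param exo An [exo_spec()].
#' @param protocol Condition table, defaults to [build_protocol()].
#' @param tol A [default_tolerances()] object.
#' @param model A [response_model()].
#' @param fs Sampling frequency, Hz.
#' @param pulse_shape "raised-cosine" (default, a realistic smooth push) or
#'   "rectangular".
#' @param invalid_fraction Expected fraction of injected invalid events per
#'   condition.
#' @param spacing_s Time between consecutive pulse onsets, seconds (>= 3 s
#'   separation between perturbations; the default leaves a full recovery
#'   window).
#' @param noise Named list of per-stream noise levels: `force_sd` (N),
#'   `quat_deg_sd` (degrees, IMU orientation jitter), `angle_deg_sd`
#'   (degrees, joint-angle white noise), `garment_sd` (raw units).
#' @param force_bias Constant per-axis force offsets the calibration must
#'   remove, N.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(subject = anthro_profile(1.76, 60, 0.45, 0.45, 0.80),
                            exo = exo_spec(FALSE),
                            protocol = build_protocol(),
                            tol = default_tolerances(),
                            model = response_model(),
                            fs = 30,
                            pulse_shape = c("raised-cosine", "rectangular"),
                            invalid_fraction = 0.1,
                            spacing_s = 6,
                            noise = list(force_sd = 0.2, quat_deg_sd = 0.2,
                                         angle_deg_sd = 0.02,
                                         garment_sd = 0.1),
                            force_bias = c(fx = 1.5, fy = -0.8, fz = 0.3)) {
  pulse_shape <- match.arg(pulse_shape)
  if (spacing_s < 3) stop("perturbations must be separated by at least 3 s",
                          call. = FALSE)
  if (invalid_fraction < 0 || invalid_fraction >= 1) {
    stop("invalid_fraction must be in [0, 1)", call. = FALSE)
  }
  defaults <- list(force_sd = 0.2, quat_deg_sd = 0.2, angle_deg_sd = 0.02,
                   garment_sd = 0.1)
  noise <- utils::modifyList(defaults, noise)
  structure(list(subject = subject, exo = exo, protocol = protocol,
                 tol = tol, model = model, fs = fs,
                 pulse_shape = pulse_shape,
                 invalid_fraction = invalid_fraction, spacing_s = spacing_s,
                 noise = noise, force_bias = force_bias),
            class = "scenario_config")
}

# Push direction (plane and sway sign) implied by the delivered zone: pushes
# from behind drive forward (positive AP) sway; front and right-side pushes
# drive negative sway, left-side pushes positive ML sway.
zone_response_direction <- function(zone) {
  if (zone %in% c("mid back", "upper back")) {
    list(plane = "AP", direction = 1)
  } else if (zone %in% c("mid torso", "upper torso")) {
    list(plane = "AP", direction = -1)
  } else if (zone %in% c("right side torso", "right side shoulder")) {
    list(plane = "ML", direction = -1)
  } else {
    list(plane = "ML", direction = 1)
  }
}

analytic_impulse <- function(peak, duration, shape) {
  if (shape == "rectangular") peak * duration else peak * duration / 2
}

# The measured duration of a push is the time its magnitude exceeds the
# "no force" threshold. A raised-cosine pulse spends part of its support in
# the sub-threshold tails, so to deliver a target supra-threshold duration
# its support must be widened by the tail fraction
# s* = acos(1 - 2*thr/peak) / (2*pi) on each side.
support_duration <- function(eff_duration, peak, shape, threshold = 5) {
  if (shape == "rectangular") return(eff_duration)
  if (peak <= threshold) stop("peak must exceed the detection threshold",
                              call. = FALSE)
  s_star <- acos(1 - 2 * threshold / peak) / (2 * pi)
  eff_duration / (1 - 2 * s_star)
}

#' Generate a complete synthetic assessment session
#'
#' Builds the full event plan for a 16-condition protocol run (five valid
#' perturbations per condition plus a configurable fraction of deliberately
#' invalid ones, each labelled with the controlled variable it violates),
#' synthesizes all sensor streams at 30 Hz, and returns them together with
#' the exact ground truth. Generation is deterministic for a given
#' config + seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer random seed.
#' @return An object of class `simulated_session`: a list with `streams`
#'   (`force`, `imu_perturbator`, `imu_garment`, `garment`, `joints`),
#'   `calibration` (`force`, `garment`), `truth` (one row per generated
#'   event), `config` and `seed`.
#' @export
generate_session <- function(config = scenario_config(), seed = 1) {
  set.seed(seed)
  tol <- config$tol
  fs <- config$fs
  protocol <- config$protocol
  seg <- derive_segment_parameters(config$subject)
  exo <- config$exo
  total_mass <- config$subject$total_mass + exo$total_mass
  weight <- total_mass * tol$g
  reps <- tol$required_reps

  # --- event plan -----------------------------------------------------------
  plan <- list()
  for (i in seq_len(nrow(protocol))) {
    cond <- protocol[i, ]
    n_inv <- stats::rbinom(1, reps, config$invalid_fraction)
    # the block always ends with the fifth valid repetition: the protocol
    # moves on as soon as it is recorded, so no push can follow it
    labels <- c(sample(c(rep(TRUE, reps - 1), rep(FALSE, n_inv))), TRUE)
    for (valid in labels) {
      center <- if (cond$magnitude_level == "Low") tol$low_center_pct else
        tol$high_center_pct
      ev <- list(
        condition_order = cond$order, valid = valid,
        violated_cv = NA_character_,
        pct = runif(1, center - 1, center + 1),
        duration = runif(1, 0.30, 0.42),
        pitch = runif(1, -10, 10),
        yaw_err = runif(1, -10, 10),
        roll = runif(1, -5, 5),
        zone = cond$location_zone, bleed = TRUE
      )
      if (!valid) {
        cv <- sample(c("magnitude", "duration", "orientation", "location"), 1)
        ev$violated_cv <- cv
        if (cv == "magnitude") {
          ev$pct <- 12  # between the Low and High bands: invalid for both
        } else if (cv == "duration") {
          ev$duration <- 0.65
        } else if (cv == "orientation") {
          ev$yaw_err <- sample(c(-1, 1), 1) * 45
        } else {
          others <- setdiff(names(garment_zone_map()), cond$location_zone)
          ev$zone <- sample(others, 1)
          ev$bleed <- FALSE
        }
      }
      plan[[length(plan) + 1]] <- ev
    }
  }
  n_ev <- length(plan)
  truth <- do.call(rbind, lapply(seq_len(n_ev), function(k) {
    ev <- plan[[k]]
    cond_zone <- protocol$location_zone[match(ev$condition_order,
                                              protocol$order)]
    onset <- 2 + (k - 1) * config$spacing_s
    peak <- ev$pct / 100 * weight
    dirn <- zone_response_direction(ev$zone)
    support <- support_duration(ev$duration, peak, config$pulse_shape,
                                tol$force_threshold_n)
    imp <- analytic_impulse(peak, support, config$pulse_shape)
    data.frame(
      event_id = k, condition_order = ev$condition_order, valid = ev$valid,
      violated_cv = ev$violated_cv, onset_t = onset,
      duration = ev$duration, support_duration = support,
      peak_magnitude = peak, impulse = imp,
      # orientation is always delivered relative to the condition's target
      # zone, so a wrong-location push violates only the location check
      pitch = ev$pitch, yaw = zone_nominal_yaw(cond_zone) + ev$yaw_err,
      roll = ev$roll, zone = ev$zone, bleed = ev$bleed,
      plane = dirn$plane, direction = dirn$direction,
      q_sway_max_true = dirn$direction * response_peak(imp, config$model),
      recovery_time_true = response_recovery(imp, config$model),
      stringsAsFactors = FALSE
    )
  }))

  t_end <- max(truth$onset_t) + config$spacing_s
  t <- round(seq(0, t_end, by = 1 / fs), 6)
  n <- length(t)
  noise <- config$noise

  # --- force stream (raw: includes the bias the calibration removes) --------
  mag <- numeric(n)
  for (k in seq_len(n_ev)) {
    mag <- mag + pulse_profile(t, truth$onset_t[k], truth$peak_magnitude[k],
                               truth$support_duration[k], config$pulse_shape)
  }
  force <- data.frame(t = t,
                      fx = mag + config$force_bias[["fx"]],
                      fy = config$force_bias[["fy"]],
                      fz = config$force_bias[["fz"]])
  if (noise$force_sd > 0) {
    for (ax in c("fx", "fy", "fz")) {
      force[[ax]] <- force[[ax]] + rnorm(n, 0, noise$force_sd)
    }
  }

  # --- IMU streams ----------------------------------------------------------
  qg <- matrix(rep(c(1, 0, 0, 0), each = n), nrow = n)
  qp <- qg
  for (k in seq_len(n_ev)) {
    w <- t >= truth$onset_t[k] - 1e-9 &
      t <= truth$onset_t[k] + truth$support_duration[k] + 1e-9
    qp[w, ] <- matrix(rep(quat_from_euler(truth$yaw[k], truth$pitch[k],
                                          truth$roll[k]), each = sum(w)),
                      nrow = sum(w))
  }
  if (noise$quat_deg_sd > 0) {
    qg <- quat_jitter(qg, noise$quat_deg_sd)
    qp <- quat_jitter(qp, noise$quat_deg_sd)
  }
  imu_garment <- data.frame(t = t, qw = qg[, 1], qx = qg[, 2], qy = qg[, 3],
                            qz = qg[, 4])
  imu_perturbator <- data.frame(t = t, qw = qp[, 1], qx = qp[, 2],
                                qy = qp[, 3], qz = qp[, 4])

  # --- joint angles ---------------------------------------------------------
  qs_ap <- numeric(n)
  qs_ml <- numeric(n)
  for (k in seq_len(n_ev)) {
    resp <- truth$direction[k] *
      response_curve(t - truth$onset_t[k], truth$impulse[k],
                     config$model)$q_sway
    if (truth$plane[k] == "AP") qs_ap <- qs_ap + resp else
      qs_ml <- qs_ml + resp
  }
  inv <- ml_inverse_map(seg, if (exo$present) exo else NULL)
  joints <- data.frame(t = t, q_ankle = deg2rad(qs_ap), q_knee = 0,
                       q_hip = 0, q_addabd = inv(qs_ml))
  if (noise$angle_deg_sd > 0) {
    for (cc in c("q_ankle", "q_knee", "q_hip", "q_addabd")) {
      joints[[cc]] <- joints[[cc]] + deg2rad(rnorm(n, 0, noise$angle_deg_sd))
    }
  }

  # --- garment stream -------------------------------------------------------
  gev <- data.frame(onset_t = truth$onset_t,
                    offset_t = truth$onset_t + truth$support_duration,
                    zone = truth$zone, bleed = truth$bleed,
                    stringsAsFactors = FALSE)
  garment <- simulate_garment(t, gev, noise_sd = noise$garment_sd)

  # --- calibration blocks ---------------------------------------------------
  t_cal_f <- round(seq(0, (2000 - 1) / fs, by = 1 / fs), 6)
  force_cal <- data.frame(t = t_cal_f,
                          fx = config$force_bias[["fx"]],
                          fy = config$force_bias[["fy"]],
                          fz = config$force_bias[["fz"]])
  if (noise$force_sd > 0) {
    for (ax in c("fx", "fy", "fz")) {
      force_cal[[ax]] <- force_cal[[ax]] + rnorm(2000, 0, noise$force_sd)
    }
  }
  t_cal_g <- round(seq(0, (200 - 1) / fs, by = 1 / fs), 6)
  bl <- garment_baselines()
  garment_cal <- data.frame(t = t_cal_g,
                            matrix(rep(bl, each = 200), nrow = 200) +
                              if (noise$garment_sd > 0)
                                matrix(rnorm(200 * 30, 0, noise$garment_sd),
                                       nrow = 200) else 0)
  names(garment_cal) <- c("t", paste0("s", 1:30))

  structure(list(
    streams = list(force = force, imu_perturbator = imu_perturbator,
                   imu_garment = imu_garment, garment = garment,
                   joints = joints),
    calibration = list(force = force_cal, garment = garment_cal),
    truth = truth, config = config, seed = seed
  ), class = "simulated_session")
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf(
    "Simulated session: %d events (%d valid, %d invalid), %.0f s at %g Hz\n",
    nrow(x$truth), sum(x$truth$valid), sum(!x$truth$valid),
    max(x$streams$force$t), x$config$fs))
  invisible(x)
}
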