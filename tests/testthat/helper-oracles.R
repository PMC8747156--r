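# Independent oracles used across the test files. These deliberately avoid
# the package's analytic code paths: the CoM oracle discretizes every segment
# into point masses placed with explicit rotation matrices, and the Euler
# oracle works through rotation-matrix products.

# planar rotation taking the vertical unit vector toward +horizontal for
# positive angles (the model's forward-lean convention)
rot2 <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), nrow = 2)
}

# CoM of one segment discretized into n point masses along its axis. The
# linear density a + b*s is chosen so the segment's total mass is m and its
# CoM sits at fraction f of the length from the segment base.
segment_point_masses <- function(base, theta, length, m, f_from_base,
                                 n = 1e4) {
  s <- (seq_len(n) - 0.5) / n
  w <- m * (4 - 6 * f_from_base) + 12 * m * (f_from_base - 0.5) * s
  u <- rot2(theta) %*% c(0, 1)  # segment direction: vertical rotated by theta
  pts_h <- base[1] + s * length * u[1]
  pts_v <- base[2] + s * length * u[2]
  list(m = sum(w / n), mh = sum(w / n * pts_h), mv = sum(w / n * pts_v))
}

# Brute-force CoM of the five-segment chain for scalar angles (radians).
# masses: c(shank=, thigh=, hat=) with shank/thigh per side; fractions are
# CoM positions from the proximal end (knee/hip/hip).
brute_force_com <- function(th1, th2, th3, lengths, masses, fractions,
                            n = 1e4) {
  u1 <- rot2(th1) %*% c(0, 1)
  u2 <- rot2(th2) %*% c(0, 1)
  knee <- lengths[["shank"]] * u1
  hip <- knee + lengths[["thigh"]] * u2
  # from the chain base the shank/thigh CoM fractions flip: f_base = 1 - f
  segs <- list(
    segment_point_masses(c(0, 0), th1, lengths[["shank"]],
                         2 * masses[["shank"]],
                         1 - fractions[["shank"]], n),
    segment_point_masses(knee, th2, lengths[["thigh"]],
                         2 * masses[["thigh"]],
                         1 - fractions[["thigh"]], n),
    segment_point_masses(hip, th3, lengths[["hat"]], masses[["hat"]],
                         fractions[["hat"]], n)
  )
  m <- sum(vapply(segs, `[[`, numeric(1), "m"))
  c(h = sum(vapply(segs, `[[`, numeric(1), "mh")) / m,
    v = sum(vapply(segs, `[[`, numeric(1), "mv")) / m)
}

# Euler Z-Y-X decomposition via explicit rotation matrices (oracle for the
# quaternion path).
euler_zyx_from_matrix <- function(R) {
  c(yaw = atan2(R[2, 1], R[1, 1]) * 180 / pi,
    pitch = asin(max(-1, min(1, -R[3, 1]))) * 180 / pi,
    roll = atan2(R[3, 2], R[3, 3]) * 180 / pi)
}

rotmat_zyx <- function(yaw, pitch, roll) {
  cz <- cos(yaw * pi / 180); sz <- sin(yaw * pi / 180)
  cy <- cos(pitch * pi / 180); sy <- sin(pitch * pi / 180)
  cx <- cos(roll * pi / 180); sx <- sin(roll * pi / 180)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

# Default fixtures shared across tests
test_profile <- function() anthro_profile(1.76, 60, 0.45, 0.45, 0.80)
test_seg <- function() derive_segment_parameters(test_profile())
test_exo <- function() exo_spec(TRUE, total_mass = 12)

# A one-row measured event with every controlled variable inside the bands
# of the given condition (total mass 60 kg by default).
valid_event_for <- function(condition, total_mass = 60, tol = default_tolerances()) {
  center <- if (condition$magnitude_level == "Low") tol$low_center_pct else
    tol$high_center_pct
  list(event_id = 1L, onset_t = 1, offset_t = 1.35, duration = 0.35,
       peak_magnitude = center / 100 * total_mass * tol$g,
       impulse = 10, mean_pitch = 0,
       mean_yaw = zone_nominal_yaw(condition$location_zone),
       mean_roll = 0,
       active_ids = condition$sensor_ids[[1]][1])
}
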