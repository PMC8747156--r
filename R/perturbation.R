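# Perturbation stream processing: calibration, event detection, relative
# orientation and location resolution for the hand-held perturbator and the
# pressure-sensing garment.

#' Calibrate the 3-axis force sensor
#'
#' Per-axis offsets are the mean of the first 2000 samples recorded with the
#' perturbator unloaded; they are subtracted from all subsequent data with
#' [apply_force_calibration()]. Exactly `n` samples are consumed even if more
#' are supplied.
#'
#' @param samples Data frame with columns `t`, `fx`, `fy`, `fz` (N, raw).
#' @param n Number of calibration samples to average (default 2000).
#' @return Named numeric vector of per-axis offsets in newtons.
#' @export
calibrate_force <- function(samples, n = 2000) {
  if (!is.data.frame(samples) || !all(c("fx", "fy", "fz") %in% names(samples))) {
    stop("samples must have columns fx, fy, fz", call. = FALSE)
  }
  if (nrow(samples) < n) {
    stop(sprintf("force calibration needs at least %d samples, got %d",
                 n, nrow(samples)), call. = FALSE)
  }
  head_rows <- samples[seq_len(n), ]
  c(fx = mean(head_rows$fx), fy = mean(head_rows$fy), fz = mean(head_rows$fz))
}

#' Subtract force offsets from a stream
#'
#' @param samples Force data frame (`t`, `fx`, `fy`, `fz`).
#' @param offsets Output of [calibrate_force()].
#' @return The calibrated data frame.
#' @export
apply_force_calibration <- function(samples, offsets) {
  for (ax in c("fx", "fy", "fz")) samples[[ax]] <- samples[[ax]] - offsets[[ax]]
  samples
}

#' Calibrate the garment pressure sensors
#'
#' Each of the 30 garment sensors gets an activation threshold equal to the
#' mean of its first `n` unloaded samples plus a fixed margin; a sensor is
#' recognized as active when its reported level exceeds its threshold.
#'
#' @param samples Wide data frame with columns `t`, `s1` ... `s30` (raw
#'   activation units).
#' @param n Number of calibration samples per sensor (default 200).
#' @param margin Activation margin added to each baseline mean (raw units).
#' @param n_sensors Expected number of sensors.
#' @return Named numeric vector of thresholds (`s1` ... `s30`).
#' @export
calibrate_garment <- function(samples, n = 200, margin = 0.5, n_sensors = 30) {
  cols <- paste0("s", seq_len(n_sensors))
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols)) {
    stop(sprintf("missing garment sensor series: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(samples) < n) {
    stop(sprintf("garment calibration needs at least %d samples per sensor, got %d",
                 n, nrow(samples)), call. = FALSE)
  }
  head_rows <- samples[seq_len(n), cols]
  setNames(colMeans(head_rows) + margin, cols)
}

#' Resultant force magnitude
#'
#' Euclidean norm of the calibrated 3-axis force.
#'
#' @param samples Force data frame (`fx`, `fy`, `fz`) or numeric matrix.
#' @return Numeric vector of magnitudes in newtons.
#' @export
resultant_magnitude <- function(samples) {
  sqrt(samples$fx^2 + samples$fy^2 + samples$fz^2)
}

#' Detect perturbation events in a calibrated force stream
#'
#' An event is a maximal run of consecutive samples whose resultant force
#' magnitude exceeds the "no force" threshold (5 N). Duration is measured on
#' the sample grid from the first to the last supra-threshold sample (so it
#' quantizes to the 30 Hz grid, +/- one sample). The impulse is the
#' trapezoidal integral of the magnitude extended to the adjacent
#' sub-threshold samples on either side, which captures the onset/offset ramps
#' of a smooth push.
#'
#' @param samples Calibrated force data frame (`t`, `fx`, `fy`, `fz`).
#' @param threshold Detection threshold in newtons (default 5).
#' @return Data frame with one row per event: `event_id`, `onset_t`,
#'   `offset_t`, `duration`, `peak_magnitude`, `impulse`.
#' @export
detect_events <- function(samples, threshold = 5) {
  if (nrow(samples) > 1 && any(diff(samples$t) <= 0)) {
    stop("force stream timestamps must be strictly increasing", call. = FALSE)
  }
  mag <- resultant_magnitude(samples)
  above <- mag > threshold
  if (!any(above)) {
    return(data.frame(event_id = integer(), onset_t = numeric(),
                      offset_t = numeric(), duration = numeric(),
                      peak_magnitude = numeric(), impulse = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  n <- nrow(samples)
  out <- lapply(seq_along(keep), function(k) {
    i0 <- starts[keep[k]]; i1 <- ends[keep[k]]
    # for the impulse integral, follow the sub-threshold onset/offset ramps
    # down to their local minima so the whole push is integrated
    j0 <- i0
    while (j0 > 1 && mag[j0 - 1] < mag[j0]) j0 <- j0 - 1
    j1 <- i1
    while (j1 < n && mag[j1 + 1] < mag[j1]) j1 <- j1 + 1
    data.frame(
      event_id = k,
      onset_t = samples$t[i0],
      offset_t = samples$t[i1],
      duration = samples$t[i1] - samples$t[i0],
      peak_magnitude = max(mag[i0:i1]),
      impulse = pracma::trapz(samples$t[j0:j1], mag[j0:j1])
    )
  })
  do.call(rbind, out)
}

# Pair two timestamped streams by nearest timestamp within a maximum skew.
# Returns indices into `b` for each row of `a` (NA where no match).
nearest_index <- function(ta, tb, max_skew) {
  idx <- findInterval(ta, tb)
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, length(tb))
  pick <- ifelse(abs(ta - tb[lo]) <= abs(tb[hi] - ta), lo, hi)
  skew <- abs(ta - tb[pick])
  pick[skew > max_skew] <- NA_integer_
  pick
}

#' Relative orientation garment -> perturbator
#'
#' Pairs the two IMU streams by nearest timestamp and decomposes the relative
#' rotation `q_garment^-1 * q_perturbator` into intrinsic Z-Y-X (yaw, pitch,
#' roll) Euler angles, i.e. the orientation of the perturbator expressed in
#' the body (garment) frame.
#'
#' @param q_pert,q_garment Data frames with columns `t`, `qw`, `qx`, `qy`,
#'   `qz` (unit quaternions).
#' @param max_skew Maximum timestamp mismatch accepted when pairing streams,
#'   seconds (default one 30 Hz sample).
#' @return Data frame with columns `t` (perturbator timestamps), `pitch`,
#'   `yaw`, `roll` in degrees; rows without a garment sample within
#'   `max_skew` are dropped.
#' @export
relative_orientation <- function(q_pert, q_garment, max_skew = 1 / 30) {
  for (df in list(q_pert, q_garment)) {
    if (!all(c("t", "qw", "qx", "qy", "qz") %in% names(df))) {
      stop("IMU streams need columns t, qw, qx, qy, qz", call. = FALSE)
    }
  }
  idx <- nearest_index(q_pert$t, q_garment$t, max_skew)
  ok <- !is.na(idx)
  qp <- quat_normalize(as.matrix(q_pert[ok, c("qw", "qx", "qy", "qz")]))
  qg <- quat_normalize(as.matrix(q_garment[idx[ok], c("qw", "qx", "qy", "qz")]))
  rel <- quat_multiply(quat_conjugate(qg), qp)
  eul <- quat_to_euler(rel)
  data.frame(t = q_pert$t[ok], pitch = eul$pitch, yaw = eul$yaw,
             roll = eul$roll)
}

#' Event-level orientation
#'
#' Circular mean of the relative pitch/yaw/roll angles over each event's
#' supra-threshold window.
#'
#' @param events Event table from [detect_events()].
#' @param orientation Output of [relative_orientation()].
#' @return `events` with added columns `mean_pitch`, `mean_yaw`, `mean_roll`
#'   (degrees).
#' @export
event_orientation <- function(events, orientation) {
  agg <- function(onset, offset, col) {
    w <- orientation$t >= onset - 1e-9 & orientation$t <= offset + 1e-9
    if (!any(w)) return(NA_real_)
    circular_mean_deg(orientation[[col]][w])
  }
  events$mean_pitch <- mapply(agg, events$onset_t, events$offset_t, "pitch")
  events$mean_yaw <- mapply(agg, events$onset_t, events$offset_t, "yaw")
  events$mean_roll <- mapply(agg, events$onset_t, events$offset_t, "roll")
  events
}

#' Garment zone map
#'
#' The 30 garment pressure sensors grouped into the eight body zones used by
#' the perturbation protocol, in protocol order of first appearance.
#'
#' @return Named list of integer sensor-id vectors.
#' @export
garment_zone_map <- function() {
  list(
    "mid back" = c(1L, 2L, 29L, 30L),
    "upper back" = c(3L, 4L, 27L, 28L),
    "mid torso" = c(10L, 11L, 12L, 19L, 20L, 21L),
    "upper torso" = c(13L, 14L, 15L, 16L, 17L, 18L),
    "right side torso" = c(7L, 8L, 9L),
    "right side shoulder" = c(5L, 6L),
    "left side torso" = c(22L, 23L, 24L),
    "left side shoulder" = c(25L, 26L)
  )
}

#' Resolve the body location of a perturbation
#'
#' Counts, across the garment samples inside the event window, how often each
#' above-threshold sensor is reported among the four most active, and returns
#' the zone accumulating the most such reports. Ties are broken
#' deterministically in favour of the zone appearing first in the protocol
#' (the order of [garment_zone_map()]).
#'
#' @param garment Garment stream data frame with columns `t`, `id1`..`id4`,
#'   `lvl1`..`lvl4` (the four most active sensors per sample).
#' @param thresholds Per-sensor thresholds from [calibrate_garment()].
#' @param onset,offset Event window in seconds.
#' @param zone_map Zone definition, defaults to [garment_zone_map()].
#' @return List with `zone` (label, or `NA` if no sensor was active) and
#'   `active_ids` (integer vector of active sensor ids).
#' @export
resolve_location <- function(garment, thresholds, onset, offset,
                             zone_map = garment_zone_map()) {
  w <- garment$t >= onset - 1e-9 & garment$t <= offset + 1e-9
  if (!any(w)) stop("no garment samples inside the event window",
                    call. = FALSE)
  win <- garment[w, ]
  counts <- integer(length(thresholds))
  for (k in 1:4) {
    id <- win[[paste0("id", k)]]
    lvl <- win[[paste0("lvl", k)]]
    act <- !is.na(id) & lvl > thresholds[id]
    if (any(act)) {
      tab <- table(id[act])
      counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] +
        as.integer(tab)
    }
  }
  active_ids <- which(counts > 0)
  if (!length(active_ids)) {
    return(list(zone = NA_character_, active_ids = integer()))
  }
  zone_votes <- vapply(zone_map, function(s) sum(counts[s]), numeric(1))
  best <- which(zone_votes == max(zone_votes))[1]  # first = protocol order
  list(zone = names(zone_map)[best], active_ids = as.integer(active_ids))
}
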