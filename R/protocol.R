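# The 16-condition perturbation protocol: condition table, controlled-variable
# tolerance checks, and session bookkeeping (five valid repetitions per
# condition before advancing).

#' Build the perturbation protocol
#'
#' The sixteen standing-balance conditions: back, front and lateral push
#' locations crossed with two magnitude levels ("Low" = 8 +/- 2% of total
#' weight, "High" = 16 +/- 2%), in the fixed order used during acquisition.
#'
#' @return Data frame with columns `order`, `location_zone`, `sensor_ids`
#'   (list column of integer vectors) and `magnitude_level`.
#' @export
build_protocol <- function() {
  zm <- garment_zone_map()
  zones <- c("mid back", "upper back", "mid back", "upper back",
             "mid torso", "upper torso", "mid torso", "upper torso",
             "right side torso", "right side shoulder",
             "right side torso", "right side shoulder",
             "left side torso", "left side shoulder",
             "left side torso", "left side shoulder")
  levels <- c("Low", "Low", "High", "High",
              "Low", "Low", "High", "High",
              "Low", "Low", "High", "High",
              "Low", "Low", "High", "High")
  out <- data.frame(order = 1:16, location_zone = zones,
                    magnitude_level = levels, stringsAsFactors = FALSE)
  out$sensor_ids <- I(unname(zm[zones]))
  out[, c("order", "location_zone", "sensor_ids", "magnitude_level")]
}

#' Nominal relative yaw for a push perpendicular to the body
#'
#' In the garment (body) frame a compliant push is perpendicular to the body
#' surface at the target zone: 0 degrees yaw for back zones, 180 for front
#' (torso) zones, +90 for the right side and -90 for the left side. Pitch is
#' nominally 0 for all zones.
#'
#' @param zone Zone label from [garment_zone_map()].
#' @return Nominal yaw in degrees.
#' @export
zone_nominal_yaw <- function(zone) {
  yaws <- c("mid back" = 0, "upper back" = 0,
            "mid torso" = 180, "upper torso" = 180,
            "right side torso" = 90, "right side shoulder" = 90,
            "left side torso" = -90, "left side shoulder" = -90)
  if (!zone %in% names(yaws)) stop(sprintf("unknown zone '%s'", zone),
                                   call. = FALSE)
  unname(yaws[zone])
}

#' Controlled-variable tolerances
#'
#' Acceptance bands for the controlled variables of a delivered perturbation.
#' Defaults follow the benchmarking protocol: magnitude 8 +/- 2% ("Low") or
#' 16 +/- 2% ("High") of the total weight (body plus exoskeleton), duration
#' 0.35 +/- 0.15 s, orientation within +/-30 degrees of perpendicular in
#' pitch and yaw, a 5 N "no force" detection threshold, and five valid
#' repetitions per condition.
#'
#' @param low_center_pct,high_center_pct Band centres, percent of total mass.
#' @param pct_halfwidth Band half-width, percent of total mass.
#' @param duration_center_s,duration_halfwidth_s Duration band, seconds.
#' @param orientation_halfwidth_deg Pitch/yaw tolerance about nominal.
#' @param force_threshold_n Event detection threshold, newtons.
#' @param required_reps Valid repetitions needed per condition.
#' @param g Gravitational acceleration used to convert mass percent to force.
#' @return An object of class `tolerances`.
#' @export
default_tolerances <- function(low_center_pct = 8, high_center_pct = 16,
                               pct_halfwidth = 2,
                               duration_center_s = 0.35,
                               duration_halfwidth_s = 0.15,
                               orientation_halfwidth_deg = 30,
                               force_threshold_n = 5,
                               required_reps = 5,
                               g = 9.81) {
  vals <- c(low_center_pct, high_center_pct, pct_halfwidth, duration_center_s,
            duration_halfwidth_s, orientation_halfwidth_deg,
            force_threshold_n, required_reps, g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all tolerance parameters must be positive", call. = FALSE)
  }
  structure(list(
    low_center_pct = low_center_pct, high_center_pct = high_center_pct,
    pct_halfwidth = pct_halfwidth,
    duration_s = c(duration_center_s - duration_halfwidth_s,
                   duration_center_s + duration_halfwidth_s),
    orientation_halfwidth_deg = orientation_halfwidth_deg,
    force_threshold_n = force_threshold_n,
    required_reps = required_reps, g = g
  ), class = "tolerances")
}

#' Magnitude acceptance band in newtons
#'
#' The protocol specifies magnitudes as a percentage of the total mass (body
#' plus exoskeleton); the force band is `pct/100 * M * g` with g = 9.81
#' m/s^2, i.e. a percentage of total weight.
#'
#' @param level "Low" or "High".
#' @param total_mass_kg Total mass (body + exoskeleton) in kilograms.
#' @param tol A [default_tolerances()] object.
#' @return Numeric vector `c(lo, hi)` in newtons.
#' @export
magnitude_bounds <- function(level, total_mass_kg, tol = default_tolerances()) {
  if (!is.finite(total_mass_kg) || total_mass_kg <= 0) {
    stop("total mass must be positive", call. = FALSE)
  }
  center <- switch(level, Low = tol$low_center_pct, High = tol$high_center_pct,
                   stop(sprintf("unknown magnitude level '%s'", level),
                        call. = FALSE))
  (center + c(-1, 1) * tol$pct_halfwidth) / 100 * total_mass_kg * tol$g
}

#' Validate a perturbation event against a protocol condition
#'
#' Checks the four controlled variables: peak magnitude inside the
#' condition's force band, duration inside the (closed) duration band,
#' event-mean pitch and yaw within +/-30 degrees of the zone's nominal
#' perpendicular orientation, and at least one active garment sensor inside
#' the condition's target zone. Roll is recorded but not constrained. The
#' event is valid only if all four checks pass.
#'
#' @param event One-row data frame (or list) with `peak_magnitude`,
#'   `duration`, `mean_pitch`, `mean_yaw` and `active_ids` (integer vector).
#' @param condition One row of [build_protocol()].
#' @param tol A [default_tolerances()] object.
#' @param total_mass_kg Total mass (body + exoskeleton) in kilograms.
#' @return List with `valid`, the four per-variable flags, and the measured
#'   values echoed.
#' @export
validate_event <- function(event, condition, tol = default_tolerances(),
                           total_mass_kg) {
  level <- condition$magnitude_level
  zone <- condition$location_zone
  sensors <- condition$sensor_ids
  if (is.list(sensors) && !is.null(sensors[[1]])) sensors <- sensors[[1]]
  # closed bands; the 1e-9 epsilon keeps grid-exact boundary values inside
  band <- magnitude_bounds(level, total_mass_kg, tol)
  magnitude_ok <- is.finite(event$peak_magnitude) &&
    event$peak_magnitude >= band[1] - 1e-9 &&
    event$peak_magnitude <= band[2] + 1e-9
  duration_ok <- is.finite(event$duration) &&
    event$duration >= tol$duration_s[1] - 1e-9 &&
    event$duration <= tol$duration_s[2] + 1e-9
  nominal <- zone_nominal_yaw(zone)
  active_ids <- event$active_ids
  if (is.list(active_ids)) active_ids <- active_ids[[1]]
  orientation_ok <- is.finite(event$mean_pitch) && is.finite(event$mean_yaw) &&
    abs(event$mean_pitch) <= tol$orientation_halfwidth_deg &&
    abs(angle_diff_deg(event$mean_yaw, nominal)) <= tol$orientation_halfwidth_deg
  location_ok <- length(active_ids) > 0 && any(active_ids %in% sensors)
  list(
    valid = magnitude_ok && duration_ok && orientation_ok && location_ok,
    magnitude_ok = magnitude_ok, duration_ok = duration_ok,
    orientation_ok = orientation_ok, location_ok = location_ok,
    measured = list(peak_magnitude = event$peak_magnitude,
                    duration = event$duration,
                    mean_pitch = event$mean_pitch,
                    mean_yaw = event$mean_yaw,
                    active_ids = active_ids),
    condition_order = condition$order
  )
}

#' Start a new protocol session
#'
#' @param protocol Condition table from [build_protocol()].
#' @param tol A [default_tolerances()] object.
#' @param total_mass_kg Total mass (body + exoskeleton) in kilograms.
#' @return An object of class `session_state` at condition 1 with zero counts.
#' @export
new_session <- function(protocol = build_protocol(),
                        tol = default_tolerances(), total_mass_kg) {
  if (!is.finite(total_mass_kg) || total_mass_kg <= 0) {
    stop("total mass must be positive", call. = FALSE)
  }
  structure(list(
    protocol = protocol, tol = tol, total_mass_kg = total_mass_kg,
    current = 1L,
    valid_counts = integer(nrow(protocol)),
    rejected_counts = integer(nrow(protocol)),
    complete = FALSE
  ), class = "session_state")
}

#' Record a validation result and advance the session
#'
#' A valid result increments the current condition's count; when the count
#' reaches the required number of repetitions the session moves to the next
#' condition, and completes after the last one. Rejected events are counted
#' but never advance the session; there is no cap on rejections.
#'
#' @param state A `session_state` from [new_session()].
#' @param result A validation result from [validate_event()].
#' @return The updated `session_state`.
#' @export
advance <- function(state, result) {
  if (state$complete) {
    stop("session already complete: all conditions have the required repetitions",
         call. = FALSE)
  }
  i <- state$current
  if (isTRUE(result$valid)) {
    state$valid_counts[i] <- state$valid_counts[i] + 1L
    if (state$valid_counts[i] >= state$tol$required_reps) {
      if (i >= nrow(state$protocol)) {
        state$complete <- TRUE
      } else {
        state$current <- i + 1L
      }
    }
  } else {
    state$rejected_counts[i] <- state$rejected_counts[i] + 1L
  }
  state
}

#' @export
print.session_state <- function(x, ...) {
  cat(sprintf("Protocol session: condition %d/%d%s; %d valid, %d rejected events\n",
              x$current, nrow(x$protocol),
              if (x$complete) " (complete)" else "",
              sum(x$valid_counts), sum(x$rejected_counts)))
  invisible(x)
}

#' Validate a sequence of events against the protocol
#'
#' Runs the session state machine over a time-ordered table of measured
#' events: each event is validated against the condition the session is
#' currently on, logged with its per-variable flags, and the session advances
#' after each fifth valid repetition.
#'
#' @param events Event table with measurement columns as required by
#'   [validate_event()] (including `active_ids` as a list column).
#' @param protocol Condition table from [build_protocol()].
#' @param tol A [default_tolerances()] object.
#' @param total_mass_kg Total mass (body + exoskeleton) in kilograms.
#' @return List with `log` (one row per event: condition, measured values,
#'   flags) and the final `state`.
#' @export
run_protocol_validation <- function(events, protocol = build_protocol(),
                                    tol = default_tolerances(),
                                    total_mass_kg) {
  state <- new_session(protocol, tol, total_mass_kg)
  rows <- vector("list", nrow(events))
  for (k in seq_len(nrow(events))) {
    ev <- events[k, ]
    res <- validate_event(ev, protocol[state$current, ], tol, total_mass_kg)
    rows[[k]] <- data.frame(
      event_id = ev$event_id, condition_order = res$condition_order,
      onset_t = ev$onset_t, duration = ev$duration,
      peak_magnitude = ev$peak_magnitude, impulse = ev$impulse,
      mean_pitch = ev$mean_pitch, mean_yaw = ev$mean_yaw,
      mean_roll = if ("mean_roll" %in% names(ev)) ev$mean_roll else NA_real_,
      zone = if ("zone" %in% names(ev)) ev$zone else NA_character_,
      magnitude_ok = res$magnitude_ok, duration_ok = res$duration_ok,
      orientation_ok = res$orientation_ok, location_ok = res$location_ok,
      valid = res$valid, stringsAsFactors = FALSE
    )
    state <- advance(state, res)
    if (state$complete && k < nrow(events)) {
      rows <- rows[seq_len(k)]
      warning(sprintf("session complete after event %d; %d later events ignored",
                      k, nrow(events) - k), call. = FALSE)
      break
    }
  }
  list(log = do.call(rbind, rows), state = state)
}
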