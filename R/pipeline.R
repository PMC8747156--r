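# End-to-end analysis: manifest -> calibration -> event detection ->
# controlled-variable validation -> balance indicators -> summaries.

#' Measure perturbation events from calibrated streams
#'
#' Combines force event detection, event-level relative orientation and
#' garment location resolution into one measured-event table ready for
#' protocol validation.
#'
#' @param force Calibrated force stream.
#' @param imu_perturbator,imu_garment IMU quaternion streams.
#' @param garment Garment activation stream.
#' @param thresholds Garment thresholds from [calibrate_garment()].
#' @param tol A [default_tolerances()] object (supplies the detection
#'   threshold).
#' @return Event table with kinematic-free controlled-variable measurements;
#'   `active_ids` is a list column.
#' @export
measure_events <- function(force, imu_perturbator, imu_garment, garment,
                           thresholds, tol = default_tolerances()) {
  events <- detect_events(force, threshold = tol$force_threshold_n)
  if (!nrow(events)) return(events)
  orientation <- relative_orientation(imu_perturbator, imu_garment)
  events <- event_orientation(events, orientation)
  loc <- lapply(seq_len(nrow(events)), function(k) {
    resolve_location(garment, thresholds, events$onset_t[k],
                     events$offset_t[k])
  })
  events$zone <- vapply(loc, function(l) l$zone, character(1))
  events$active_ids <- I(lapply(loc, function(l) l$active_ids))
  events
}

#' Analyze a recorded or simulated session
#'
#' Full pipeline: reads the manifest, calibrates the force and garment
#' streams, detects and measures perturbation events, validates them against
#' the 16-condition protocol, computes the balance indicators (peak body
#' sway and recovery time) for every accepted repetition from the
#' joint-angle stream through the planar CoM model, and summarizes per
#' condition.
#'
#' @param manifest Path to a `manifest.yaml` (see [write_session()]) or an
#'   in-memory `simulated_session`.
#' @param smooth_hz Optional low-pass cutoff (Hz) applied to the sway angle
#'   before differentiation when computing recovery times; use with noisy
#'   angle streams. Default `NULL` (off).
#' @param response_window_s Response window for the sway extremum, seconds.
#' @return An object of class `analysis`: list with `events` (measured),
#'   `log` (validation log), `outcomes` (per-repetition indicators),
#'   `summary` (per-condition mean/SD), `qsway` (the two sway-angle series)
#'   and `state` (final session state).
#' @export
analyze_session <- function(manifest, smooth_hz = NULL,
                            response_window_s = 3) {
  if (inherits(manifest, "simulated_session")) {
    streams <- manifest$streams
    cal_force <- manifest$calibration$force
    cal_garment <- manifest$calibration$garment
    cfg <- list(subject = manifest$config$subject, exo = manifest$config$exo,
                tol = manifest$config$tol,
                protocol = manifest$config$protocol)
  } else {
    m <- read_manifest(manifest)
    streams <- list(
      force = read_stream(m$streams$force, "force"),
      imu_perturbator = read_stream(m$streams$imu_perturbator, "imu"),
      imu_garment = read_stream(m$streams$imu_garment, "imu"),
      garment = read_stream(m$streams$garment, "garment"),
      joints = read_stream(m$streams$joints, "joints")
    )
    cal_force <- read_stream(m$calibration$force, "force")
    cal_garment <- read_stream(m$calibration$garment, "garment_wide")
    cfg <- m$config
  }
  tol <- cfg$tol
  total_mass <- cfg$subject$total_mass + cfg$exo$total_mass

  offsets <- calibrate_force(cal_force)
  force <- apply_force_calibration(streams$force, offsets)
  thresholds <- calibrate_garment(cal_garment)

  protocol <- cfg$protocol %||% build_protocol()
  events <- measure_events(force, streams$imu_perturbator,
                           streams$imu_garment, streams$garment,
                           thresholds, tol)
  val <- run_protocol_validation(events, protocol = protocol, tol = tol,
                                 total_mass_kg = total_mass)

  # sway angle series for both planes, reconstructed once from joint angles
  seg <- derive_segment_parameters(cfg$subject)
  exo <- if (cfg$exo$present) cfg$exo else NULL
  qs_ap <- compute_qsway(sagittal_com(streams$joints, seg, exo))
  qs_ml <- compute_qsway(frontal_com(streams$joints, seg, exo))

  full_protocol <- build_protocol()  # zone lookup by condition order
  log <- val$log
  accepted <- log[log$valid, ]
  outcomes <- NULL
  if (nrow(accepted)) {
    rows <- lapply(seq_len(nrow(accepted)), function(k) {
      row <- accepted[k, ]
      zone <- full_protocol$location_zone[row$condition_order]
      plane <- zone_response_direction(zone)$plane
      series <- if (plane == "AP") qs_ap else qs_ml
      rec <- recovery_time(series, row$onset_t, smooth_hz = smooth_hz)
      win <- min(response_window_s,
                 if (is.na(rec)) response_window_s else max(rec, 1 / 30))
      data.frame(event_id = row$event_id,
                 condition_order = row$condition_order,
                 plane = plane,
                 q_sway_max = body_sway(series, row$onset_t, window = win),
                 recovery_time = rec)
    })
    outcomes <- do.call(rbind, rows)
    outcomes$repetition <- unsplit(lapply(
      split(outcomes$condition_order, outcomes$condition_order), seq_along),
      outcomes$condition_order)
  }
  structure(list(events = events, log = log, outcomes = outcomes,
                 summary = if (!is.null(outcomes)) summarize_outcomes(outcomes)
                           else NULL,
                 qsway = list(AP = qs_ap, ML = qs_ml),
                 state = val$state), class = "analysis")
}

#' @export
print.analysis <- function(x, ...) {
  n_acc <- sum(x$log$valid)
  cat(sprintf("Session analysis: %d events, %d accepted, %d rejected%s\n",
              nrow(x$log), n_acc, sum(!x$log$valid),
              if (x$state$complete) "; protocol complete" else ""))
  if (!is.null(x$summary)) {
    cat(sprintf("Conditions summarized: %d; |q_sway| mean %.2f deg; recovery mean %.2f s\n",
                nrow(x$summary), mean(abs(x$summary$q_sway_mean)),
                mean(x$summary$recovery_mean, na.rm = TRUE)))
  }
  invisible(x)
}

#' Plot a sway-angle response
#'
#' Time series of the sway angle around one perturbation, with the event
#' window and (when defined) the recovery time marked. Requires ggplot2.
#'
#' @param series Sway data frame (`t`, `q_sway`).
#' @param onset,offset Event window, seconds.
#' @param recovery Optional recovery time (s after onset) to mark.
#' @param pad Seconds of context around the event window.
#' @return A ggplot object.
#' @export
plot_sway_response <- function(series, onset, offset, recovery = NA,
                               pad = c(1, 4)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sway_response requires ggplot2", call. = FALSE)
  }
  w <- series$t >= onset - pad[1] & series$t <= offset + pad[2]
  p <- ggplot2::ggplot(series[w, ], ggplot2::aes(x = t, y = q_sway)) +
    ggplot2::annotate("rect", xmin = onset, xmax = offset, ymin = -Inf,
                      ymax = Inf, alpha = 0.25, fill = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "body sway (deg)")
  if (!is.na(recovery)) {
    p <- p + ggplot2::geom_vline(xintercept = onset + recovery,
                                 linetype = "dotted")
  }
  p
}

#' Plot per-condition balance-indicator summaries
#'
#' Bar chart of the per-condition mean with SD error bars for one indicator,
#' mirroring the standard presentation of perturbed-stance results.
#'
#' @param summary Summary table from [summarize_outcomes()].
#' @param indicator "q_sway" or "recovery".
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(summary,
                                   indicator = c("q_sway", "recovery")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_condition_summary requires ggplot2", call. = FALSE)
  }
  indicator <- match.arg(indicator)
  mcol <- paste0(indicator, "_mean")
  scol <- paste0(indicator, "_sd")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(condition_order),
                               y = .data[[mcol]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.3) +
    ggplot2::labs(x = "condition",
                  y = if (indicator == "q_sway") "body sway (deg)"
                      else "recovery time (s)")
}
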