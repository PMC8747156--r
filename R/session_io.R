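# Readers and writers for stream files, the session manifest, configuration
# and result tables. All files are plain delimited text (CSV with a header);
# timestamps are seconds since session start, written with 6 decimal places.

stream_schemas <- function() {
  list(
    force = c("t", "fx", "fy", "fz"),
    imu = c("t", "qw", "qx", "qy", "qz"),
    garment = c("t", paste0("id", 1:4), paste0("lvl", 1:4)),
    joints = c("t", "q_ankle", "q_knee", "q_hip", "q_addabd"),
    garment_wide = c("t", paste0("s", 1:30))
  )
}

#' Read a sensor stream file
#'
#' Reads one of the documented delimited stream formats, validates the header
#' and every row (malformed or non-numeric rows are reported with their line
#' number), and returns the samples sorted by timestamp. Joint angles are
#' stored in degrees on disk and converted to radians here, at the boundary.
#'
#' @param path File path.
#' @param type One of "force", "imu", "garment", "joints", "garment_wide".
#' @return A typed, time-sorted data frame.
#' @export
read_stream <- function(path, type = c("force", "imu", "garment", "joints",
                                       "garment_wide")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop(sprintf("stream file not found: %s", path),
                               call. = FALSE)
  schema <- stream_schemas()[[type]]
  nf <- count.fields(path, sep = ",")
  bad <- which(nf != length(schema))
  if (length(bad)) {
    stop(sprintf("malformed row(s) in %s at line(s) %s: expected %d fields",
                 path, paste(utils::head(bad, 5), collapse = ", "),
                 length(schema)), call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), schema)) {
    stop(sprintf("%s: header %s does not match the %s schema (%s)",
                 path, paste(names(df), collapse = ","), type,
                 paste(schema, collapse = ",")), call. = FALSE)
  }
  for (cc in schema) {
    if (!is.numeric(df[[cc]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
      stop(sprintf("%s: non-numeric value in column %s at line %d",
                   path, cc, bad_row + 1L), call. = FALSE)
    }
    if (anyNA(df[[cc]])) {
      stop(sprintf("%s: missing value in column %s at line %d",
                   path, cc, which(is.na(df[[cc]]))[1] + 1L), call. = FALSE)
    }
  }
  df <- df[order(df$t), , drop = FALSE]
  rownames(df) <- NULL
  if (type == "joints") {
    for (cc in setdiff(schema, "t")) df[[cc]] <- deg2rad(df[[cc]])
  }
  if (type == "garment") {
    for (cc in paste0("id", 1:4)) df[[cc]] <- as.integer(df[[cc]])
  }
  df
}

#' Write a sensor stream file
#'
#' Inverse of [read_stream()]: fixed column order, numeric columns formatted
#' with 6 decimal places (sensor ids as integers), joint angles converted
#' back to degrees.
#'
#' @param df Stream data frame.
#' @param path Output path.
#' @param type Stream type, see [read_stream()].
#' @return `path`, invisibly.
#' @export
write_stream <- function(df, path, type = c("force", "imu", "garment",
                                            "joints", "garment_wide")) {
  type <- match.arg(type)
  schema <- stream_schemas()[[type]]
  if (!all(schema %in% names(df))) {
    stop(sprintf("stream is missing columns: %s",
                 paste(setdiff(schema, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  out <- df[, schema]
  if (type == "joints") {
    for (cc in setdiff(schema, "t")) out[[cc]] <- rad2deg(out[[cc]])
  }
  for (cc in schema) {
    out[[cc]] <- if (type == "garment" && grepl("^id", cc)) {
      sprintf("%d", as.integer(out[[cc]]))
    } else {
      sprintf("%.6f", out[[cc]])
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated session to disk
#'
#' Emits the session-manifest layout the processing pipeline consumes: the
#' four runtime streams, the joint-angle stream, the two calibration blocks,
#' a YAML config (subject, exoskeleton, tolerances) and a YAML manifest
#' listing them, plus the ground-truth event table.
#'
#' @param session A `simulated_session` from [generate_session()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- session$streams
  write_stream(st$force, file.path(dir, "force.csv"), "force")
  write_stream(st$imu_perturbator, file.path(dir, "imu_perturbator.csv"), "imu")
  write_stream(st$imu_garment, file.path(dir, "imu_garment.csv"), "imu")
  write_stream(st$garment, file.path(dir, "garment.csv"), "garment")
  write_stream(st$joints, file.path(dir, "joints.csv"), "joints")
  write_stream(session$calibration$force,
               file.path(dir, "force_calibration.csv"), "force")
  write_stream(session$calibration$garment,
               file.path(dir, "garment_calibration.csv"), "garment_wide")
  write_config(session$config, file.path(dir, "config.yaml"))
  truth <- session$truth
  for (cc in names(truth)) {
    if (is.numeric(truth[[cc]]) && !is.integer(truth[[cc]])) {
      truth[[cc]] <- sprintf("%.6f", truth[[cc]])
    }
  }
  write.csv(truth, file.path(dir, "ground_truth_events.csv"),
            row.names = FALSE, quote = TRUE)
  manifest <- list(
    sampling_hz = session$config$fs,
    config = "config.yaml",
    streams = list(force = "force.csv",
                   imu_perturbator = "imu_perturbator.csv",
                   imu_garment = "imu_garment.csv",
                   garment = "garment.csv",
                   joints = "joints.csv"),
    calibration = list(force = "force_calibration.csv",
                       garment = "garment_calibration.csv")
  )
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Write the scenario / analysis configuration
#'
#' One documented YAML dialect holding the subject anthropometrics (m, kg),
#' the exoskeleton spec, and the controlled-variable tolerances. All
#' tolerance values default to the protocol's but are overridable.
#'
#' @param config A [scenario_config()] (or a list with `subject`, `exo`,
#'   `tol` entries).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  s <- config$subject
  e <- config$exo
  tol <- config$tol
  orders <- if (!is.null(config$protocol)) as.integer(config$protocol$order)
            else 1:16
  yaml::write_yaml(list(
    protocol_conditions = orders,
    subject = list(height_m = s$height, total_mass_kg = s$total_mass,
                   shank_length_m = s$shank_length,
                   thigh_length_m = s$thigh_length,
                   hat_length_m = s$hat_length),
    exoskeleton = list(present = e$present, total_mass_kg = e$total_mass,
                       link_mass_fractions = as.list(e$link_masses /
                         max(e$total_mass, 1)),
                       link_com_fractions = as.list(e$link_com_fractions)),
    tolerances = list(low_center_pct = tol$low_center_pct,
                      high_center_pct = tol$high_center_pct,
                      pct_halfwidth = tol$pct_halfwidth,
                      duration_center_s = mean(tol$duration_s),
                      duration_halfwidth_s = diff(tol$duration_s) / 2,
                      orientation_halfwidth_deg = tol$orientation_halfwidth_deg,
                      force_threshold_n = tol$force_threshold_n,
                      required_reps = tol$required_reps,
                      g = tol$g)
  ), path)
  invisible(path)
}

#' Read the scenario / analysis configuration
#'
#' @param path Path to a YAML file written by [write_config()].
#' @return List with `subject` ([anthro_profile()]), `exo` ([exo_spec()]) and
#'   `tol` ([default_tolerances()]).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  s <- y$subject
  subject <- anthro_profile(s$height_m, s$total_mass_kg, s$shank_length_m,
                            s$thigh_length_m, s$hat_length_m)
  e <- y$exoskeleton
  exo <- if (isTRUE(e$present)) {
    exo_spec(TRUE, e$total_mass_kg,
             link_mass_fractions = unlist(e$link_mass_fractions),
             link_com_fractions = unlist(e$link_com_fractions))
  } else {
    exo_spec(FALSE)
  }
  tl <- y$tolerances
  tol <- default_tolerances(
    low_center_pct = tl$low_center_pct %||% 8,
    high_center_pct = tl$high_center_pct %||% 16,
    pct_halfwidth = tl$pct_halfwidth %||% 2,
    duration_center_s = tl$duration_center_s %||% 0.35,
    duration_halfwidth_s = tl$duration_halfwidth_s %||% 0.15,
    orientation_halfwidth_deg = tl$orientation_halfwidth_deg %||% 30,
    force_threshold_n = tl$force_threshold_n %||% 5,
    required_reps = tl$required_reps %||% 5,
    g = tl$g %||% 9.81
  )
  orders <- y$protocol_conditions %||% 1:16
  full <- build_protocol()
  protocol <- full[match(orders, full$order), ]
  rownames(protocol) <- NULL
  list(subject = subject, exo = exo, tol = tol, protocol = protocol)
}

#' Read a session manifest
#'
#' @param path Path to a `manifest.yaml`; stream paths are resolved relative
#'   to the manifest's directory and checked for existence.
#' @return List with `sampling_hz`, resolved `streams` and `calibration`
#'   paths and the parsed `config`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path),
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) file.path(base, p)
  streams <- lapply(y$streams, resolve)
  calibration <- lapply(y$calibration, resolve)
  for (p in c(unlist(streams), unlist(calibration))) {
    if (!file.exists(p)) stop(sprintf("manifest references missing file: %s", p),
                              call. = FALSE)
  }
  list(sampling_hz = y$sampling_hz %||% 30,
       streams = streams, calibration = calibration,
       config = read_config(resolve(y$config)))
}

#' Write analysis result tables
#'
#' Writes the per-event validation log (all measured controlled variables and
#' their flags, the stored audit trail of rejected perturbations), the
#' per-repetition balance-indicator table and the per-condition summary as
#' CSV with a deterministic column order and formatting. Conditions with
#' fewer accepted repetitions than required are flagged incomplete in the
#' summary.
#'
#' @param analysis An `analysis` object from [analyze_session()].
#' @param dir Output directory.
#' @param required_reps Repetitions expected per complete condition.
#' @return Character vector of the written paths, invisibly.
#' @export
write_results <- function(analysis, dir, required_reps = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    for (cc in names(df)) {
      if (is.numeric(df[[cc]]) && !is.integer(df[[cc]])) {
        df[[cc]] <- sprintf("%.6f", df[[cc]])
      }
    }
    df
  }
  paths <- c(validation_log = file.path(dir, "validation_log.csv"),
             balance_indicators = file.path(dir, "balance_indicators.csv"),
             condition_summary = file.path(dir, "condition_summary.csv"))
  write.csv(fmt(analysis$log), paths[["validation_log"]], row.names = FALSE,
            quote = FALSE)
  write.csv(fmt(analysis$outcomes), paths[["balance_indicators"]],
            row.names = FALSE, quote = FALSE)
  summary <- analysis$summary
  summary$complete <- summary$n >= required_reps
  write.csv(fmt(summary), paths[["condition_summary"]], row.names = FALSE,
            quote = FALSE)
  invisible(paths)
}
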