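# Link-segment anthropometry and planar centre-of-mass model.
#
# The body is modelled as a five-segment rigid chain standing on flat feet:
# bilateral shanks, bilateral thighs, and a single HAT (head-arms-trunk)
# segment. The ankle is treated as fixed to the ground, so every posture is a
# planar chain rooted at the ankle. Two planar projections are used: a
# sagittal model driven by ankle/knee/hip flexion and a frontal model driven
# by hip add/abduction only.
#
# Coordinate frame: x forward (antero-posterior positive), y up, z toward the
# subject's right (mediolateral positive). With this choice pushes from the
# front or the right side drive the centre of mass to negative sway angles.

#' Default segment mass fractions
#'
#' Classic Winter/Dempster body-segment mass fractions, expressed per side for
#' shank and thigh. The foot (0.0145 of body mass per side) is folded into the
#' shank because the ankle is modelled as fixed to the ground, giving
#' shank = 0.0465 + 0.0145 = 0.0610. The HAT fraction is always the remainder
#' `1 - 2 * (shank + thigh)` so that segment masses sum exactly to body mass.
#'
#' @return Named numeric vector with elements `shank` and `thigh`.
#' @export
winter_mass_fractions <- function() c(shank = 0.0610, thigh = 0.100)

#' Default segment CoM position fractions
#'
#' Winter/Dempster centre-of-mass locations as a fraction of segment length
#' measured from the proximal end (knee for the shank, hip for the thigh and
#' for the HAT).
#'
#' @return Named numeric vector with elements `shank`, `thigh`, `hat`.
#' @export
winter_com_fractions <- function() c(shank = 0.433, thigh = 0.433, hat = 0.626)

#' Subject anthropometric profile
#'
#' @param height Standing height in metres.
#' @param total_mass Total body mass in kilograms.
#' @param shank_length,thigh_length,hat_length Segment lengths in metres
#'   (ankle-knee, knee-hip, hip-top of HAT).
#' @return An object of class `anthro_profile`.
#' @examples
#' anthro_profile(1.76, 60, 0.45, 0.45, 0.80)
#' @export
anthro_profile <- function(height, total_mass, shank_length, thigh_length,
                           hat_length) {
  vals <- c(height = height, total_mass = total_mass,
            shank_length = shank_length, thigh_length = thigh_length,
            hat_length = hat_length)
  stop_if_not_finite(vals, "anthropometric values")
  if (any(vals <= 0)) {
    stop("all anthropometric values must be strictly positive", call. = FALSE)
  }
  if (shank_length + thigh_length + hat_length > height + 1e-9) {
    stop("segment lengths exceed standing height", call. = FALSE)
  }
  structure(as.list(vals), class = "anthro_profile")
}

#' @export
print.anthro_profile <- function(x, ...) {
  cat(sprintf("Subject: %.2f m, %.1f kg (shank %.2f, thigh %.2f, HAT %.2f m)\n",
              x$height, x$total_mass, x$shank_length, x$thigh_length,
              x$hat_length))
  invisible(x)
}

#' Exoskeleton mass specification
#'
#' Describes the mass distribution of a lower-limb exoskeleton whose links are
#' assumed to have exactly the same lengths as the corresponding human
#' segments (joints perfectly aligned). Link masses are given as fractions of
#' the exoskeleton total mass, per side for shank and thigh; the constraint
#' `2 * shank + 2 * thigh + trunk = 1` is enforced.
#'
#' @param present Logical; is an exoskeleton worn?
#' @param total_mass Exoskeleton mass in kilograms (ignored, forced to zero,
#'   when `present` is `FALSE`).
#' @param link_mass_fractions Named vector `c(shank=, thigh=, trunk=)` of mass
#'   fractions (shank/thigh per side).
#' @param link_com_fractions Named vector of link CoM positions as fractions of
#'   link length from the proximal end (same convention as the human segments).
#' @return An object of class `exo_spec`.
#' @examples
#' exo_spec(TRUE, total_mass = 12)
#' @export
exo_spec <- function(present = FALSE, total_mass = 0,
                     link_mass_fractions = c(shank = 0.15, thigh = 0.20,
                                             trunk = 0.30),
                     link_com_fractions = c(shank = 0.5, thigh = 0.5,
                                            trunk = 0.5)) {
  if (!present) total_mass <- 0
  if (present && total_mass <= 0) {
    stop("an exoskeleton that is present must have positive mass",
         call. = FALSE)
  }
  need <- c("shank", "thigh", "trunk")
  if (!all(need %in% names(link_mass_fractions)) ||
      !all(need %in% names(link_com_fractions))) {
    stop("link fractions must be named shank, thigh, trunk", call. = FALSE)
  }
  fsum <- 2 * link_mass_fractions[["shank"]] + 2 * link_mass_fractions[["thigh"]] +
    link_mass_fractions[["trunk"]]
  if (abs(fsum - 1) > 1e-9) {
    stop("exoskeleton link mass fractions must satisfy 2*shank + 2*thigh + trunk = 1",
         call. = FALSE)
  }
  if (any(link_com_fractions[need] <= 0 | link_com_fractions[need] >= 1)) {
    stop("link CoM fractions must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    present = present,
    total_mass = total_mass,
    link_masses = c(shank = total_mass * link_mass_fractions[["shank"]],
                    thigh = total_mass * link_mass_fractions[["thigh"]],
                    trunk = total_mass * link_mass_fractions[["trunk"]]),
    link_com_fractions = link_com_fractions[need]
  ), class = "exo_spec")
}

#' Derive segment parameters from an anthropometric profile
#'
#' Computes segment masses and CoM locations from total body mass using
#' standard anthropometric fractions (see [winter_mass_fractions()]). The HAT
#' mass is the remainder after both legs, so `2*shank + 2*thigh + hat` equals
#' the total body mass exactly.
#'
#' @param profile An [anthro_profile()].
#' @param mass_fractions Per-side mass fractions for `shank` and `thigh`.
#' @param com_fractions CoM position fractions from the proximal end for
#'   `shank`, `thigh` and `hat`.
#' @return An object of class `segment_parameters` with per-side `masses`
#'   (`shank`, `thigh`) plus the single `hat` mass, `com_fractions`, segment
#'   `lengths` and the `total_mass`.
#' @export
derive_segment_parameters <- function(profile,
                                      mass_fractions = winter_mass_fractions(),
                                      com_fractions = winter_com_fractions()) {
  if (!inherits(profile, "anthro_profile")) {
    stop("profile must be an anthro_profile", call. = FALSE)
  }
  if (any(mass_fractions <= 0) ||
      2 * sum(mass_fractions[c("shank", "thigh")]) >= 1) {
    stop("mass fractions must be positive with 2*(shank + thigh) < 1",
         call. = FALSE)
  }
  if (any(com_fractions <= 0 | com_fractions >= 1)) {
    stop("CoM fractions must lie in (0, 1)", call. = FALSE)
  }
  m <- profile$total_mass
  m_shank <- m * mass_fractions[["shank"]]
  m_thigh <- m * mass_fractions[["thigh"]]
  m_hat <- m - 2 * m_shank - 2 * m_thigh
  structure(list(
    masses = c(shank = m_shank, thigh = m_thigh, hat = m_hat),
    com_fractions = com_fractions[c("shank", "thigh", "hat")],
    lengths = c(shank = profile$shank_length, thigh = profile$thigh_length,
                hat = profile$hat_length),
    total_mass = m
  ), class = "segment_parameters")
}

# Planar chain geometry. Angles are relative joint rotations accumulated
# distally-to-proximally from the ankle, in radians: the shank is tilted by
# q_ankle from vertical, the thigh by q_ankle + q_knee, the HAT by
# q_ankle + q_knee + q_hip. Positive angles tilt segments toward +horizontal.
# Returns the mass-weighted CoM (horizontal, vertical) for one mass set.
chain_com <- function(th1, th2, th3, lengths, masses, com_from_proximal) {
  u1h <- sin(th1); u1v <- cos(th1)
  u2h <- sin(th2); u2v <- cos(th2)
  u3h <- sin(th3); u3v <- cos(th3)
  ls <- lengths[["shank"]]; lt <- lengths[["thigh"]]; lh <- lengths[["hat"]]
  knee_h <- ls * u1h; knee_v <- ls * u1v
  hip_h <- knee_h + lt * u2h; hip_v <- knee_v + lt * u2v
  # shank/thigh CoM fractions are from the proximal (upper) end, so the
  # distance from the chain base is (1 - fraction) * length; the HAT fraction
  # is from its proximal (hip) end, which is the chain side.
  c_sh_h <- (1 - com_from_proximal[["shank"]]) * ls * u1h
  c_sh_v <- (1 - com_from_proximal[["shank"]]) * ls * u1v
  c_th_h <- knee_h + (1 - com_from_proximal[["thigh"]]) * lt * u2h
  c_th_v <- knee_v + (1 - com_from_proximal[["thigh"]]) * lt * u2v
  c_ht_h <- hip_h + com_from_proximal[["hat"]] * lh * u3h
  c_ht_v <- hip_v + com_from_proximal[["hat"]] * lh * u3v
  m_tot <- 2 * masses[["shank"]] + 2 * masses[["thigh"]] + masses[["hat"]]
  list(
    h = (2 * masses[["shank"]] * c_sh_h + 2 * masses[["thigh"]] * c_th_h +
           masses[["hat"]] * c_ht_h) / m_tot,
    v = (2 * masses[["shank"]] * c_sh_v + 2 * masses[["thigh"]] * c_th_v +
           masses[["hat"]] * c_ht_v) / m_tot,
    mass = m_tot
  )
}

exo_masses_as_segments <- function(exo) {
  c(shank = exo$link_masses[["shank"]], thigh = exo$link_masses[["thigh"]],
    hat = exo$link_masses[["trunk"]])
}

exo_com_fractions <- function(exo) {
  c(shank = exo$link_com_fractions[["shank"]],
    thigh = exo$link_com_fractions[["thigh"]],
    hat = exo$link_com_fractions[["trunk"]])
}

check_angles <- function(angles, cols) {
  if (!is.data.frame(angles) || !all(c("t", cols) %in% names(angles))) {
    stop(sprintf("angles must be a data frame with columns t, %s",
                 paste(cols, collapse = ", ")), call. = FALSE)
  }
  for (cc in c("t", cols)) stop_if_not_finite(angles[[cc]], cc)
  if (nrow(angles) > 1 && any(diff(angles$t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  invisible(angles)
}

#' Sagittal-plane centre of mass
#'
#' Computes the antero-posterior CoM trajectory of the five-segment chain from
#' sagittal joint angles (radians; left/right averages). Joint angles are
#' relative rotations accumulated from the ankle: the shank is oriented by
#' `q_ankle` from vertical, the thigh by `q_ankle + q_knee`, the HAT by
#' `q_ankle + q_knee + q_hip`. Positive angles lean segments forward, so a
#' forward lean gives positive `com_x`.
#'
#' When an exoskeleton is present its link CoMs are placed on the same chain
#' (links share the human segment lengths) and the combined CoM is returned
#' via [combine_com()]; pass `component` to obtain the human-only or
#' exoskeleton-only trajectory instead.
#'
#' @param angles Data frame with columns `t`, `q_ankle`, `q_knee`, `q_hip`
#'   (radians).
#' @param seg [derive_segment_parameters()] output.
#' @param exo Optional [exo_spec()]; `NULL` or an absent exoskeleton returns
#'   the human-only CoM unchanged.
#' @param component One of "combined", "human", "exo".
#' @return Data frame with columns `t`, `com_x` (m, forward positive) and
#'   `com_y` (m, up), carrying attribute `plane = "sagittal"`.
#' @export
sagittal_com <- function(angles, seg, exo = NULL,
                         component = c("combined", "human", "exo")) {
  component <- match.arg(component)
  check_angles(angles, c("q_ankle", "q_knee", "q_hip"))
  th1 <- angles$q_ankle
  th2 <- th1 + angles$q_knee
  th3 <- th2 + angles$q_hip
  planar_com(th1, th2, th3, angles$t, seg, exo, component, horiz = "com_x",
             plane = "sagittal")
}

#' Frontal-plane centre of mass
#'
#' Computes the mediolateral CoM trajectory. Only hip add/abduction defines
#' the frontal posture: the legs stand as a vertical column and the HAT is
#' rotated by `q_addabd` about the mid-hip point. Positive `q_addabd` tilts
#' the trunk toward the subject's right, giving positive `com_z`.
#'
#' @inheritParams sagittal_com
#' @param angles Data frame with columns `t` and `q_addabd` (radians).
#' @return Data frame with columns `t`, `com_z` (m, rightward positive) and
#'   `com_y` (m, up), carrying attribute `plane = "frontal"`.
#' @export
frontal_com <- function(angles, seg, exo = NULL,
                        component = c("combined", "human", "exo")) {
  component <- match.arg(component)
  check_angles(angles, "q_addabd")
  zero <- rep(0, nrow(angles))
  planar_com(zero, zero, angles$q_addabd, angles$t, seg, exo, component,
             horiz = "com_z", plane = "frontal")
}

planar_com <- function(th1, th2, th3, t, seg, exo, component, horiz, plane) {
  if (!inherits(seg, "segment_parameters")) {
    stop("seg must come from derive_segment_parameters()", call. = FALSE)
  }
  have_exo <- !is.null(exo) && isTRUE(exo$present)
  make_df <- function(cc) {
    out <- data.frame(t = t, h = cc$h, com_y = cc$v)
    names(out)[2] <- horiz
    attr(out, "plane") <- plane
    out
  }
  if (component == "exo" && !have_exo) {
    stop("no exoskeleton present in this configuration", call. = FALSE)
  }
  if (component != "exo") {
    com_h <- make_df(chain_com(th1, th2, th3, seg$lengths, seg$masses,
                               seg$com_fractions))
  }
  if (component == "human") return(com_h)
  if (!have_exo) return(com_h)  # combined without exoskeleton is the human CoM
  com_e <- make_df(chain_com(th1, th2, th3, seg$lengths,
                             exo_masses_as_segments(exo),
                             exo_com_fractions(exo)))
  if (component == "exo") return(com_e)
  combine_com(com_h, seg$total_mass, com_e, exo$total_mass)
}

#' Combine human and exoskeleton centres of mass
#'
#' Mass-weighted coordinate-wise average
#' `CoM_T = (CoM_H * M_H + CoM_E * M_E) / (M_H + M_E)`. With `m_e = 0` the
#' human trajectory is returned unchanged (bit-identically).
#'
#' @param com_h,com_e CoM data frames sharing the same time base and
#'   coordinate columns.
#' @param m_h,m_e Human and exoskeleton masses in kilograms.
#' @return A CoM data frame of the same shape as `com_h`.
#' @export
combine_com <- function(com_h, m_h, com_e, m_e) {
  if (!is.finite(m_h) || m_h <= 0) stop("human mass must be positive",
                                        call. = FALSE)
  if (!is.finite(m_e) || m_e < 0) stop("exoskeleton mass must be >= 0",
                                       call. = FALSE)
  if (m_e == 0) return(com_h)
  coords <- setdiff(intersect(names(com_h), names(com_e)), "t")
  if (!length(coords)) stop("no shared coordinate columns", call. = FALSE)
  if (nrow(com_h) != nrow(com_e) ||
      any(abs(com_h$t - com_e$t) > 1e-9)) {
    stop("human and exoskeleton CoM series must share the same time base",
         call. = FALSE)
  }
  out <- com_h
  for (cc in coords) {
    out[[cc]] <- (com_h[[cc]] * m_h + com_e[[cc]] * m_e) / (m_h + m_e)
  }
  out
}

#' Body sway angle from a CoM trajectory
#'
#' The sway angle is the inclination of the ankle-to-CoM line from vertical:
#' `q_sway_AP = atan(com_x / com_y)` for the sagittal model and
#' `q_sway_ML = atan(com_z / com_y)` for the frontal model, reported in
#' degrees. With the package's sign conventions, pushes from the front or the
#' right side produce negative sway.
#'
#' @param com A CoM data frame from [sagittal_com()] or [frontal_com()] (the
#'   plane is inferred from whether it carries `com_x` or `com_z`).
#' @return Data frame with columns `t`, `q_sway` (degrees) and `plane`
#'   ("AP" or "ML").
#' @export
compute_qsway <- function(com) {
  if (!is.data.frame(com) || !"com_y" %in% names(com)) {
    stop("com must be a CoM data frame with a com_y column", call. = FALSE)
  }
  if (any(com$com_y <= 0)) {
    stop("com_y must be strictly positive (CoM above the ground)",
         call. = FALSE)
  }
  if ("com_x" %in% names(com)) {
    horiz <- com$com_x; plane <- "AP"
  } else if ("com_z" %in% names(com)) {
    horiz <- com$com_z; plane <- "ML"
  } else {
    stop("com must contain com_x (sagittal) or com_z (frontal)", call. = FALSE)
  }
  data.frame(t = com$t, q_sway = rad2deg(atan(horiz / com$com_y)),
             plane = plane)
}
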