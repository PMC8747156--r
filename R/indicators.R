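# Balance indicators: sway velocity, peak body sway, recovery time, and
# per-condition summaries.

#' Sway angular velocity
#'
#' Central finite difference of the sway angle on its timestamp grid
#' (one-sided differences at the ends). Optional zero-phase low-pass
#' smoothing of the angle before differencing (2nd-order Butterworth applied
#' forward and backward), off by default; enable it when the angle stream is
#' noisy, since differencing amplifies high-frequency noise.
#'
#' @param series Data frame with columns `t` (s) and `q_sway` (degrees).
#' @param smooth_hz Optional low-pass cutoff in Hz; `NULL` (default) disables
#'   smoothing.
#' @return Data frame with columns `t` and `velocity` (deg/s).
#' @export
sway_velocity <- function(series, smooth_hz = NULL) {
  if (nrow(series) < 2) stop("need at least 2 samples", call. = FALSE)
  t <- series$t
  if (any(diff(t) == 0)) stop("duplicate timestamps in sway series",
                              call. = FALSE)
  if (any(diff(t) < 0)) stop("timestamps must be increasing", call. = FALSE)
  q <- series$q_sway
  if (!is.null(smooth_hz)) {
    fs <- 1 / median(diff(t))
    if (smooth_hz >= fs / 2) stop("smoothing cutoff must be below Nyquist",
                                  call. = FALSE)
    bf <- signal::butter(2, smooth_hz / (fs / 2), type = "low")
    q <- as.numeric(signal::filtfilt(bf, q))
  }
  n <- length(q)
  v <- numeric(n)
  if (n == 2) {
    v[] <- (q[2] - q[1]) / (t[2] - t[1])
  } else {
    v[1] <- (q[2] - q[1]) / (t[2] - t[1])
    v[n] <- (q[n] - q[n - 1]) / (t[n] - t[n - 1])
    v[2:(n - 1)] <- (q[3:n] - q[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  data.frame(t = t, velocity = v)
}

#' Peak body sway of a perturbation response
#'
#' The body sway indicator is the signed sway-angle excursion of largest
#' magnitude within the response window, measured relative to the pre-onset
#' baseline (the mean sway angle over the `baseline_s` seconds preceding
#' onset; subjects recover their initial stance between perturbations). The
#' sign is preserved, so pushes from the front or the right side yield
#' negative values.
#'
#' @param series Sway data frame (`t`, `q_sway` in degrees).
#' @param onset Perturbation onset time, seconds.
#' @param window Response window length after onset, seconds (default 3, the
#'   minimum spacing between consecutive perturbations).
#' @param baseline_s Pre-onset baseline averaging window, seconds.
#' @param baseline Either "pre_onset" (default) or "zero" to reference the
#'   excursion to an absolute zero sway angle.
#' @return Signed peak sway in degrees.
#' @export
body_sway <- function(series, onset, window = 3, baseline_s = 0.5,
                      baseline = c("pre_onset", "zero")) {
  baseline <- match.arg(baseline)
  t <- series$t
  if (max(t) < onset + window - 1e-9) {
    stop("sway series ends before the response window", call. = FALSE)
  }
  base <- 0
  if (baseline == "pre_onset") {
    wb <- t >= onset - baseline_s - 1e-9 & t < onset - 1e-9
    if (!any(wb)) stop("no samples in the pre-onset baseline window",
                       call. = FALSE)
    base <- mean(series$q_sway[wb])
  }
  wr <- t >= onset - 1e-9 & t <= onset + window + 1e-9
  dev <- series$q_sway[wr] - base
  dev[which.max(abs(dev))]
}

#' Recovery time after a perturbation
#'
#' Time from perturbation onset until the sway velocity stays below the
#' quiescence threshold (0.86 deg/s) for at least `quiet_s` seconds (0.5 s):
#' the smallest `t* >= onset` such that `|velocity| < threshold` at every
#' sample in `[t*, t* + quiet_s]`. The reported recovery time is
#' `t* - onset`; it is 0 for a trace already quiescent at onset and `NA`
#' (undefined) when no such window exists before the trace ends.
#'
#' @param series Sway data frame (`t`, `q_sway` in degrees).
#' @param onset Perturbation onset time, seconds.
#' @param threshold Quiescence velocity threshold, deg/s.
#' @param quiet_s Required quiescence window, seconds.
#' @param smooth_hz Optional velocity smoothing, see [sway_velocity()].
#' @return Recovery time in seconds, or `NA_real_` if never recovered within
#'   the trace.
#' @export
recovery_time <- function(series, onset, threshold = 0.86, quiet_s = 0.5,
                          smooth_hz = NULL) {
  if (max(series$t) < onset + quiet_s - 1e-9) {
    stop("sway series must extend at least quiet_s past onset", call. = FALSE)
  }
  vel <- sway_velocity(series, smooth_hz = smooth_hz)
  keep <- vel$t >= onset - 1e-9
  t <- vel$t[keep]
  ok <- abs(vel$velocity[keep]) < threshold
  quiescence_start(t, ok, quiet_s) - onset
}

# First time t* such that ok is TRUE at every sample in [t*, t* + quiet_s],
# with the window fully inside the trace. NA if none.
quiescence_start <- function(t, ok, quiet_s) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    if (t[ends[k]] - t[starts[k]] >= quiet_s - 1e-9) return(t[starts[k]])
  }
  NA_real_
}

#' Summarize balance outcomes per condition
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' balance indicator over the accepted repetitions of each condition.
#' Undefined recovery times (`NA`) are dropped from the recovery summary and
#' counted in `n_recovery_undefined`.
#'
#' @param outcomes Data frame with columns `condition_order`, `q_sway_max`
#'   and `recovery_time` (one row per accepted repetition).
#' @return Data frame with one row per condition present in `outcomes`.
#' @export
summarize_outcomes <- function(outcomes) {
  if (!nrow(outcomes)) stop("no outcomes to summarize", call. = FALSE)
  res <- lapply(split(outcomes, outcomes$condition_order), function(d) {
    rt <- d$recovery_time[!is.na(d$recovery_time)]
    data.frame(
      condition_order = d$condition_order[1],
      n = nrow(d),
      q_sway_mean = mean(d$q_sway_max),
      q_sway_sd = if (nrow(d) > 1) sd(d$q_sway_max) else NA_real_,
      recovery_mean = if (length(rt)) mean(rt) else NA_real_,
      recovery_sd = if (length(rt) > 1) sd(rt) else NA_real_,
      n_recovery_undefined = sum(is.na(d$recovery_time))
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$condition_order), ]
}
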