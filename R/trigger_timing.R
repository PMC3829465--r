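#' Online-style head-thrust detection
#'
#' Replicates the real-time trigger rule: when head angular velocity
#' magnitude exceeds the velocity threshold and, at the same sample, the
#' backward-difference acceleration magnitude exceeds the acceleration
#' threshold, a thrust is recognized (and the optotype would be shown).
#' Magnitudes make CW and CCW rotations symmetric. After a trigger, further
#' triggers are suppressed until `|velocity|` has returned below the
#' velocity threshold and a refractory period has elapsed, which prevents
#' double-triggering inside one impulse.
#'
#' Raising either threshold can only remove triggers, never add them
#' (monotonicity in both thresholds).
#'
#' @param yaw_velocity signed yaw velocity (deg/s).
#' @param yaw_acceleration acceleration series (deg/s^2), same length;
#'   defaults to [differentiate_backward()] of the velocity.
#' @param fs sampling rate (Hz).
#' @param protocol a [protocol_config()] supplying both thresholds.
#' @param refractory minimum time (s) after a trigger before re-arming.
#' @param t0 time of the first sample (s).
#' @return Numeric vector of trigger times (s); empty when no thrust occurs.
#' @export
detect_thrusts <- function(yaw_velocity, fs, protocol,
                           yaw_acceleration = NULL, refractory = 0.5,
                           t0 = 0) {
  v <- abs(yaw_velocity)
  if (is.null(yaw_acceleration))
    yaw_acceleration <- differentiate_backward(yaw_velocity, fs)
  a <- abs(yaw_acceleration)
  vt <- protocol$velocity_threshold
  at <- protocol$acceleration_threshold
  cond <- v > vt & a > at
  n <- length(v)
  triggers <- numeric(0)
  armed <- TRUE
  last <- -Inf
  for (k in seq_len(n)) {
    if (!armed && v[k] < vt && (k - 1L) / fs + t0 >= last + refractory)
      armed <- TRUE
    if (armed && cond[k]) {
      last <- t0 + (k - 1L) / fs
      triggers <- c(triggers, last)
      armed <- FALSE
    }
  }
  triggers
}

#' Nominal stimulus scheduling on the vsync grid
#'
#' Stimulus onset and offset can only change at vertical-sync boundaries,
#' so the nominal onset is the first vsync boundary at or after
#' `trigger_time + nominal_delay_frames * frame_duration`, and the offset
#' follows `nominal_duration_frames` frames later. The vsync grid is
#' `vsync_phase + n * frame_duration`.
#'
#' @param trigger_time trigger time (s).
#' @param display a [display_config()].
#' @param vsync_phase phase of the vsync grid (s), default 0.
#' @return Named numeric vector `c(onset, offset)` in seconds, both on the
#'   vsync grid.
#' @export
schedule_stimulus <- function(trigger_time, display, vsync_phase = 0) {
  fd <- display$frame_duration
  target <- trigger_time + display$nominal_delay_frames * fd
  nframes <- ceiling((target - vsync_phase) / fd - 1e-9)
  onset <- vsync_phase + nframes * fd
  c(onset = onset, offset = onset + display$nominal_duration_frames * fd)
}

#' Audit actual stimulus timing from the photodiode channel
#'
#' The photodiode attached to the screen is high for the whole permanence of
#' the optotype, so its edges measure the true onset/offset of each
#' stimulus, independently of OS scheduling and rendering delays. The
#' channel is binarized at mid-range with +/-10% hysteresis (sensor
#' rise-time is microseconds and is neglected). For each trigger, the first
#' rising edge within `max_delay` seconds is the measured onset and the next
#' falling edge the measured offset; if none is found the event is flagged
#' `missing_stimulus`. A stimulus is `valid_during_motion` only if it is
#' extinguished no later than the end of the associated head movement —
#' stimuli that persist past the head-velocity zero crossing can be read
#' with a momentarily stable retina and would distort the functional test.
#'
#' @param photodiode photodiode voltage series.
#' @param t time base (s), same length.
#' @param stimuli data frame with columns `trial_id`, `trigger_time`, and
#'   optionally `nominal_onset`, `nominal_offset`.
#' @param motion_end_times numeric vector (s), one per stimulus row (`NA`
#'   allowed): end of the associated head movement.
#' @param max_delay search horizon for the pulse after each trigger (s).
#' @return The `stimuli` data frame with columns `measured_onset`,
#'   `measured_offset`, `measured_delay`, `measured_duration`,
#'   `valid_during_motion`, `missing_stimulus` filled; the session-level
#'   summary (mean/SD of delay and duration over measured events, in
#'   seconds) is attached as attribute `"timing_summary"` and retrievable
#'   with [timing_summary()].
#' @export
audit_timing <- function(photodiode, t, stimuli,
                         motion_end_times = rep(NA_real_, nrow(stimuli)),
                         max_delay = 0.5) {
  rng <- range(photodiode)
  span <- diff(rng)
  noise_sd <- stats::sd(photodiode[photodiode < rng[1] + span / 2])
  if (!is.finite(noise_sd)) noise_sd <- 0
  distinguishable <- span > 10 * max(noise_sd, 1e-12) || (noise_sd == 0 && span > 0)
  mid <- mean(rng)
  hi_thr <- mid + 0.1 * span
  lo_thr <- mid - 0.1 * span
  n <- length(photodiode)
  rising <- falling <- numeric(0)
  # edge times are interpolated to the mid-range crossing between the two
  # samples straddling the transition, for sub-sample timing accuracy
  cross_time <- function(k) {
    dy <- photodiode[k] - photodiode[k - 1]
    frac <- if (abs(dy) > 1e-300) (mid - photodiode[k - 1]) / dy else 1
    t[k - 1] + min(max(frac, 0), 1) * (t[k] - t[k - 1])
  }
  if (distinguishable) {
    state <- photodiode[1] > mid
    for (k in 2:n) {
      if (!state && photodiode[k] > hi_thr) {
        state <- TRUE
        rising <- c(rising, cross_time(k))
      } else if (state && photodiode[k] < lo_thr) {
        state <- FALSE
        falling <- c(falling, cross_time(k))
      }
    }
  }
  m <- nrow(stimuli)
  out <- stimuli
  out$measured_onset <- out$measured_offset <- rep(NA_real_, m)
  out$measured_delay <- out$measured_duration <- rep(NA_real_, m)
  out$valid_during_motion <- rep(NA, m)
  out$missing_stimulus <- rep(TRUE, m)
  for (i in seq_len(m)) {
    tr <- stimuli$trigger_time[i]
    cand <- rising[rising >= tr & rising <= tr + max_delay]
    if (length(cand) == 0) next
    on <- cand[1]
    offc <- falling[falling > on]
    if (length(offc) == 0) next
    off <- offc[1]
    out$measured_onset[i] <- on
    out$measured_offset[i] <- off
    out$measured_delay[i] <- on - tr
    out$measured_duration[i] <- off - on
    out$missing_stimulus[i] <- FALSE
    me <- motion_end_times[i]
    out$valid_during_motion[i] <- if (is.na(me)) NA else off <= me
  }
  meas <- !out$missing_stimulus
  attr(out, "timing_summary") <- list(
    n_measured = sum(meas), n_missing = sum(!meas),
    delay_mean = mean(out$measured_delay[meas]),
    delay_sd = stats::sd(out$measured_delay[meas]),
    duration_mean = mean(out$measured_duration[meas]),
    duration_sd = stats::sd(out$measured_duration[meas]))
  out
}

#' Session-level stimulus timing summary
#'
#' @param audited result of [audit_timing()].
#' @return List with `n_measured`, `n_missing`, and mean/SD of measured
#'   delay and duration (s).
#' @export
timing_summary <- function(audited) attr(audited, "timing_summary")
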