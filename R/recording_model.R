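#' Build a synchronized multichannel trace set
#'
#' Container for the synchronized channels recorded (or simulated) during a
#' functional head-impulse session: a 3-axis head gyroscope (deg/s, sensor
#' frame), 3-axis linear acceleration (m/s^2, sensor frame), monocular eye
#' position (deg, eye-in-head, horizontal and vertical), and the photodiode
#' voltage that transduces the presence of the optotype on screen. All
#' channels share one uniform time base.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing
#'   with a constant step `1/fs`. If `NULL`, built as `(0:(n-1))/fs` from the
#'   length of `gyro`.
#' @param gyro n x 3 numeric matrix of angular velocity (deg/s), sensor frame.
#' @param linacc n x 3 numeric matrix of specific force (m/s^2), sensor frame.
#' @param eye_h,eye_v numeric vectors of eye-in-head position (deg); missing
#'   samples (blinks) are `NA`.
#' @param photodiode numeric vector, photodiode output (V).
#' @param fs sampling rate in Hz.
#' @return An object of class `hitd_traces` (a list with the above fields).
#' @seealso [session_recording()], [validate_session()]
#' @export
trace_set <- function(gyro, linacc, eye_h, eye_v, photodiode, fs, t = NULL) {
  gyro <- as.matrix(gyro)
  linacc <- as.matrix(linacc)
  n <- nrow(gyro)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  structure(
    list(t = as.numeric(t), gyro = gyro, linacc = linacc,
         eye_h = as.numeric(eye_h), eye_v = as.numeric(eye_v),
         photodiode = as.numeric(photodiode), fs = as.numeric(fs)),
    class = "hitd_traces")
}

#' Protocol configuration for functional head-impulse testing
#'
#' Thresholds and bookkeeping rules of the testing protocol. Defaults follow
#' the published protocol: a thrust is recognized when head angular velocity
#' exceeds 10 deg/s while acceleration exceeds 300 deg/s^2; thrusts are
#' classified into 1000 deg/s^2-wide acceleration bins with upper bounds
#' 2000-7000 deg/s^2; at least five thrusts are required per bin and
#' direction, escalated to eight once the subject makes a reading error in
#' that bin; the dynamic optotype is the static visual acuity (SVA) size
#' increased by 0.6 logMAR, viewed at 1 m.
#'
#' @param velocity_threshold deg/s, head angular velocity trigger threshold.
#' @param acceleration_threshold deg/s^2, head angular acceleration trigger
#'   threshold.
#' @param bin_width deg/s^2, width of each acceleration bin.
#' @param bin_upper_bounds deg/s^2, strictly increasing upper bounds of the
#'   acceleration bins; spacing must equal `bin_width`.
#' @param min_thrusts_per_bin minimum thrusts per (direction, bin) cell.
#' @param escalated_thrusts_per_bin required thrusts once a reading error
#'   occurred in the cell.
#' @param sva_increment logMAR added to the measured SVA for dynamic testing.
#' @param viewing_distance meters from eye to screen.
#' @return An object of class `hitd_protocol`.
#' @export
protocol_config <- function(velocity_threshold = 10,
                            acceleration_threshold = 300,
                            bin_width = 1000,
                            bin_upper_bounds = seq(2000, 7000, by = 1000),
                            min_thrusts_per_bin = 5L,
                            escalated_thrusts_per_bin = 8L,
                            sva_increment = 0.6,
                            viewing_distance = 1.0) {
  structure(
    list(velocity_threshold = velocity_threshold,
         acceleration_threshold = acceleration_threshold,
         bin_width = bin_width,
         bin_upper_bounds = as.numeric(bin_upper_bounds),
         min_thrusts_per_bin = as.integer(min_thrusts_per_bin),
         escalated_thrusts_per_bin = as.integer(escalated_thrusts_per_bin),
         sva_increment = sva_increment,
         viewing_distance = viewing_distance),
    class = "hitd_protocol")
}

#' Display configuration
#'
#' Stimulus timing is expressible only in multiples of the frame duration,
#' the inverse of the screen's vertical refresh rate: the optotype onset is
#' delayed by a whole number of frames after the trigger and stays on screen
#' for a whole number of frames.
#'
#' @param refresh_rate screen vertical refresh rate (Hz).
#' @param nominal_delay_frames integer >= 0, frames between trigger and onset.
#' @param nominal_duration_frames integer >= 1, frames the optotype stays on.
#' @return An object of class `hitd_display`; `frame_duration` (s) is derived.
#' @export
display_config <- function(refresh_rate = 75,
                           nominal_delay_frames = 0L,
                           nominal_duration_frames = 6L) {
  structure(
    list(refresh_rate = as.numeric(refresh_rate),
         nominal_delay_frames = as.integer(nominal_delay_frames),
         nominal_duration_frames = as.integer(nominal_duration_frames),
         frame_duration = 1 / as.numeric(refresh_rate)),
    class = "hitd_display")
}

#' Trial bookkeeping table
#'
#' One row per presented optotype: rotation direction of the head thrust
#' (`"CW"`/`"CCW"`, yaw viewed from above), the Landolt C gap orientation
#' shown (degrees, one of 0, 45, ..., 315), the subject's response (`NA` for
#' no response), correctness (`NA` iff no response), and the trigger time.
#'
#' @param trial_id integer ids.
#' @param direction character, `"CW"` or `"CCW"`.
#' @param trigger_time_s seconds from recording start.
#' @param orientation_deg presented gap orientation (deg).
#' @param response_deg reported orientation (deg) or `NA`.
#' @param correct logical or `NA` (must be `NA` iff `response_deg` is `NA`).
#' @param nominal_delay_frames,nominal_duration_frames per-trial display
#'   timing (frames); defaults taken from the session display config if `NA`.
#' @return A `data.frame` with one row per trial.
#' @export
trial_table <- function(trial_id, direction, trigger_time_s, orientation_deg,
                        response_deg = NA_real_, correct = NA,
                        nominal_delay_frames = NA_integer_,
                        nominal_duration_frames = NA_integer_) {
  n <- length(trial_id)
  data.frame(trial_id = as.integer(trial_id),
             direction = rep_len(as.character(direction), n),
             trigger_time_s = rep_len(as.numeric(trigger_time_s), n),
             orientation_deg = rep_len(as.numeric(orientation_deg), n),
             response_deg = rep_len(as.numeric(response_deg), n),
             correct = rep_len(as.logical(correct), n),
             nominal_delay_frames = rep_len(as.integer(nominal_delay_frames), n),
             nominal_duration_frames = rep_len(as.integer(nominal_duration_frames), n),
             stringsAsFactors = FALSE)
}

#' Assemble a session recording
#'
#' The universal exchange object of the package: synchronized traces,
#' protocol and display configuration, the trial table, and free-form
#' metadata (subject id, measured SVA, simulation seed, ...).
#'
#' @param traces a [trace_set()].
#' @param protocol a [protocol_config()].
#' @param display a [display_config()].
#' @param trials a [trial_table()] data frame (may have zero rows).
#' @param meta named list of free-form metadata.
#' @return An object of class `hitd_session`.
#' @export
session_recording <- function(traces, protocol = protocol_config(),
                              display = display_config(),
                              trials = trial_table(integer(0), character(0),
                                                   numeric(0), numeric(0)),
                              meta = list()) {
  structure(list(traces = traces, protocol = protocol, display = display,
                 trials = trials, meta = meta),
            class = "hitd_session")
}

TRACE_TIME_TOL <- 1e-9

#' Validate a session recording
#'
#' Checks every structural invariant of the session: equal channel lengths
#' (>= 2), a strictly increasing time base with constant step `1/fs` (to
#' 1e-9 s), positive sampling rate, positive protocol thresholds, strictly
#' increasing bin bounds spaced by the bin width, the 5/8 thrust-count
#' ordering, positive refresh rate, integer frame counts, trial orientations
#' on the 45 deg grid, `correct` defined iff a response was given, and every
#' trial trigger time inside the trace time span.
#'
#' Violations are returned, never raised, so the function can be used as a
#' gatekeeper (e.g., by [write_session()]) and in reporting. It is
#' side-effect free and idempotent.
#'
#' @param s a `hitd_session`.
#' @return Character vector of violation descriptors (`"field: rule"`);
#'   empty when the session is well formed.
#' @export
validate_session <- function(s) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  tr <- s$traces
  n <- length(tr$t)
  lens <- c(nrow(tr$gyro), nrow(tr$linacc), length(tr$eye_h),
            length(tr$eye_v), length(tr$photodiode))
  if (n < 2) add("traces$t: all channels must have length >= 2")
  if (any(lens != n))
    add("traces: all channels must have the same length as t")
  if (!is.finite(tr$fs) || tr$fs <= 0) add("traces$fs: must be > 0")
  if (n >= 2) {
    dt <- diff(tr$t)
    if (any(dt <= 0)) add("traces$t: must be strictly increasing")
    if (max(abs(dt - 1 / tr$fs)) > TRACE_TIME_TOL)
      add("traces$t: time step must equal 1/fs within 1e-9 s")
  }
  if (ncol(tr$gyro) != 3) add("traces$gyro: must have 3 columns")
  if (ncol(tr$linacc) != 3) add("traces$linacc: must have 3 columns")

  p <- s$protocol
  if (p$velocity_threshold <= 0) add("protocol$velocity_threshold: must be > 0")
  if (p$acceleration_threshold <= 0)
    add("protocol$acceleration_threshold: must be > 0")
  if (p$bin_width <= 0) add("protocol$bin_width: must be > 0")
  b <- p$bin_upper_bounds
  if (length(b) < 1 || any(diff(b) <= 0))
    add("protocol$bin_upper_bounds: must be strictly increasing")
  if (length(b) > 1 && max(abs(diff(b) - p$bin_width)) > 1e-9)
    add("protocol$bin_upper_bounds: spacing must equal bin_width")
  if (p$min_thrusts_per_bin < 1)
    add("protocol$min_thrusts_per_bin: must be >= 1")
  if (p$escalated_thrusts_per_bin < p$min_thrusts_per_bin)
    add("protocol$escalated_thrusts_per_bin: must be >= min_thrusts_per_bin")

  d <- s$display
  if (d$refresh_rate <= 0) add("display$refresh_rate: must be > 0")
  if (d$nominal_delay_frames < 0)
    add("display$nominal_delay_frames: must be >= 0")
  if (d$nominal_duration_frames < 1)
    add("display$nominal_duration_frames: must be >= 1")
  if (abs(d$frame_duration - 1 / d$refresh_rate) > 1e-12)
    add("display$frame_duration: must equal 1/refresh_rate")

  trl <- s$trials
  if (nrow(trl) > 0) {
    if (!all(trl$direction %in% c("CW", "CCW")))
      add("trials$direction: must be CW or CCW")
    ok_orient <- trl$orientation_deg %in% seq(0, 315, by = 45)
    if (!all(ok_orient))
      add("trials$orientation_deg: must lie on the 45 deg grid 0..315")
    bad_corr <- xor(is.na(trl$response_deg), is.na(trl$correct))
    if (any(bad_corr))
      add("trials$correct: must be defined iff a response was given")
    inside <- trl$trigger_time_s >= tr$t[1] & trl$trigger_time_s <= tr$t[n]
    if (!all(inside))
      add("trials$trigger_time_s: every trigger must lie inside the trace time span")
  }
  v
}

#' @export
print.hitd_session <- function(x, ...) {
  tr <- x$traces
  cat("Functional head-impulse session\n")
  cat(sprintf("  %d samples at %.5g Hz (%.2f s), %d trials\n",
              length(tr$t), tr$fs, diff(range(tr$t)), nrow(x$trials)))
  cat(sprintf("  bins: upper bounds %s deg/s^2; thresholds %g deg/s, %g deg/s^2\n",
              paste(x$protocol$bin_upper_bounds, collapse = ", "),
              x$protocol$velocity_threshold, x$protocol$acceleration_threshold))
  cat(sprintf("  display: %g Hz, delay %d frames, duration %d frames\n",
              x$display$refresh_rate, x$display$nominal_delay_frames,
              x$display$nominal_duration_frames))
  nv <- length(validate_session(x))
  if (nv > 0) cat(sprintf("  ** %d validation violation(s) — see validate_session()\n", nv))
  invisible(x)
}
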