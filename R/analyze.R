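#' Run the full analysis chain on a session
#'
#' The offline pipeline applied to a recorded (or simulated) session:
#'
#' 1. gravity calibration from the pre-test baseline and projection of the
#'    gyro onto the earth-vertical axis ([estimate_gravity()],
#'    [vertical_yaw_velocity()]);
#' 2. backward-difference head acceleration and smoothed eye velocity;
#' 3. per-trial impulse segmentation around the recorded trigger times
#'    ([segment_impulse()]; trials are used when present, otherwise
#'    thrusts are re-detected with [detect_thrusts()] on a low-pass
#'    filtered acceleration);
#' 4. VOR gain over the peak-acceleration to peak-velocity window
#'    ([vor_gain()]); impulses with blink (`NA`) samples inside the gain
#'    window are flagged and excluded;
#' 5. acceleration binning ([assign_bin()]) and per-bin reading
#'    performance ([bin_reports()]);
#' 6. photodiode timing audit ([audit_timing()]) against the nominal vsync
#'    schedule;
#' 7. gaze reconstruction, saccade detection and covert/overt labeling
#'    ([gaze_trace()], [detect_saccades()], [label_saccades()]).
#'
#' For landmark detection the yaw velocity is low-pass filtered
#' (zero-phase, `landmark_cutoff` Hz) to stabilize peak finding under gyro
#' noise; the five-sample acceleration slope is fitted on the same
#' filtered series so one definition holds throughout.
#'
#' @param s a `hitd_session`.
#' @param landmark_cutoff low-pass cutoff (Hz) for landmark detection.
#' @param eye_cutoff low-pass cutoff (Hz) for eye velocity.
#' @param saccade_threshold residual-velocity threshold (deg/s) for
#'   [detect_saccades()].
#' @return An object of class `hitd_analysis`: list with `impulses` (one
#'   row per trial: landmarks, impulse acceleration, bin, gain, correct,
#'   excluded + reason), `stimuli` (the audited timing table), `saccades`,
#'   `bins` (the [bin_reports()] table), `classification`
#'   ([classify_performance()]), `timing` (summary list), `gravity_unit`,
#'   `protocol`, `display`, `meta`.
#' @export
analyze_session <- function(s, landmark_cutoff = 30, eye_cutoff = 50,
                            saccade_threshold = 60) {
  tr <- s$traces
  fs <- tr$fs
  t0 <- tr$t[1]
  g_unit <- estimate_gravity(tr$linacc, tr$gyro, fs)
  yaw <- vertical_yaw_velocity(tr$gyro, g_unit)
  yaw_f <- lowpass_zerophase(yaw, fs, landmark_cutoff)
  acc_f <- differentiate_backward(yaw_f, fs)
  eye_vel <- smooth_eye_velocity(tr$eye_h, fs, cutoff = eye_cutoff)

  if (nrow(s$trials) > 0) {
    triggers <- s$trials$trigger_time_s
    trial_ids <- s$trials$trial_id
    correct <- s$trials$correct
    delay_frames <- s$trials$nominal_delay_frames
    dur_frames <- s$trials$nominal_duration_frames
  } else {
    triggers <- detect_thrusts(yaw_f, fs, s$protocol,
                               yaw_acceleration = acc_f, t0 = t0)
    trial_ids <- seq_along(triggers)
    correct <- rep(NA, length(triggers))
    delay_frames <- rep(s$display$nominal_delay_frames, length(triggers))
    dur_frames <- rep(s$display$nominal_duration_frames, length(triggers))
  }
  n <- length(triggers)
  imp_list <- vector("list", n)
  sac_list <- vector("list", n)
  impulses_obj <- vector("list", n)
  nominal <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    di <- display_config(s$display$refresh_rate,
                         if (is.na(delay_frames[i]))
                           s$display$nominal_delay_frames else delay_frames[i],
                         if (is.na(dur_frames[i]))
                           s$display$nominal_duration_frames else dur_frames[i])
    nominal[i, ] <- schedule_stimulus(triggers[i], di)
    imp <- tryCatch(
      segment_impulse(yaw_f, fs, triggers[i], s$protocol,
                      yaw_acceleration = acc_f, t0 = t0),
      error = function(e) e)
    if (inherits(imp, "error")) {
      imp_list[[i]] <- data.frame(
        trial_id = trial_ids[i], trigger_time = triggers[i],
        onset_time = NA_real_, peak_acceleration_time = NA_real_,
        peak_velocity_time = NA_real_, end_time = NA_real_,
        direction = NA_character_, impulse_acceleration = NA_real_,
        peak_velocity = NA_real_, gain = NA_real_, bin = NA_real_,
        correct = correct[i], excluded = TRUE,
        exclusion_reason = conditionMessage(imp),
        stringsAsFactors = FALSE)
      next
    }
    impulses_obj[[i]] <- imp
    win <- imp$gain_window
    i1 <- as.integer(round((win[1] - t0) * fs)) + 1L
    i2 <- as.integer(round((win[2] - t0) * fs)) + 1L
    has_nan <- anyNA(eye_vel[i1:i2])
    gain <- NA_real_
    excl <- FALSE
    reason <- ""
    if (has_nan) {
      excl <- TRUE
      reason <- "blink (NaN) inside gain window"
    } else {
      gain <- tryCatch(vor_gain(yaw, eye_vel, fs, win, t0 = t0),
                       error = function(e) e)
      if (inherits(gain, "error")) {
        excl <- TRUE
        reason <- conditionMessage(gain)
        gain <- NA_real_
      }
    }
    imp_list[[i]] <- data.frame(
      trial_id = trial_ids[i], trigger_time = triggers[i],
      onset_time = imp$onset_time,
      peak_acceleration_time = imp$peak_acceleration_time,
      peak_velocity_time = imp$peak_velocity_time,
      end_time = imp$end_time, direction = imp$direction,
      impulse_acceleration = imp$impulse_acceleration,
      peak_velocity = imp$peak_velocity, gain = gain,
      bin = assign_bin(imp$impulse_acceleration, s$protocol),
      correct = correct[i], excluded = excl, exclusion_reason = reason,
      stringsAsFactors = FALSE)
  }
  impulses <- do.call(rbind, imp_list)
  if (is.null(impulses))
    impulses <- data.frame(
      trial_id = integer(0), trigger_time = numeric(0),
      onset_time = numeric(0), peak_acceleration_time = numeric(0),
      peak_velocity_time = numeric(0), end_time = numeric(0),
      direction = character(0), impulse_acceleration = numeric(0),
      peak_velocity = numeric(0), gain = numeric(0), bin = numeric(0),
      correct = logical(0), excluded = logical(0),
      exclusion_reason = character(0), stringsAsFactors = FALSE)

  stimuli <- data.frame(trial_id = trial_ids, trigger_time = triggers,
                        nominal_onset = nominal[, 1],
                        nominal_offset = nominal[, 2])
  audited <- audit_timing(tr$photodiode, tr$t, stimuli,
                          motion_end_times = impulses$end_time)

  # For the saccade detector the slow-phase prediction uses the median gain
  # of the impulse's direction: a covert saccade inside an impulse's own
  # gain window inflates that impulse's measured gain, which would offset
  # the residual and mask the very saccade to be detected. The per-impulse
  # gain itself is reported unchanged.
  med_gain <- vapply(c(CW = "CW", CCW = "CCW"), function(d) {
    g <- impulses$gain[!impulses$excluded & impulses$direction == d]
    if (length(g) > 0) stats::median(g, na.rm = TRUE) else NA_real_
  }, numeric(1))
  for (i in seq_len(n)) {
    imp <- impulses_obj[[i]]
    if (is.null(imp) || impulses$excluded[i]) next
    stim_win <- if (!audited$missing_stimulus[i])
      c(audited$measured_onset[i], audited$measured_offset[i])
    else c(audited$nominal_onset[i], audited$nominal_offset[i])
    g_loc <- med_gain[[impulses$direction[i]]]
    if (!is.finite(g_loc)) g_loc <- impulses$gain[i]
    sac <- detect_saccades(eye_vel, yaw, fs,
                           window = c(imp$onset_time, imp$end_time + 0.5),
                           gain_local = g_loc,
                           threshold = saccade_threshold, t0 = t0)
    sac <- label_saccades(sac, imp, stim_win)
    if (nrow(sac) > 0) {
      sac$trial_id <- trial_ids[i]
      sac$direction <- impulses$direction[i]
      sac_list[[i]] <- sac
    }
  }
  saccades <- do.call(rbind, sac_list)
  if (is.null(saccades))
    saccades <- data.frame(onset = numeric(0), offset = numeric(0),
                           amplitude = numeric(0), peak_velocity = numeric(0),
                           label = character(0),
                           latency_from_head_onset = numeric(0),
                           stimulus_overlap_fraction = numeric(0),
                           straddles_head_end = logical(0),
                           trial_id = integer(0), direction = character(0))

  bins <- bin_reports(impulses, s$protocol)
  classification <- classify_performance(bins)
  structure(list(impulses = impulses, stimuli = audited,
                 saccades = saccades, bins = bins,
                 classification = classification,
                 timing = timing_summary(audited),
                 gravity_unit = g_unit, protocol = s$protocol,
                 display = s$display, meta = s$meta,
                 yaw_velocity = yaw, eye_velocity = eye_vel,
                 t = tr$t, fs = fs),
            class = "hitd_analysis")
}

#' @export
print.hitd_analysis <- function(x, ...) {
  ok <- !x$impulses$excluded
  cat("Functional head-impulse analysis\n")
  cat(sprintf("  %d impulses (%d excluded); mean gain CW %.2f, CCW %.2f\n",
              nrow(x$impulses), sum(!ok),
              mean(x$impulses$gain[ok & x$impulses$direction == "CW"]),
              mean(x$impulses$gain[ok & x$impulses$direction == "CCW"])))
  if (!is.null(x$timing) && x$timing$n_measured > 0)
    cat(sprintf("  stimulus timing: delay %.1f +/- %.1f ms, duration %.1f +/- %.1f ms (%d measured, %d missing)\n",
                1e3 * x$timing$delay_mean, 1e3 * x$timing$delay_sd,
                1e3 * x$timing$duration_mean, 1e3 * x$timing$duration_sd,
                x$timing$n_measured, x$timing$n_missing))
  cat(sprintf("  saccades: %d covert, %d overt\n",
              sum(x$saccades$label == "covert"),
              sum(x$saccades$label == "overt")))
  invisible(x)
}

#' Standard end-of-examination report
#'
#' Builds the predefined set of results presented at the end of an
#' examination: per-direction per-bin reading performance with gain
#' statistics, the gain-versus-peak-acceleration table with wrong-reading
#' markers, the stimulus timing audit, the saccade inventory with
#' covert/overt counts, and the impairment classification. All tables are
#' plain data frames (machine-readable); `plot()` draws the standard
#' panels.
#'
#' @param x a `hitd_session` or a `hitd_analysis`.
#' @param ... passed to [analyze_session()] when `x` is a session.
#' @return An object of class `hitd_report`.
#' @export
run_report <- function(x, ...) {
  a <- if (inherits(x, "hitd_analysis")) x else analyze_session(x, ...)
  ok <- !a$impulses$excluded
  gain_table <- a$impulses[, c("trial_id", "direction",
                               "impulse_acceleration", "bin", "gain",
                               "correct", "excluded", "exclusion_reason")]
  sac_counts <- data.frame(
    label = c("covert", "overt"),
    n = c(sum(a$saccades$label == "covert"),
          sum(a$saccades$label == "overt")))
  structure(list(
    n_impulses = nrow(a$impulses), n_excluded = sum(!ok),
    bin_table = a$classification,
    gain_table = gain_table,
    timing = a$timing,
    stimuli = a$stimuli,
    saccade_table = a$saccades,
    saccade_counts = sac_counts,
    analysis = a), class = "hitd_report")
}

#' @export
print.hitd_report <- function(x, ...) {
  cat("=== Functional head-impulse test report ===\n")
  if (x$n_impulses == 0) {
    cat("No head impulses detected in this session.\n")
    return(invisible(x))
  }
  cat(sprintf("Impulses: %d (%d excluded)\n", x$n_impulses, x$n_excluded))
  cat("\nPer-bin reading performance:\n")
  b <- x$bin_table
  b$percent_correct <- round(b$percent_correct, 1)
  b$gain_mean <- round(b$gain_mean, 3)
  b$gain_sd <- round(b$gain_sd, 3)
  b$p_value <- signif(b$p_value, 3)
  print(as.data.frame(b), row.names = FALSE)
  if (!is.null(x$timing) && x$timing$n_measured > 0) {
    cat(sprintf("\nStimulus timing: delay %.1f +/- %.1f ms, duration %.1f +/- %.1f ms (%d measured, %d missing)\n",
                1e3 * x$timing$delay_mean, 1e3 * x$timing$delay_sd,
                1e3 * x$timing$duration_mean, 1e3 * x$timing$duration_sd,
                x$timing$n_measured, x$timing$n_missing))
    nval <- sum(!x$stimuli$valid_during_motion, na.rm = TRUE)
    if (nval > 0)
      cat(sprintf("  ** %d stimulus/stimuli persisted past the end of head motion\n", nval))
  } else {
    cat("\nStimulus timing: no photodiode pulses measured (all missing)\n")
  }
  cat(sprintf("\nSaccades: %d covert, %d overt\n",
              x$saccade_counts$n[1], x$saccade_counts$n[2]))
  invisible(x)
}

#' @export
plot.hitd_report <- function(x, ...) {
  a <- x$analysis
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ok <- !a$impulses$excluded
  for (d in c("CW", "CCW")) {
    imp <- a$impulses[ok & a$impulses$direction == d, , drop = FALSE]
    graphics::plot(NULL, xlim = c(-0.05, 0.45),
                   ylim = c(-350, 350), xlab = "time from onset (s)",
                   ylab = "velocity (deg/s)",
                   main = paste("Head (black) / eye (red),", d))
    for (k in seq_len(nrow(imp))) {
      i1 <- max(1L, as.integer(round((imp$onset_time[k] - a$t[1]) * a$fs)) - 10L)
      i2 <- min(length(a$t), i1 + as.integer(0.5 * a$fs))
      tt <- a$t[i1:i2] - imp$onset_time[k]
      graphics::lines(tt, a$yaw_velocity[i1:i2], col = "black")
      graphics::lines(tt, a$eye_velocity[i1:i2], col = "red")
    }
  }
  imp <- a$impulses[ok, , drop = FALSE]
  graphics::plot(imp$impulse_acceleration, imp$gain,
                 pch = ifelse(!is.na(imp$correct) & !imp$correct, 4, 1),
                 col = ifelse(imp$direction == "CW", "blue", "darkgreen"),
                 xlab = "peak head acceleration (deg/s^2)", ylab = "VOR gain",
                 main = "Gain vs acceleration (x = wrong reading)")
  graphics::abline(h = 1, lty = 2)
  b <- x$bin_table
  bb <- b[!is.na(b$percent_correct), , drop = FALSE]
  if (nrow(bb) > 0) {
    graphics::barplot(
      height = bb$percent_correct,
      names.arg = paste(bb$direction, bb$bin_upper_bound),
      las = 2, ylim = c(0, 100), ylab = "% correct",
      main = "Reading performance per bin")
  }
  invisible(x)
}
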