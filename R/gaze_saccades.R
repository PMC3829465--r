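#' Gaze and retinal-slip trace for one impulse
#'
#' Gaze (eye-in-space direction) is the sum of head displacement and
#' eye-in-head displacement, zeroed at the impulse onset where the subject
#' fixates the reference position: with a perfect VOR it stays at zero
#' throughout the thrust. Head displacement is the cumulative trapezoidal
#' integral of head yaw velocity from onset; eye displacement is the eye
#' position re-referenced to its onset value. Retinal slip is the
#' forward-difference derivative of gaze, `slip[k] = (gaze[k+1] - gaze[k])
#' * fs` (last sample repeated): defined this way its rectangle-rule
#' integral telescopes exactly to the gaze change over any sub-window, so
#' slip and gaze are mutually consistent to machine precision. Use
#' [mean_abs_slip()] for window statistics; an optional low-pass is
#' available there for noisy recordings.
#'
#' `NA` (blink) spans inside the window leave gaze defined piecewise and
#' are flagged.
#'
#' @param head_yaw_velocity head yaw velocity series (deg/s, CCW positive).
#' @param eye_h eye-in-head horizontal position series (deg).
#' @param fs sampling rate (Hz).
#' @param onset_time start of the window (s), typically `impulse$onset_time`.
#' @param end_time end of the window (s); defaults to 0.6 s after onset.
#' @param t0 time of the first sample (s).
#' @return An object of class `hitd_gaze`: list with `t`, `gaze` (deg),
#'   `head_displacement` (deg), `eye_displacement` (deg), `retinal_slip`
#'   (deg/s), `fs`, `has_nan` (logical), `nan_spans` (index matrix).
#' @export
gaze_trace <- function(head_yaw_velocity, eye_h, fs, onset_time,
                       end_time = onset_time + 0.6, t0 = 0) {
  n <- length(head_yaw_velocity)
  i1 <- as.integer(round((onset_time - t0) * fs)) + 1L
  i2 <- min(n, as.integer(round((end_time - t0) * fs)) + 1L)
  if (i1 < 1L || i1 >= i2) stop("window outside series")
  idx <- i1:i2
  h <- head_yaw_velocity[idx]
  m <- length(idx)
  hd <- c(0, cumsum((h[-1] + h[-m]) / 2) / fs)
  e <- eye_h[idx]
  ed <- e - e[1]
  gz <- hd + ed
  slip <- c(diff(gz) * fs, NA_real_)
  slip[m] <- slip[m - 1]
  nas <- is.na(gz)
  spans <- NULL
  if (any(nas)) {
    r <- rle(nas)
    en <- cumsum(r$lengths)
    st <- en - r$lengths + 1L
    spans <- cbind(start = st[r$values], end = en[r$values])
  }
  structure(list(t = t0 + (idx - 1L) / fs, gaze = gz,
                 head_displacement = hd, eye_displacement = ed,
                 retinal_slip = slip, fs = fs,
                 has_nan = any(nas), nan_spans = spans),
            class = "hitd_gaze")
}

#' Mean absolute retinal slip over a time window
#'
#' @param gz a [gaze_trace()].
#' @param window `c(t1, t2)` seconds; defaults to the whole trace. The
#'   window is half-open `[t1, t2)` on the slip samples, matching the
#'   forward-difference definition.
#' @param cutoff optional low-pass cutoff (Hz) applied to gaze before
#'   differentiation (for noisy recordings); `NULL` for none.
#' @return Mean of `|retinal slip|` (deg/s) over the window (`NA` values
#'   removed).
#' @export
mean_abs_slip <- function(gz, window = range(gz$t), cutoff = NULL) {
  slip <- gz$retinal_slip
  if (!is.null(cutoff)) {
    g <- gz$gaze
    ok <- !is.na(g)
    if (sum(ok) > 10 && cutoff < gz$fs / 2) {
      gf <- g
      gf[!ok] <- stats::approx(which(ok), g[ok], xout = which(!ok),
                               rule = 2)$y
      gf <- lowpass_zerophase(gf, gz$fs, cutoff)
      slip <- c(diff(gf) * gz$fs, NA_real_)
      slip[length(slip)] <- slip[length(slip) - 1]
      slip[!ok] <- NA_real_
    }
  }
  sel <- gz$t >= window[1] & gz$t < window[2]
  mean(abs(slip[sel]), na.rm = TRUE)
}

#' Detect saccades from residual eye velocity
#'
#' Candidate saccades are contiguous spans where the residual eye velocity
#' `|eye_velocity + gain_local * head_yaw_velocity|` exceeds a threshold
#' for a minimum number of samples. Using the residual rather than raw eye
#' velocity prevents the slow phase of a low-gain response from being
#' detected as a saccade: the impulse's own measured gain predicts the slow
#' phase, and only departures from it count. Spans closer than a merge gap
#' are fused (saccades with dynamic overshoot would otherwise split).
#'
#' @param eye_velocity eye velocity series (deg/s).
#' @param head_yaw_velocity head yaw velocity series (deg/s).
#' @param fs sampling rate (Hz).
#' @param window `c(t1, t2)` search window (s).
#' @param gain_local the impulse's measured VOR gain.
#' @param threshold residual-velocity threshold (deg/s), default 60.
#' @param min_samples minimum span length (samples), default 3.
#' @param merge_gap spans closer than this (s) are merged, default 0.02.
#' @param onset_floor deg/s; after detection each span is extended outward
#'   while the residual stays above this floor, sharpening onset/offset
#'   estimates toward the true start and end of the movement.
#' @param t0 time of the first sample (s).
#' @return Data frame with one row per saccade: `onset`, `offset` (s),
#'   `amplitude` (deg, signed eye displacement over the span),
#'   `peak_velocity` (deg/s, signed, largest-magnitude eye velocity).
#' @export
detect_saccades <- function(eye_velocity, head_yaw_velocity, fs, window,
                            gain_local, threshold = 60, min_samples = 3L,
                            merge_gap = 0.02, onset_floor = 5, t0 = 0) {
  n <- length(eye_velocity)
  i1 <- max(1L, as.integer(round((window[1] - t0) * fs)) + 1L)
  i2 <- min(n, as.integer(round((window[2] - t0) * fs)) + 1L)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0))
  if (i2 <= i1) return(empty)
  idx <- i1:i2
  resid <- eye_velocity[idx] + gain_local * head_yaw_velocity[idx]
  above <- !is.na(resid) & abs(resid) > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  en <- cumsum(r$lengths)
  st <- en - r$lengths + 1L
  runs <- cbind(st[r$values], en[r$values])
  gap_n <- as.integer(round(merge_gap * fs))
  merge_close <- function(sp) {
    out <- sp[1, , drop = FALSE]
    if (nrow(sp) > 1) {
      for (k in 2:nrow(sp)) {
        if (sp[k, 1] - out[nrow(out), 2] - 1L < gap_n)
          out[nrow(out), 2] <- max(out[nrow(out), 2], sp[k, 2])
        else out <- rbind(out, sp[k, , drop = FALSE])
      }
    }
    out
  }
  merged <- merge_close(runs)
  merged <- merged[merged[, 2] - merged[, 1] + 1L >= min_samples, ,
                   drop = FALSE]
  if (nrow(merged) == 0) return(empty)
  # extend each span outward to the onset floor, then re-merge spans the
  # extension brought within the merge gap
  m_len <- length(resid)
  for (k in seq_len(nrow(merged))) {
    a <- merged[k, 1]
    while (a > 1L && !is.na(resid[a - 1L]) &&
           abs(resid[a - 1L]) > onset_floor) a <- a - 1L
    b <- merged[k, 2]
    while (b < m_len && !is.na(resid[b + 1L]) &&
           abs(resid[b + 1L]) > onset_floor) b <- b + 1L
    merged[k, ] <- c(a, b)
  }
  merged <- merge_close(merged)
  rows <- lapply(seq_len(nrow(merged)), function(k) {
    a <- merged[k, 1]; b <- merged[k, 2]
    span <- idx[a]:idx[b]
    ev <- eye_velocity[span]
    m <- length(span)
    amp <- sum((ev[-1] + ev[-m]) / 2) / fs
    data.frame(onset = t0 + (idx[a] - 1L) / fs,
               offset = t0 + (idx[b] - 1L) / fs,
               amplitude = amp,
               peak_velocity = ev[which.max(abs(ev))])
  })
  do.call(rbind, rows)
}

#' Label saccades as covert or overt and score stimulus overlap
#'
#' A corrective saccade is covert when it starts while the head is still
#' moving (onset before the impulse end, i.e. before head velocity returns
#' below the velocity threshold) and overt when it starts after the head
#' movement has ended. Saccades straddling the boundary are labeled by
#' their onset and flagged. The stimulus-overlap fraction is the part of
#' the saccade's duration spent inside the stimulus window (measured
#' photodiode window when available, nominal otherwise).
#'
#' @param saccades data frame from [detect_saccades()].
#' @param impulse a `hitd_impulse` (for `onset_time` and `end_time`).
#' @param stimulus_window `c(onset, offset)` of the stimulus (s), or `NULL`.
#' @return `saccades` with added columns `label` (`"covert"`/`"overt"`),
#'   `latency_from_head_onset` (s), `stimulus_overlap_fraction` (`NA` when
#'   no stimulus window), `straddles_head_end` (logical).
#' @export
label_saccades <- function(saccades, impulse, stimulus_window = NULL) {
  out <- saccades
  n <- nrow(out)
  out$label <- character(n)
  out$latency_from_head_onset <- numeric(n)
  out$stimulus_overlap_fraction <- rep(NA_real_, n)
  out$straddles_head_end <- logical(n)
  if (n == 0) return(out)
  for (k in seq_len(n)) {
    on <- out$onset[k]; off <- out$offset[k]
    out$label[k] <- if (on <= impulse$end_time) "covert" else "overt"
    out$latency_from_head_onset[k] <- on - impulse$onset_time
    out$straddles_head_end[k] <- on < impulse$end_time &&
      off > impulse$end_time
    if (!is.null(stimulus_window) && !anyNA(stimulus_window)) {
      ov <- max(0, min(off, stimulus_window[2]) - max(on, stimulus_window[1]))
      dur <- off - on
      out$stimulus_overlap_fraction[k] <- if (dur > 0) ov / dur
        else as.numeric(on >= stimulus_window[1] && on <= stimulus_window[2])
    }
  }
  out
}

#' Longitudinal comparison of analyzed sessions
#'
#' Summarizes recovery across repeated examinations of one subject: per
#' session and rotation direction the mean VOR gain, covert and overt
#' saccade counts and mean absolute amplitudes, and per-bin percent-correct
#' rates; plus deltas between consecutive sessions on the bins the sessions
#' share. Sessions analyzed under different protocol configurations are
#' still compared on shared bins, with a recorded warning.
#'
#' @param analyses list of two or more [analyze_session()] results.
#' @return List of class `hitd_followup`: `summary` (per session and
#'   direction), `bins` (per session, direction, bin), `deltas` (between
#'   consecutive sessions on shared bins, including gain and
#'   percent-correct changes), `warnings` (character).
#' @export
followup_compare <- function(analyses) {
  if (length(analyses) < 2)
    stop("need at least 2 analyzed sessions")
  warn <- character(0)
  proto <- lapply(analyses, function(a) a$protocol$bin_upper_bounds)
  for (k in 2:length(analyses))
    if (!identical(proto[[k]], proto[[1]]))
      warn <- c(warn, sprintf("session %d uses a different bin layout than session 1", k))
  per_dir <- do.call(rbind, lapply(seq_along(analyses), function(k) {
    a <- analyses[[k]]
    do.call(rbind, lapply(c("CW", "CCW"), function(d) {
      imp <- a$impulses[a$impulses$direction == d & !a$impulses$excluded, ,
                        drop = FALSE]
      sac <- a$saccades[a$saccades$direction == d, , drop = FALSE]
      cov <- sac[sac$label == "covert", , drop = FALSE]
      ovt <- sac[sac$label == "overt", , drop = FALSE]
      data.frame(session = k, direction = d,
                 n_impulses = nrow(imp),
                 gain_mean = if (nrow(imp)) mean(imp$gain) else NA_real_,
                 covert_count = nrow(cov),
                 covert_mean_amplitude = if (nrow(cov))
                   mean(abs(cov$amplitude)) else NA_real_,
                 overt_count = nrow(ovt),
                 overt_mean_amplitude = if (nrow(ovt))
                   mean(abs(ovt$amplitude)) else NA_real_,
                 percent_correct = if (nrow(imp) && any(!is.na(imp$correct)))
                   100 * mean(imp$correct[!is.na(imp$correct)]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  bins <- do.call(rbind, lapply(seq_along(analyses), function(k) {
    b <- analyses[[k]]$bins
    cbind(session = k, as.data.frame(b))
  }))
  deltas <- NULL
  for (k in 2:length(analyses)) {
    b1 <- analyses[[k - 1]]$bins
    b2 <- analyses[[k]]$bins
    shared <- merge(as.data.frame(b1), as.data.frame(b2),
                    by = c("direction", "bin_upper_bound"),
                    suffixes = c("_from", "_to"))
    shared <- shared[shared$n_thrusts_from > 0 & shared$n_thrusts_to > 0, ,
                     drop = FALSE]
    if (nrow(shared) > 0) {
      d <- data.frame(from_session = k - 1, to_session = k,
                      direction = shared$direction,
                      bin_upper_bound = shared$bin_upper_bound,
                      delta_gain = shared$gain_mean_to - shared$gain_mean_from,
                      delta_percent_correct =
                        shared$percent_correct_to - shared$percent_correct_from,
                      stringsAsFactors = FALSE)
      deltas <- rbind(deltas, d)
    } else {
      warn <- c(warn,
                sprintf("sessions %d and %d share no populated bins", k - 1, k))
    }
  }
  # direction-level deltas between consecutive sessions
  dir_deltas <- do.call(rbind, lapply(2:length(analyses), function(k) {
    a <- per_dir[per_dir$session == k - 1, ]
    b <- per_dir[per_dir$session == k, ]
    m <- merge(a, b, by = "direction", suffixes = c("_from", "_to"))
    data.frame(from_session = k - 1, to_session = k,
               direction = m$direction,
               delta_gain = m$gain_mean_to - m$gain_mean_from,
               delta_covert_count = m$covert_count_to - m$covert_count_from,
               delta_overt_count = m$overt_count_to - m$overt_count_from,
               delta_percent_correct =
                 m$percent_correct_to - m$percent_correct_from,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = per_dir, bins = bins, deltas = deltas,
                 direction_deltas = dir_deltas, warnings = warn),
            class = "hitd_followup")
}

#' @export
print.hitd_followup <- function(x, ...) {
  cat("Longitudinal functional-HIT comparison across",
      max(x$summary$session), "sessions\n")
  print(x$summary, row.names = FALSE)
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
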