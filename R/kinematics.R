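#' Estimate the gravity direction from quiescent accelerometer data
#'
#' The head-mounted sensor is worn at an arbitrary (typically ~30 deg
#' nose-down) orientation, so the earth-vertical axis must be recovered from
#' the IMU's linear-acceleration channels before yaw velocity can be
#' computed. During quiescence the accelerometer measures only the specific
#' force opposing gravity; its mean direction over a still baseline is the
#' earth-up axis in sensor coordinates.
#'
#' The baseline is the first contiguous run of at least
#' `max(min_samples, baseline_window * fs)` samples whose gyro magnitude
#' stays below `quiescence_threshold`. Impulses contaminate the
#' accelerometer with inertial components, so gravity is estimated once per
#' session from this pre-test baseline, not continuously.
#'
#' @param linacc n x 3 matrix of specific force (m/s^2, sensor frame).
#' @param gyro n x 3 matrix of angular velocity (deg/s, sensor frame), used
#'   only to find the quiescent window.
#' @param fs sampling rate (Hz).
#' @param baseline_window minimum quiescent duration (s), default 0.2.
#' @param quiescence_threshold gyro magnitude bound (deg/s) defining
#'   quiescence, default 5.
#' @param min_samples minimum number of quiescent samples, default 10.
#' @return Unit 3-vector pointing along the measured specific force
#'   (earth-up) in sensor coordinates.
#' @export
estimate_gravity <- function(linacc, gyro, fs, baseline_window = 0.2,
                             quiescence_threshold = 5, min_samples = 10L) {
  linacc <- as.matrix(linacc)
  gyro <- as.matrix(gyro)
  need <- max(as.integer(min_samples), as.integer(round(baseline_window * fs)))
  quiet <- sqrt(rowSums(gyro^2)) < quiescence_threshold
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0)
    stop("cannot calibrate gravity: no quiescent window of ", need,
         " samples with gyro magnitude < ", quiescence_threshold, " deg/s")
  idx <- starts[ok[1]]:(starts[ok[1]] + need - 1L)
  g <- colMeans(linacc[idx, , drop = FALSE])
  nrm <- sqrt(sum(g^2))
  if (nrm < 1e-12)
    stop("cannot calibrate gravity: zero-norm mean specific force")
  g / nrm
}

#' Earth-vertical (yaw) angular velocity
#'
#' Projects the sensor-frame gyro onto the earth-vertical axis estimated
#' from gravity, yielding the head angular velocity about earth-up. With the
#' right-hand rule about earth-up, positive values are counterclockwise
#' (CCW) head rotations viewed from above and negative values are clockwise
#' (CW); this sign convention is used throughout the package. The projection
#' is invariant to any rigid sensor mounting: rotating gyro and gravity by
#' the same matrix leaves the dot product unchanged.
#'
#' @param gyro n x 3 matrix (deg/s, sensor frame).
#' @param gravity_unit unit 3-vector from [estimate_gravity()].
#' @return Numeric vector of signed yaw velocity (deg/s), CCW positive.
#' @export
vertical_yaw_velocity <- function(gyro, gravity_unit) {
  gravity_unit <- as.numeric(gravity_unit)
  nrm <- sqrt(sum(gravity_unit^2))
  if (abs(nrm - 1) > 1e-6)
    stop("gravity_unit must be a unit vector")
  drop(as.matrix(gyro) %*% gravity_unit)
}

#' Backward-difference angular acceleration
#'
#' The online trigger acceleration: the first backward difference of yaw
#' velocity divided by the sample period, `a[k] = (v[k] - v[k-1]) * fs`,
#' with `a[1] = 0` by convention. This causal definition matches its role
#' as a real-time trigger; the same series is used for offline landmark
#' detection so one acceleration definition holds end-to-end. No filtering
#' is applied.
#'
#' @param v yaw velocity series (deg/s).
#' @param fs sampling rate (Hz).
#' @return Acceleration series (deg/s^2), same length as `v`.
#' @export
differentiate_backward <- function(v, fs) {
  if (length(v) < 2) stop("series must have length >= 2")
  c(0, diff(v) * fs)
}

# Zero-phase Butterworth low-pass with odd (mirror) end padding so that
# constant or trending signals carry no edge transient into the output.
lowpass_zerophase <- function(x, fs, cutoff, order = 2) {
  n <- length(x)
  if (cutoff >= fs / 2 || n < 8) return(x)
  np <- min(n - 1L, 60L)
  front <- 2 * x[1] - x[(np + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - np)]
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(np + 1):(np + n)]
}

#' Smoothed eye velocity from eye position
#'
#' Zero-phase low-pass (2nd-order Butterworth, applied forward and backward)
#' followed by a central-difference derivative. Eye position from
#' video-oculography carries pixel-quantization noise which raw
#' differentiation at 220 Hz would amplify; the default 50 Hz cutoff
#' preserves saccade dynamics (main sequence content < 50 Hz) while
#' suppressing that noise. `NA` (blink) samples propagate as `NA` over the
#' filter support (the blink span dilated by `ceiling(fs / cutoff)` samples
#' on each side).
#'
#' @param eye eye position series (deg); blinks as `NA`.
#' @param fs sampling rate (Hz).
#' @param cutoff low-pass cutoff (Hz); values >= `fs/2` disable filtering.
#' @return Eye velocity series (deg/s), same length.
#' @export
smooth_eye_velocity <- function(eye, fs, cutoff = 50) {
  n <- length(eye)
  if (n < 5) stop("series must have length >= 5")
  nas <- is.na(eye)
  x <- eye
  if (any(nas)) {
    if (all(nas)) return(rep(NA_real_, n))
    x <- stats::approx(which(!nas), eye[!nas], xout = seq_len(n),
                       rule = 2)$y
  }
  x <- lowpass_zerophase(x, fs, cutoff)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  if (any(nas)) {
    pad <- ceiling(fs / max(cutoff, 1))
    bad <- which(nas)
    mask <- unique(pmin(pmax(rep(bad, each = 2 * pad + 1) +
                               (-pad):pad, 1L), n))
    d[mask] <- NA_real_
  }
  d
}

#' Segment one head impulse around a trigger
#'
#' Locates the kinematic landmarks of a single head thrust: onset (last
#' upward crossing of the velocity threshold before the velocity peak), the
#' velocity peak itself, the time of maximum magnitude of the
#' backward-difference acceleration within `[onset, peak]` (ties broken by
#' earliest time), and the end (first return of `|velocity|` below the
#' velocity threshold after the peak). The impulse acceleration is the
#' magnitude of the ordinary-least-squares slope of the five velocity
#' samples centered on the peak-acceleration sample. The VOR gain window is
#' `[peak_acceleration_time, peak_velocity_time]`.
#'
#' @param yaw_velocity signed yaw velocity series (deg/s, CCW positive).
#' @param fs sampling rate (Hz).
#' @param trigger_time trigger time (s, on the trace time base starting at
#'   `t0`).
#' @param protocol a [protocol_config()].
#' @param yaw_acceleration optional acceleration series; defaults to
#'   [differentiate_backward()] of `yaw_velocity`.
#' @param t0 time of the first sample (s), default 0.
#' @param max_duration search horizon after the trigger for the velocity
#'   peak (s). Head thrusts last 80-250 ms, so 0.4 s bounds the search well
#'   clear of the slow return-to-center movement.
#' @return An object of class `hitd_impulse`: a list with `onset_time`,
#'   `peak_acceleration_time`, `peak_velocity_time`, `end_time`,
#'   `direction` (`"CW"`/`"CCW"`), `impulse_acceleration` (deg/s^2,
#'   magnitude), `peak_velocity` (signed deg/s), `gain_window` (length-2
#'   numeric), and the corresponding sample indices.
#' @export
segment_impulse <- function(yaw_velocity, fs, trigger_time, protocol,
                            yaw_acceleration = NULL, t0 = 0,
                            max_duration = 0.4) {
  v <- yaw_velocity
  n <- length(v)
  if (is.null(yaw_acceleration)) yaw_acceleration <- differentiate_backward(v, fs)
  a <- yaw_acceleration
  vt <- protocol$velocity_threshold
  k0 <- as.integer(round((trigger_time - t0) * fs)) + 1L
  if (k0 < 1L || k0 > n) stop("trigger_time outside trace")
  k1 <- min(n, k0 + as.integer(round(max_duration * fs)))
  av <- abs(v)
  win <- k0:k1
  pk <- win[which.max(av[win])]
  if (av[pk] <= vt || pk == n || pk == k1)
    stop("truncated impulse: no velocity peak above threshold before search horizon")
  # onset: last sample below threshold before the peak, then the first
  # sample of the final supra-threshold run
  below <- which(av[1:pk] < vt)
  on <- if (length(below) == 0) 1L else min(below[length(below)] + 1L, pk)
  # end: first return below threshold after the peak
  after <- which(av[(pk + 1L):n] < vt)
  en <- if (length(after) == 0) n else pk + after[1]
  seg <- on:pk
  pa <- seg[which.max(abs(a[seg]))]  # which.max takes the earliest tie
  # The backward difference a[k] estimates the derivative at k - 1/2, so the
  # raw argmax is offset by about half a sample; refine with parabolic
  # interpolation and center the 5-sample slope fit on the nearest sample.
  d <- 0
  if (pa > 1L && pa < n) {
    y1 <- abs(a[pa - 1L]); y2 <- abs(a[pa]); y3 <- abs(a[pa + 1L])
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0) d <- 0.5 * (y1 - y3) / den
    if (!is.finite(d) || abs(d) > 1) d <- 0
  }
  ctr <- min(max(as.integer(round(pa - 0.5 + d)), on), pk)
  # the 5-sample slope magnitude is maximal when the window is centered on
  # the true inflection; evaluate the neighboring centers and keep the best
  slope_at <- function(cc) {
    ks <- max(1L, cc - 2L):min(n, cc + 2L)
    stats::cov(ks / fs, v[ks]) / stats::var(ks / fs)
  }
  cands <- unique(pmin(pmax(ctr + (-1L):1L, on), pk))
  slopes <- vapply(cands, slope_at, numeric(1))
  best <- which.max(abs(slopes))
  pa <- cands[best]
  slope <- slopes[best]
  structure(list(
    onset_time = t0 + (on - 1L) / fs,
    peak_acceleration_time = t0 + (pa - 1L) / fs,
    peak_velocity_time = t0 + (pk - 1L) / fs,
    end_time = t0 + (en - 1L) / fs,
    direction = if (v[pk] >= 0) "CCW" else "CW",
    impulse_acceleration = abs(slope),
    peak_velocity = v[pk],
    gain_window = c(t0 + (pa - 1L) / fs, t0 + (pk - 1L) / fs),
    onset_index = on, peak_acceleration_index = pa,
    peak_velocity_index = pk, end_index = en),
    class = "hitd_impulse")
}

#' @export
print.hitd_impulse <- function(x, ...) {
  cat(sprintf(
    "Head impulse (%s): onset %.3f s, peak accel %.0f deg/s^2 at %.3f s, peak vel %.0f deg/s at %.3f s, end %.3f s\n",
    x$direction, x$onset_time, x$impulse_acceleration,
    x$peak_acceleration_time, x$peak_velocity, x$peak_velocity_time,
    x$end_time))
  invisible(x)
}
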