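#' Subject model for the session simulator
#'
#' Phenomenological model of a subject undergoing functional head-impulse
#' testing: direction-specific slow-phase VOR gains (a unilateral deficit
#' is modeled by a low gain toward the affected side), probabilistic covert
#' and overt corrective saccades, and a logistic reading model linking mean
#' absolute retinal slip during the optotype presentation to the
#' probability of a correct report.
#'
#' The reading model is a stand-in for the unknown true slip-to-legibility
#' relation (which the instrument exists to study): the probability of a
#' correct answer is `chance + (1 - chance - lapse) * plogis(-(s - s50) /
#' sigma)` with `s` the mean absolute retinal slip (deg/s) over the
#' stimulus window, so reading degrades smoothly from near-perfect at zero
#' slip to chance at high slip. All parameters are exposed.
#'
#' @param gain_cw,gain_ccw slow-phase VOR gain for CW / CCW head rotations,
#'   in `[0, 1.2]`.
#' @param covert_prob,overt_prob probability per impulse of a covert
#'   (during head movement) / overt (after head movement) corrective
#'   saccade.
#' @param saccade_latency_mean,saccade_latency_sd covert saccade latency
#'   from head-movement onset (s); draws are truncated at a 50 ms
#'   physiological floor.
#' @param overt_latency_mean,overt_latency_sd overt saccade latency from
#'   head-movement end (s), truncated at 20 ms.
#' @param saccade_gain_correction fraction of the instantaneous gaze error
#'   corrected by a covert saccade (overt saccades correct the full
#'   residual error to regain fixation).
#' @param sva static visual acuity (logMAR).
#' @param slip_threshold_s50 retinal slip (deg/s) at which reading
#'   probability is halfway between floor and ceiling.
#' @param slip_sigma logistic width (deg/s) of the reading model.
#' @param lapse lapse rate of the reading model.
#' @param no_response_prob probability of giving no answer on a trial.
#' @param min_saccade_amplitude deg; corrective saccades are only triggered
#'   when the would-be amplitude exceeds this dead zone (small gaze errors
#'   do not elicit corrective saccades).
#' @return An object of class `hitd_subject`.
#' @export
subject_model <- function(gain_cw = 1.0, gain_ccw = 1.0,
                          covert_prob = 0.1, overt_prob = 0.1,
                          saccade_latency_mean = 0.10,
                          saccade_latency_sd = 0.02,
                          overt_latency_mean = 0.08,
                          overt_latency_sd = 0.03,
                          saccade_gain_correction = 0.8,
                          sva = 0.0,
                          slip_threshold_s50 = 20,
                          slip_sigma = 5,
                          lapse = 0.01,
                          no_response_prob = 0,
                          min_saccade_amplitude = 2) {
  stopifnot(gain_cw >= 0, gain_cw <= 1.2, gain_ccw >= 0, gain_ccw <= 1.2,
            covert_prob >= 0, covert_prob <= 1,
            overt_prob >= 0, overt_prob <= 1,
            saccade_latency_mean > 0)
  structure(as.list(environment()), class = "hitd_subject")
}

#' Raised-cosine head-impulse velocity profile
#'
#' Closed-form yaw-velocity profile of one head thrust:
#' `v(t) = (V/2) (1 - cos(2 pi t / T))` on `[0, T]` with duration
#' `T = pi V / A`, so the peak angular acceleration `max |dv/dt|` equals
#' `A` exactly (at `t = T/4`) and the peak velocity equals `V` (at
#' `t = T/2`). The closed form gives analytic oracles for every landmark.
#' Real impulses are mildly asymmetric; that is not modeled.
#'
#' @param peak_velocity V (deg/s), > 0.
#' @param peak_acceleration A (deg/s^2), > 0.
#' @param direction `"CW"` or `"CCW"`; CCW is positive yaw velocity.
#' @param fs sampling rate (Hz).
#' @return List with `v` (sampled signed velocity, samples `0..floor(T*fs)`),
#'   `T` (s), `peak_velocity`, `peak_acceleration`.
#' @export
gen_impulse_profile <- function(peak_velocity, peak_acceleration,
                                direction = "CCW", fs = 220) {
  stopifnot(peak_velocity > 0, peak_acceleration > 0)
  T_dur <- pi * peak_velocity / peak_acceleration
  if (T_dur * fs < 6)
    stop("unresolvable impulse: duration ", signif(T_dur, 3),
         " s spans fewer than 6 samples at ", fs, " Hz")
  tt <- seq(0, floor(T_dur * fs)) / fs
  v <- (peak_velocity / 2) * (1 - cos(2 * pi * tt / T_dur))
  if (direction == "CW") v <- -v
  list(v = v, T = T_dur, peak_velocity = peak_velocity,
       peak_acceleration = peak_acceleration)
}

# minimum-jerk position profile on tau in [0,1]
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# cumulative trapezoidal integral of a sampled series
cumtrapz_fs <- function(x, fs) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2)) / fs
}

# add a minimum-jerk saccade of given amplitude starting at sample `onset`
# to a position series; duration 25 ms + 2.5 ms/deg (saccadic main sequence)
add_saccade_profile <- function(pos, onset, amplitude, fs) {
  n <- length(pos)
  dur <- 0.025 + 0.0025 * abs(amplitude)
  m <- max(2L, as.integer(round(dur * fs)))
  last <- min(n, onset + m)
  if (onset >= n) return(list(pos = pos, duration = dur))
  span <- onset:last
  tau <- (span - onset) / m
  pos[span] <- pos[span] + amplitude * min_jerk(tau)
  if (last < n) pos[(last + 1L):n] <- pos[(last + 1L):n] + amplitude
  list(pos = pos, duration = dur)
}

#' Eye response to a single head impulse
#'
#' Composes the slow-phase response (eye velocity `-g` times head velocity,
#' with the direction-specific gain) with probabilistic corrective
#' saccades: a covert saccade at a truncated-normal latency from movement
#' onset correcting `saccade_gain_correction` of the instantaneous gaze
#' error, and an overt saccade after the head movement ends correcting the
#' full residual error. Saccades follow a minimum-jerk position profile
#' with duration 25 ms + 2.5 ms per degree. Uses R's global RNG.
#'
#' @param head_v signed head yaw velocity of one impulse and its aftermath
#'   (deg/s), starting at movement onset.
#' @param fs sampling rate (Hz).
#' @param subject a [subject_model()].
#' @param velocity_threshold deg/s, defines the head-movement end (first
#'   return of `|head_v|` below it after the peak).
#' @return List with `eye_pos` (deg, noise-free, starts at 0), `head_end`
#'   (s from the start of the series), and `saccades` (data frame: `onset`
#'   s, `duration` s, `amplitude` deg, `label`, `latency` s).
#' @export
gen_eye_response <- function(head_v, fs, subject,
                             velocity_threshold = 10) {
  n <- length(head_v)
  g <- ifelse(head_v > 0, subject$gain_ccw, subject$gain_cw)
  slow_pos <- cumtrapz_fs(-g * head_v, fs)
  head_disp <- cumtrapz_fs(head_v, fs)
  pk <- which.max(abs(head_v))
  after <- which(abs(head_v[pk:n]) < velocity_threshold)
  end_idx <- if (length(after)) pk + after[1] - 1L else n
  sac_pos <- numeric(n)
  sacs <- data.frame(onset = numeric(0), duration = numeric(0),
                     amplitude = numeric(0), label = character(0),
                     latency = numeric(0), stringsAsFactors = FALSE)
  gaze_at <- function(k) head_disp[k] + slow_pos[k] + sac_pos[k]
  if (stats::runif(1) < subject$covert_prob) {
    lat <- max(0.05, stats::rnorm(1, subject$saccade_latency_mean,
                                  subject$saccade_latency_sd))
    k <- as.integer(round(lat * fs)) + 1L
    if (k < n) {
      amp <- -subject$saccade_gain_correction * gaze_at(k)
      if (abs(amp) >= subject$min_saccade_amplitude) {
        res <- add_saccade_profile(sac_pos, k, amp, fs)
        sac_pos <- res$pos
        lbl <- if (k <= end_idx) "covert" else "overt"
        sacs <- rbind(sacs, data.frame(
          onset = (k - 1L) / fs, duration = res$duration, amplitude = amp,
          label = lbl, latency = (k - 1L) / fs, stringsAsFactors = FALSE))
      }
    }
  }
  if (stats::runif(1) < subject$overt_prob) {
    lat <- max(0.02, stats::rnorm(1, subject$overt_latency_mean,
                                  subject$overt_latency_sd))
    k <- end_idx + as.integer(round(lat * fs))
    if (k < n) {
      amp <- -gaze_at(k)
      if (abs(amp) >= subject$min_saccade_amplitude) {
        res <- add_saccade_profile(sac_pos, k, amp, fs)
        sac_pos <- res$pos
        sacs <- rbind(sacs, data.frame(
          onset = (k - 1L) / fs, duration = res$duration, amplitude = amp,
          label = "overt", latency = (k - 1L) / fs,
          stringsAsFactors = FALSE))
      }
    }
  }
  list(eye_pos = slow_pos + sac_pos, head_end = (end_idx - 1L) / fs,
       saccades = sacs)
}

#' Simulate the display channel for a set of triggers
#'
#' Emulates the rendering pipeline: each stimulus onset is the trigger time
#' plus a random processing latency (truncated normal, default 25 +/- 8 ms
#' emulating measured performance at 75 Hz), quantized up to the next vsync
#' boundary; the offset follows the nominal duration in frames. The
#' photodiode channel is high for the whole permanence of the stimulus and
#' carries additive Gaussian sensor noise. Uses R's global RNG.
#'
#' @param trigger_times numeric vector (s).
#' @param display a [display_config()].
#' @param t trace time base (s).
#' @param latency_model `c(mean, sd)` of the processing latency (s).
#' @param vsync_phase phase of the vsync grid (s).
#' @param noise_sd photodiode noise SD (V).
#' @param high,low photodiode levels (V).
#' @return List with `photodiode` (series) and `events` (data frame:
#'   `trigger_time`, `true_onset`, `true_offset`).
#' @export
gen_display_channel <- function(trigger_times, display, t,
                                latency_model = c(0.025, 0.008),
                                vsync_phase = 0, noise_sd = 0.02,
                                high = 1, low = 0) {
  fd <- display$frame_duration
  pd <- rep(low, length(t))
  ons <- offs <- numeric(length(trigger_times))
  for (i in seq_along(trigger_times)) {
    lat <- max(0, stats::rnorm(1, latency_model[1], latency_model[2]))
    target <- trigger_times[i] + lat
    onset <- vsync_phase + ceiling((target - vsync_phase) / fd - 1e-9) * fd
    offset <- onset + display$nominal_duration_frames * fd
    pd[t >= onset & t < offset] <- high
    ons[i] <- onset
    offs[i] <- offset
  }
  pd <- pd + stats::rnorm(length(pd), 0, noise_sd)
  list(photodiode = pd,
       events = data.frame(trigger_time = trigger_times,
                           true_onset = ons, true_offset = offs))
}

#' Probabilistic reading answer from retinal slip
#'
#' The reading model of [subject_model()]: the probability of a correct
#' report is `chance + (1 - chance - lapse) * plogis(-(s - s50) / sigma)`
#' with `s` the mean absolute retinal slip over the stimulus window. A
#' correct trial reports the presented orientation; an error reports one of
#' the remaining orientations uniformly; with `no_response_prob` the trial
#' has no answer. Uses R's global RNG.
#'
#' @param retinal_slip slip series over the stimulus window (deg/s).
#' @param subject a [subject_model()].
#' @param orientation presented orientation (deg).
#' @param orientations full orientation set.
#' @return List with `response` (deg or `NA`), `correct` (logical or `NA`),
#'   `p_correct`, `slip_mean`.
#' @export
answer_model <- function(retinal_slip, subject, orientation,
                         orientations = ORIENTATIONS) {
  if (length(retinal_slip) == 0) stop("stimulus window is empty")
  chance <- chance_probability(length(orientations))
  s <- mean(abs(retinal_slip), na.rm = TRUE)
  p <- chance + (1 - chance - subject$lapse) *
    stats::plogis(-(s - subject$slip_threshold_s50) / subject$slip_sigma)
  if (stats::runif(1) < subject$no_response_prob)
    return(list(response = NA_real_, correct = NA, p_correct = p,
                slip_mean = s))
  if (stats::runif(1) < p) {
    resp <- orientation
  } else {
    others <- setdiff(orientations, orientation)
    resp <- others[sample.int(length(others), 1L)]
  }
  list(response = resp, correct = resp == orientation, p_correct = p,
       slip_mean = s)
}

#' Simulate a complete functional head-impulse session
#'
#' Generates a fully synthetic, ground-truth-annotated session: head
#' impulses covering the requested acceleration bins in both directions
#' (peak accelerations uniform within each bin, impulse order shuffled),
#' separated by at least one second of rest and followed by a slow
#' sub-threshold return-to-center movement so the head trace stays bounded;
#' slow-phase and saccadic eye responses; a vsync-quantized display with
#' photodiode feedback; and probabilistic reading answers. The sensor is
#' mounted pitched nose-down (default 30 deg), so the earth-vertical
#' rotation is distributed over the gyro axes and must be recovered via the
#' gravity estimate, as in a real recording.
#'
#' Impulse durations are drawn so the peak-acceleration-to-peak-velocity
#' interval (a quarter of the impulse duration) falls in the 35-55 ms band
#' typical of manually imposed thrusts. Peak velocity is then
#' `V = A T / pi`, clamped to 80-400 deg/s.
#'
#' All randomness flows through R's global RNG, seeded with `seed`:
#' identical arguments and seed give identical sessions.
#'
#' @param protocol a [protocol_config()].
#' @param display a [display_config()].
#' @param subject a [subject_model()].
#' @param plan data frame with columns `bin_upper_bound`, `direction`,
#'   `count`, or `NULL` for the default full plan (`n_per_bin` per bin and
#'   direction).
#' @param n_per_bin impulses per (bin, direction) cell of the default plan.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param fs sampling rate (Hz).
#' @param sensor_pitch_deg sensor mounting pitch (deg, nose-down positive).
#' @param latency_model `c(mean, sd)` display processing latency (s).
#' @param gyro_noise_sd gyro white noise SD (deg/s per axis).
#' @param eye_noise_sd eye-velocity white noise SD (deg/s), integrated into
#'   the recorded position channel.
#' @param linacc_noise_sd accelerometer noise SD (m/s^2 per axis).
#' @param photodiode_noise_sd photodiode noise SD (V).
#' @param vsync_phase phase of the vsync grid (s).
#' @param rest quiet time before each impulse (s), >= 1.
#' @param post quiet time after each impulse before the return movement (s).
#' @param return_duration duration of the return-to-center movement (s).
#' @param lead_in initial quiet time for gravity calibration (s).
#' @return List with `session` (a [session_recording()]) and `truth` (list
#'   with per-trial data frame `trials`, per-saccade data frame `saccades`,
#'   and the generating parameters).
#' @export
simulate_session <- function(protocol = protocol_config(),
                             display = display_config(),
                             subject = subject_model(),
                             plan = NULL,
                             n_per_bin = protocol$min_thrusts_per_bin,
                             seed = NULL, fs = 220,
                             sensor_pitch_deg = 30,
                             latency_model = c(0.025, 0.008),
                             gyro_noise_sd = 0.5, eye_noise_sd = 2,
                             linacc_noise_sd = 0.05,
                             photodiode_noise_sd = 0.02,
                             vsync_phase = 0, rest = 1.0, post = 0.7,
                             return_duration = 1.2, lead_in = 1.2) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(plan))
    plan <- expand.grid(bin_upper_bound = protocol$bin_upper_bounds,
                        direction = c("CW", "CCW"),
                        count = n_per_bin, stringsAsFactors = FALSE)
  rows <- plan[rep(seq_len(nrow(plan)), plan$count), c("bin_upper_bound",
                                                       "direction")]
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  n_imp <- nrow(rows)

  # draw impulse parameters and precompute profiles
  profs <- vector("list", n_imp)
  for (i in seq_len(n_imp)) {
    b <- rows$bin_upper_bound[i]
    A <- stats::runif(1, b - protocol$bin_width, b)
    T_dur <- stats::runif(1, 0.14, 0.22)
    V <- min(400, max(80, A * T_dur / pi))
    prof <- tryCatch(
      gen_impulse_profile(V, A, rows$direction[i], fs),
      error = function(e)
        stop("requested bin ", b, " is infeasible: ", conditionMessage(e)))
    profs[[i]] <- c(prof, list(A = A))
  }

  n_rest <- as.integer(round(rest * fs))
  n_post <- as.integer(round(post * fs))
  n_ret <- as.integer(round(return_duration * fs))
  n_lead <- as.integer(round(lead_in * fs))
  n_total <- n_lead +
    sum(vapply(profs, function(p) length(p$v), 1L)) +
    n_imp * (n_rest + n_post + n_ret)
  head_v <- numeric(n_total)
  t_all <- (seq_len(n_total) - 1L) / fs

  cursor <- n_lead
  starts <- ends_seg <- integer(n_imp)
  for (i in seq_len(n_imp)) {
    cursor <- cursor + n_rest
    v <- profs[[i]]$v
    starts[i] <- cursor + 1L
    head_v[starts[i]:(cursor + length(v))] <- v
    cursor <- cursor + length(v) + n_post
    # slow return to center: raised cosine, peak acceleration well below
    # the 300 deg/s^2 trigger threshold
    D <- profs[[i]]$peak_velocity * profs[[i]]$T / 2 *
      (if (rows$direction[i] == "CW") -1 else 1)
    tr <- seq_len(n_ret) / fs
    vr <- -(D / return_duration) * (1 - cos(2 * pi * tr / return_duration))
    head_v[(cursor + 1L):(cursor + n_ret)] <- vr
    cursor <- cursor + n_ret
    ends_seg[i] <- cursor
  }

  head_disp <- cumtrapz_fs(head_v, fs)
  g_vec <- ifelse(head_v > 0, subject$gain_ccw, subject$gain_cw)
  eye_slow_pos <- cumtrapz_fs(-g_vec * head_v, fs)
  sac_pos <- numeric(n_total)

  truth_tr <- vector("list", n_imp)
  truth_sac <- vector("list", n_imp)
  trial_rows <- vector("list", n_imp)
  pd_events <- vector("list", n_imp)
  pd <- numeric(n_total)
  orient_hist <- numeric(0)
  fd <- display$frame_duration

  for (i in seq_len(n_imp)) {
    p <- profs[[i]]
    s0 <- starts[i]
    nv <- length(p$v)
    vm <- abs(p$v)
    am <- abs(c(0, diff(p$v) * fs))
    ktr <- which(vm > protocol$velocity_threshold &
                   am > protocol$acceleration_threshold)[1]
    trigger_time <- t_all[s0 + ktr - 1L]
    pk <- which.max(vm)
    after <- which(vm[pk:nv] < protocol$velocity_threshold)
    end_rel <- if (length(after)) pk + after[1] - 1L else nv
    head_end_time <- t_all[s0 + end_rel - 1L]

    gaze_at <- function(k)
      (head_disp[k] + eye_slow_pos[k] + sac_pos[k]) -
        (head_disp[s0] + eye_slow_pos[s0] + sac_pos[s0])
    sacs <- NULL
    if (stats::runif(1) < subject$covert_prob) {
      lat <- max(0.05, stats::rnorm(1, subject$saccade_latency_mean,
                                    subject$saccade_latency_sd))
      k <- s0 + as.integer(round(lat * fs))
      amp <- -subject$saccade_gain_correction * gaze_at(k)
      if (abs(amp) >= subject$min_saccade_amplitude) {
        res <- add_saccade_profile(sac_pos, k, amp, fs)
        sac_pos <- res$pos
        sacs <- rbind(sacs, data.frame(
          trial_id = i, onset = t_all[k], duration = res$duration,
          amplitude = amp,
          label = if (t_all[k] <= head_end_time) "covert" else "overt",
          latency = t_all[k] - t_all[s0], stringsAsFactors = FALSE))
      }
    }
    if (stats::runif(1) < subject$overt_prob) {
      lat <- max(0.02, stats::rnorm(1, subject$overt_latency_mean,
                                    subject$overt_latency_sd))
      k <- s0 + end_rel - 1L + as.integer(round(lat * fs))
      amp <- -gaze_at(k)
      if (abs(amp) >= subject$min_saccade_amplitude) {
        res <- add_saccade_profile(sac_pos, k, amp, fs)
        sac_pos <- res$pos
        sacs <- rbind(sacs, data.frame(
          trial_id = i, onset = t_all[k], duration = res$duration,
          amplitude = amp, label = "overt",
          latency = t_all[k] - t_all[s0], stringsAsFactors = FALSE))
      }
    }
    # refixation between trials: regain the reference position during rest
    kf <- ends_seg[i] + as.integer(round(0.3 * fs))
    if (kf < n_total) {
      amp_f <- -(head_disp[kf] + eye_slow_pos[kf] + sac_pos[kf])
      if (abs(amp_f) > 0.1)
        sac_pos <- add_saccade_profile(sac_pos, kf, amp_f, fs)$pos
    }

    # display timing
    lat_d <- max(0, stats::rnorm(1, latency_model[1], latency_model[2]))
    onset <- vsync_phase +
      ceiling((trigger_time + lat_d - vsync_phase) / fd - 1e-9) * fd
    offset <- onset + display$nominal_duration_frames * fd
    pd[t_all >= onset & t_all < offset] <- 1
    pd_events[[i]] <- data.frame(trigger_time = trigger_time,
                                 true_onset = onset, true_offset = offset)

    # reading answer from true retinal slip over the stimulus window
    win <- which(t_all >= onset & t_all < offset)
    gz <- (head_disp[win] + eye_slow_pos[win] + sac_pos[win]) -
      (head_disp[s0] + eye_slow_pos[s0] + sac_pos[s0])
    slip <- diff(gz) * fs
    orient <- next_orientation(orient_hist)
    orient_hist <- c(orient_hist, orient)
    ans <- answer_model(slip, subject, orient)

    truth_tr[[i]] <- data.frame(
      trial_id = i, t_start = t_all[s0], direction = rows$direction[i],
      bin_upper_bound = rows$bin_upper_bound[i],
      peak_acceleration = p$A, peak_velocity = p$peak_velocity,
      duration = p$T,
      gain_true = if (rows$direction[i] == "CW") subject$gain_cw
        else subject$gain_ccw,
      trigger_time = trigger_time, head_end_time = head_end_time,
      display_onset = onset, display_offset = offset,
      slip_mean = ans$slip_mean, p_correct = ans$p_correct,
      orientation = orient, response = ans$response,
      correct = ans$correct, stringsAsFactors = FALSE)
    truth_sac[[i]] <- sacs
    trial_rows[[i]] <- trial_table(
      trial_id = i, direction = rows$direction[i],
      trigger_time_s = trigger_time, orientation_deg = orient,
      response_deg = ans$response, correct = ans$correct,
      nominal_delay_frames = display$nominal_delay_frames,
      nominal_duration_frames = display$nominal_duration_frames)
  }

  truth_trials <- do.call(rbind, truth_tr)
  truth_saccades <- do.call(rbind, truth_sac)
  if (is.null(truth_saccades))
    truth_saccades <- data.frame(trial_id = integer(0), onset = numeric(0),
                                 duration = numeric(0), amplitude = numeric(0),
                                 label = character(0), latency = numeric(0))

  # assemble recorded channels
  pitch <- sensor_pitch_deg * pi / 180
  axis <- c(0, sin(pitch), cos(pitch))
  gyro <- outer(head_v, axis) +
    matrix(stats::rnorm(3 * n_total, 0, gyro_noise_sd), ncol = 3)
  linacc <- matrix(rep(9.81 * axis, each = n_total), ncol = 3) +
    matrix(stats::rnorm(3 * n_total, 0, linacc_noise_sd), ncol = 3)
  eye_pos_true <- eye_slow_pos + sac_pos
  eye_h <- eye_pos_true +
    cumsum(stats::rnorm(n_total, 0, eye_noise_sd)) / fs
  eye_v <- cumsum(stats::rnorm(n_total, 0, eye_noise_sd / 2)) / fs
  photodiode <- pd + stats::rnorm(n_total, 0, photodiode_noise_sd)

  traces <- trace_set(gyro = gyro, linacc = linacc, eye_h = eye_h,
                      eye_v = eye_v, photodiode = photodiode, fs = fs,
                      t = t_all)
  trials <- do.call(rbind, trial_rows)
  sess <- session_recording(
    traces, protocol, display, trials,
    meta = list(simulated = TRUE, seed = seed,
                sva_logmar = subject$sva,
                sensor_pitch_deg = sensor_pitch_deg,
                subject = unclass(subject)))
  truth <- list(trials = truth_trials, saccades = truth_saccades,
                subject = subject, eye_pos_true = eye_pos_true,
                head_v_true = head_v, latency_model = latency_model,
                noise = list(gyro = gyro_noise_sd, eye = eye_noise_sd,
                             linacc = linacc_noise_sd,
                             photodiode = photodiode_noise_sd))
  list(session = sess, truth = truth)
}
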