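test_that("gaze stays at zero under a perfect VOR and follows the head at gain 0", {
  fs <- 220
  b <- rc_bump(V = 180, A = 3500, fs = fs)
  h <- b$v
  n <- length(h)
  head_disp <- c(0, cumsum((h[-1] + h[-n]) / 2)) / fs
  # perfect VOR: eye position is exactly minus the head displacement
  gz <- gaze_trace(h, -head_disp, fs, onset_time = b$t_start,
                   end_time = b$t_start + 0.4)
  expect_lt(max(abs(gz$gaze)), 1e-3)
  # gain 0, no saccades: gaze equals head displacement
  gz0 <- gaze_trace(h, numeric(n), fs, onset_time = b$t_start,
                    end_time = b$t_start + 0.4)
  i0 <- round(b$t_start * fs) + 1
  expect_equal(gz0$gaze, head_disp[i0:(i0 + length(gz0$gaze) - 1)] -
                 head_disp[i0], tolerance = 1e-3)
})

test_that("retinal slip integrates back to the gaze change (fundamental theorem)", {
  set.seed(13)
  fs <- 220
  for (rep_i in 1:10) {
    b <- rc_bump(V = stats::runif(1, 100, 300), A = stats::runif(1, 2000, 6000),
                 fs = fs)
    eye <- -0.3 * c(0, cumsum((b$v[-1] + b$v[-length(b$v)]) / 2)) / fs +
      cumsum(stats::rnorm(length(b$v), 0, 0.5)) / fs
    gz <- gaze_trace(b$v, eye, fs, onset_time = b$t_start,
                     end_time = b$t_start + 0.5)
    m <- length(gz$gaze)
    i1 <- 10; i2 <- m - 10
    integral <- sum(gz$retinal_slip[i1:(i2 - 1)]) / fs
    expect_equal(integral, gz$gaze[i2] - gz$gaze[i1], tolerance = 1e-6)
  }
})

test_that("saccade detection finds simulated saccades and merges close spans", {
  fs <- 220
  n <- 660
  h <- numeric(n)
  # a single 8-deg minimum-jerk saccade at 100 ms in an otherwise still eye
  eye_pos <- numeric(n)
  onset_idx <- round(0.1 * fs) + 1
  dur <- 0.025 + 0.0025 * 8
  m <- round(dur * fs)
  tau <- pmin(pmax((seq_len(n) - onset_idx) / m, 0), 1)
  eye_pos <- 8 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  ev <- smooth_eye_velocity(eye_pos, fs)
  sac <- detect_saccades(ev, h, fs, window = c(0, 2), gain_local = 0)
  expect_equal(nrow(sac), 1)
  expect_lt(abs(sac$onset - 0.1), 0.010)
  expect_equal(sac$amplitude, 8, tolerance = 0.5)
  # perfect VOR trial: no residual, no saccades
  b <- rc_bump(V = 200, A = 4000, fs = fs)
  hd <- c(0, cumsum((b$v[-1] + b$v[-length(b$v)]) / 2)) / fs
  ev2 <- smooth_eye_velocity(-hd, fs)
  expect_equal(nrow(detect_saccades(ev2, b$v, fs, c(0, 2), gain_local = 1)), 0)
  # two saccades 15 ms apart are merged into one event
  eye2 <- eye_pos
  onset2 <- onset_idx + m + round(0.015 * fs)
  tau2 <- pmin(pmax((seq_len(n) - onset2) / m, 0), 1)
  eye2 <- eye2 + 6 * (10 * tau2^3 - 15 * tau2^4 + 6 * tau2^5)
  sac2 <- detect_saccades(smooth_eye_velocity(eye2, fs), h, fs,
                          window = c(0, 2), gain_local = 0)
  expect_equal(nrow(sac2), 1)
  expect_equal(sac2$amplitude, 14, tolerance = 1)
})

test_that("saccades are labeled covert/overt by onset against the head-movement end", {
  imp <- structure(list(onset_time = 1.0, end_time = 1.15), class = "hitd_impulse")
  sac <- data.frame(onset = c(1.10, 1.30, 1.14), offset = c(1.14, 1.35, 1.20),
                    amplitude = c(5, 3, 4), peak_velocity = c(200, 150, 180))
  out <- label_saccades(sac, imp, stimulus_window = c(1.08, 1.16))
  expect_equal(out$label, c("covert", "overt", "covert"))
  expect_equal(out$latency_from_head_onset, c(0.10, 0.30, 0.14))
  # saccade entirely inside the stimulus window
  expect_equal(out$stimulus_overlap_fraction[1], 1.0)
  # saccade entirely outside
  expect_equal(out$stimulus_overlap_fraction[2], 0.0)
  # straddling the boundary is flagged
  expect_true(out$straddles_head_end[3])
  expect_false(out$straddles_head_end[1])
})

test_that("covert/overt labels agree with simulator ground truth", {
  subj <- subject_model(gain_cw = 0.5, gain_ccw = 0.5, covert_prob = 1,
                        overt_prob = 0, saccade_latency_mean = 0.165,
                        saccade_latency_sd = 0.05)
  plan <- expand.grid(bin_upper_bound = c(3000, 4000, 5000, 6000),
                      direction = c("CW", "CCW"), count = 13,
                      stringsAsFactors = FALSE)
  sim <- simulate_session(subject = subj, plan = plan, seed = 404,
                          gyro_noise_sd = 0, eye_noise_sd = 0,
                          linacc_noise_sd = 0, photodiode_noise_sd = 0)
  a <- analyze_session(sim$session)
  ts <- sim$truth$saccades
  expect_gt(nrow(ts), 90)
  ok <- 0
  for (i in seq_len(nrow(ts))) {
    det <- a$saccades[a$saccades$trial_id == ts$trial_id[i], , drop = FALSE]
    if (nrow(det) == 0) next
    j <- which.min(abs(det$onset - ts$onset[i]))
    if (abs(det$onset[j] - ts$onset[i]) < 0.03 &&
        det$label[j] == ts$label[i]) ok <- ok + 1
  }
  expect_gte(ok / nrow(ts), 0.98)
})

test_that("few false-positive saccade trials under eye noise on healthy impulses", {
  sim <- simulate_session(seed = 91, n_per_bin = 4, gyro_noise_sd = 2,
                          eye_noise_sd = 2,
                          subject = subject_model(covert_prob = 0,
                                                  overt_prob = 0))
  a <- analyze_session(sim$session)
  fp <- length(unique(a$saccades$trial_id))
  expect_lte(fp / nrow(a$impulses), 0.05)
})

test_that("longitudinal comparison tracks recovery with correct signs", {
  s1 <- subject_model(gain_cw = 0.15, gain_ccw = 0.15, covert_prob = 0.2,
                      overt_prob = 0.9)
  s2 <- subject_model(gain_cw = 0.30, gain_ccw = 0.30, covert_prob = 0.8,
                      overt_prob = 0.9)
  a1 <- analyze_session(simulate_session(subject = s1, seed = 51,
                                         n_per_bin = 3)$session)
  a2 <- analyze_session(simulate_session(subject = s2, seed = 52,
                                         n_per_bin = 3)$session)
  fu <- followup_compare(list(a1, a2))
  expect_true(all(fu$direction_deltas$delta_gain > 0))
  expect_true(all(fu$direction_deltas$delta_covert_count > 0))
  expect_length(fu$warnings, 0)
  # identical sessions: all deltas zero
  fu0 <- followup_compare(list(a1, a1))
  expect_true(all(abs(fu0$deltas$delta_gain) < 1e-12))
  expect_true(all(fu0$direction_deltas$delta_covert_count == 0))
  expect_error(followup_compare(list(a1)), "at least 2")
})

test_that("sessions with disjoint bins compare on nothing and warn", {
  plan_lo <- expand.grid(bin_upper_bound = c(2000, 3000),
                         direction = c("CW", "CCW"), count = 3,
                         stringsAsFactors = FALSE)
  plan_hi <- expand.grid(bin_upper_bound = c(6000, 7000),
                         direction = c("CW", "CCW"), count = 3,
                         stringsAsFactors = FALSE)
  a1 <- analyze_session(simulate_session(plan = plan_lo, seed = 61)$session)
  a2 <- analyze_session(simulate_session(plan = plan_hi, seed = 62)$session)
  fu <- followup_compare(list(a1, a2))
  expect_true(any(grepl("share no populated bins", fu$warnings)))
  expect_true(is.null(fu$deltas) || nrow(fu$deltas) == 0)
})
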