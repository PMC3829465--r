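test_that("gravity estimation recovers the sensor attitude from quiescent data", {
  n <- 200
  gyro <- matrix(0, n, 3)
  # aligned sensor
  la <- matrix(rep(c(0, 0, 9.81), each = n), ncol = 3)
  expect_equal(estimate_gravity(la, gyro, 220), c(0, 0, 1), tolerance = 1e-12)
  # pitched 30 deg: analytic unit vector (0, sin30, cos30)
  la2 <- matrix(rep(9.81 * c(0, sin(pi / 6), cos(pi / 6)), each = n), ncol = 3)
  expect_equal(estimate_gravity(la2, gyro, 220), c(0, 0.5, sqrt(3) / 2),
               tolerance = 1e-12)
  # degenerate: zero specific force
  expect_error(estimate_gravity(matrix(0, n, 3), gyro, 220), "zero-norm")
  # no quiescent window
  gyro_busy <- matrix(50, n, 3)
  expect_error(estimate_gravity(la, gyro_busy, 220), "cannot calibrate")
})

test_that("yaw projection recovers earth-vertical rotation at any mounting", {
  n <- 50
  # aligned axes
  g <- matrix(rep(c(0, 0, 100), each = n), ncol = 3)
  expect_equal(vertical_yaw_velocity(g, c(0, 0, 1)), rep(100, n))
  # sensor pitched 30 deg nose-down, pure earth-vertical rotation
  R <- rbind(c(1, 0, 0),
             c(0, cos(pi / 6), -sin(pi / 6)),
             c(0, sin(pi / 6), cos(pi / 6)))
  w_sensor <- t(t(R) %*% c(0, 0, 100))
  g2 <- matrix(rep(w_sensor, each = n), ncol = 3)
  gu <- drop(t(R) %*% c(0, 0, 1))
  expect_equal(vertical_yaw_velocity(g2, gu), rep(100, n), tolerance = 1e-9)
  # orthogonal rotation projects to zero
  expect_equal(vertical_yaw_velocity(matrix(rep(c(100, 0, 0), each = n),
                                            ncol = 3), c(0, 0, 1)),
               rep(0, n))
  expect_error(vertical_yaw_velocity(g, c(0, 0, 2)), "unit")
})

test_that("yaw projection is invariant to joint sensor-frame rotations", {
  set.seed(101)
  w_earth <- c(3, -7, 120)
  for (rep_i in 1:20) {
    R <- random_rotation()
    g <- matrix(rep(drop(t(R) %*% w_earth), each = 10), ncol = 3)
    gu <- drop(t(R) %*% c(0, 0, 1))
    expect_equal(vertical_yaw_velocity(g, gu), rep(120, 10),
                 tolerance = 1e-9)
  }
})

test_that("backward-difference acceleration matches closed forms", {
  fs <- 220
  expect_equal(differentiate_backward(rep(5, 10), fs), rep(0, 10))
  v <- seq(0, 9)  # +1 deg/s per sample
  expect_equal(differentiate_backward(v, fs), c(0, rep(220, 9)))
  # raised cosine: first difference vs analytic derivative, Taylor bound
  b <- rc_bump(V = 200, A = 4000, fs = fs)
  a_num <- differentiate_backward(b$v, fs)
  tt <- (seq_along(b$v) - 1) / fs - b$t_start
  a_true <- ifelse(tt >= 0 & tt <= b$T,
                   (pi * b$V / b$T) * sin(2 * pi * tt / b$T), 0)
  # backward difference estimates the derivative at t - h/2; bound the
  # mismatch by max|second derivative| * h/2 + curvature term
  bound <- (pi * b$V / b$T) * (2 * pi / b$T) / fs
  expect_lt(max(abs(a_num[-1] - a_true[-1])), bound)
  expect_error(differentiate_backward(5, fs), "length")
})

test_that("smoothed eye velocity reproduces analytic derivatives", {
  fs <- 220
  n <- 440
  tt <- (0:(n - 1)) / fs
  # linear ramp 30 deg/s
  d <- smooth_eye_velocity(30 * tt, fs)
  mid <- 100:340
  expect_lt(max(abs(d[mid] - 30)), 1e-6)
  # constant position
  expect_equal(smooth_eye_velocity(rep(2, n), fs), rep(0, n),
               tolerance = 1e-9)
  # 2 Hz sinusoid, amplitude 5: derivative amplitude 2*pi*2*5
  x <- 5 * sin(2 * pi * 2 * tt)
  d2 <- smooth_eye_velocity(x, fs)
  expect_equal(max(abs(d2[mid])), 2 * pi * 2 * 5, tolerance = 0.01)
  # NaN propagation over the filter support
  x[200] <- NA
  d3 <- smooth_eye_velocity(x, fs)
  expect_true(is.na(d3[200]))
  expect_false(anyNA(d3[1:150]))
})

test_that("impulse segmentation finds analytic landmarks of a raised cosine", {
  fs <- 220
  b <- rc_bump(V = 200, A = 4000, fs = fs)  # T ~ 0.157 s
  proto <- protocol_config()
  trig <- b$t_start + 0.03
  imp <- segment_impulse(b$v, fs, trig, proto)
  expect_s3_class(imp, "hitd_impulse")
  expect_equal(imp$direction, "CCW")
  # impulse acceleration near the closed-form peak pi*V/T; the 5-sample
  # line fit has an irreducible discretization bias of ~0.57 (omega h)^2
  # (about 1.9% at this T and 220 Hz), so allow 2.5%
  expect_lt(abs(imp$impulse_acceleration - b$A) / b$A, 0.025)
  expect_equal(imp$peak_velocity_time, b$t_peak_vel, tolerance = 1.5 / fs)
  expect_equal(imp$peak_acceleration_time, b$t_peak_acc, tolerance = 1.5 / fs)
  expect_true(imp$onset_time <= imp$peak_acceleration_time)
  expect_true(imp$peak_acceleration_time <= imp$peak_velocity_time)
  expect_true(imp$peak_velocity_time <= imp$end_time)
  # gain-window duration ~ T/4 sits in the plausible 20-80 ms band
  expect_gt(diff(imp$gain_window), 0.020)
  expect_lt(diff(imp$gain_window), 0.080)
})

test_that("impulse acceleration is exact for collinear samples and errors on flat traces", {
  fs <- 220
  # triangular ramp of slope 3000 deg/s^2: 5 collinear samples -> exact
  up <- 3000 * (0:15) / fs
  v <- c(numeric(220), up, rev(up), numeric(220))
  imp <- segment_impulse(v, fs, trigger_time = 221 / fs, protocol_config())
  expect_equal(imp$impulse_acceleration, 3000, tolerance = 1e-9)
  # flat zero velocity: no peak
  expect_error(segment_impulse(numeric(500), fs, 1.0, protocol_config()),
               "truncated impulse")
})

test_that("simulated impulse acceleration is recovered across all bins", {
  # noise-free: within 3% of the requested peak acceleration
  sim <- simulate_session(seed = 31, n_per_bin = 3, gyro_noise_sd = 0,
                          eye_noise_sd = 0, linacc_noise_sd = 0,
                          photodiode_noise_sd = 0)
  a <- analyze_session(sim$session)
  tt <- merge(a$impulses, sim$truth$trials, by = "trial_id")
  rel <- abs(tt$impulse_acceleration - tt$peak_acceleration) /
    tt$peak_acceleration
  expect_true(all(is.finite(rel)))
  expect_lt(max(rel), 0.03)
  # gyro noise 2 deg/s: recovery within 10% for the vast majority
  sim2 <- simulate_session(seed = 32, n_per_bin = 5, gyro_noise_sd = 2)
  a2 <- analyze_session(sim2$session)
  tt2 <- merge(a2$impulses, sim2$truth$trials, by = "trial_id")
  rel2 <- abs(tt2$impulse_acceleration - tt2$peak_acceleration) /
    tt2$peak_acceleration
  expect_lt(mean(rel2), 0.05)
  expect_gte(mean(rel2 <= 0.10), 0.95)
})
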