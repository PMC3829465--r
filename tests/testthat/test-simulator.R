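test_that("the raised-cosine profile has the requested analytic landmarks", {
  fs <- 220
  p <- gen_impulse_profile(200, 4000, "CCW", fs)
  expect_equal(p$T, pi * 200 / 4000)
  # sampled maximum within curvature error of the requested peak velocity
  expect_lt(abs(max(p$v) - 200), 200 * (pi / (p$T * fs))^2)
  # numerically differentiated peak acceleration near A for every bin
  for (A in seq(2000, 7000, by = 1000)) {
    V <- A * 0.18 / pi
    pp <- gen_impulse_profile(V, A, "CCW", fs)
    a_num <- max(abs(diff(pp$v) * fs))
    expect_lt(abs(a_num - A) / A, 0.03)
  }
  # direction symmetry
  pcw <- gen_impulse_profile(200, 4000, "CW", fs)
  expect_equal(pcw$v, -p$v)
  # too short to resolve
  expect_error(gen_impulse_profile(10, 7000, "CCW", fs), "unresolvable")
})

test_that("the eye-response generator follows the correction algebra", {
  fs <- 220
  prof <- gen_impulse_profile(200, 4000, "CCW", fs)
  head_v <- c(prof$v, numeric(150))
  # perfect VOR, no saccades: zero gaze error throughout
  s_perfect <- subject_model(gain_cw = 1, gain_ccw = 1, covert_prob = 0,
                             overt_prob = 0)
  r <- gen_eye_response(head_v, fs, s_perfect)
  n <- length(head_v)
  hd <- c(0, cumsum((head_v[-1] + head_v[-n]) / 2)) / fs
  expect_lt(max(abs(hd + r$eye_pos)), 1e-9)
  expect_equal(nrow(r$saccades), 0)
  # low gain with one full-probability covert saccade correcting 80%:
  # the terminal gaze error is 20% of the pre-saccadic error plus the
  # slow-phase error accrued after the saccade
  s_pat <- subject_model(gain_cw = 0.15, gain_ccw = 0.15, covert_prob = 1,
                         overt_prob = 0, saccade_latency_sd = 0,
                         saccade_gain_correction = 0.8)
  set.seed(42)
  r2 <- gen_eye_response(head_v, fs, s_pat)
  expect_equal(nrow(r2$saccades), 1)
  expect_equal(r2$saccades$label, "covert")
  k_on <- round(r2$saccades$onset * fs) + 1
  gaze <- hd + r2$eye_pos
  pre_err <- hd[k_on] + (-0.15 * hd[k_on])  # slow-phase-only error at onset
  expect_equal(r2$saccades$amplitude, -0.8 * pre_err, tolerance = 1e-6)
  # after the saccade ends, gaze = 0.2*pre_err + error accrued since onset
  k_off <- k_on + round(r2$saccades$duration * fs) + 1
  accrued <- 0.85 * (hd[k_off] - hd[k_on])
  expect_equal(gaze[k_off], 0.2 * pre_err + accrued, tolerance = 1e-3)
  # determinism
  set.seed(42)
  r3 <- gen_eye_response(head_v, fs, s_pat)
  expect_identical(r2$eye_pos, r3$eye_pos)
})

test_that("the display channel is vsync-quantized with the nominal duration", {
  fs <- 220
  t <- (0:(30 * fs - 1)) / fs
  d <- display_config(75, 0, 6)
  trig <- seq(1, 28, by = 1.5)
  # zero-jitter latency of one frame: delay in [1, 2) frames
  set.seed(1)
  g <- gen_display_channel(trig, d, t, latency_model = c(1 / 75, 0),
                           noise_sd = 0)
  delays <- g$events$true_onset - g$events$trigger_time
  expect_true(all(delays >= 1 / 75 - 1e-9 & delays < 2 / 75 + 1e-9))
  expect_equal(g$events$true_offset - g$events$true_onset,
               rep(6 / 75, length(trig)))  # 80 ms exactly
  # onsets on the vsync grid
  resid <- g$events$true_onset * 75
  expect_lt(max(abs(resid - round(resid))), 1e-6)
})

test_that("the timing audit recovers the simulated latency distribution", {
  fs <- 220
  n_tr <- 400
  set.seed(8)
  # irregular trigger spacing, as in a real session: commensurate spacing
  # would alias the vsync grid against the sample grid
  trig <- 0.5 + cumsum(stats::runif(n_tr, 0.8, 1.2))
  t <- (0:(ceiling((max(trig) + 1) * fs) - 1)) / fs
  d <- display_config(75, 0, 6)
  g <- gen_display_channel(trig, d, t, latency_model = c(0.025, 0.008),
                           noise_sd = 0.02)
  out <- audit_timing(g$photodiode, t,
                      data.frame(trial_id = seq_along(trig),
                                 trigger_time = trig))
  ts <- timing_summary(out)
  true_delays <- g$events$true_onset - g$events$trigger_time
  expect_equal(ts$n_measured, length(trig))
  expect_lt(abs(ts$delay_mean - mean(true_delays)), 1e-3)
  expect_lt(abs(ts$delay_sd - stats::sd(true_delays)) / stats::sd(true_delays),
            0.20)
  expect_equal(ts$duration_mean, 0.080, tolerance = 1.5e-3)
})

test_that("the reading model follows its logistic closed form", {
  s <- subject_model(slip_threshold_s50 = 20, slip_sigma = 5, lapse = 0)
  set.seed(3)
  a0 <- answer_model(rep(0, 20), s, 90)
  expect_equal(a0$p_correct, 0.125 + 0.875 * stats::plogis(4),
               tolerance = 1e-12)
  a_mid <- answer_model(rep(20, 20), s, 90)
  expect_equal(a_mid$p_correct, 0.5625, tolerance = 1e-12)
  a_inf <- answer_model(rep(1e4, 20), s, 90)
  expect_equal(a_inf$p_correct, 0.125, tolerance = 1e-6)
  expect_error(answer_model(numeric(0), s, 90), "empty")
  # errors report a different orientation; corrects report the true one
  set.seed(5)
  draws <- replicate(200, answer_model(rep(1e4, 5), s, 90)$response)
  expect_true(all(draws %in% seq(0, 315, by = 45)))
  expect_lt(mean(draws == 90), 0.35)
})

test_that("simulated sessions are valid, seeded-reproducible and truthful", {
  sim <- simulate_session(seed = 14, n_per_bin = 1)
  expect_identical(validate_session(sim$session), character(0))
  expect_equal(nrow(sim$session$trials), 12)
  # binwise coverage matches the plan
  expect_equal(sort(unique(sim$truth$trials$bin_upper_bound)),
               seq(2000, 7000, by = 1000))
  # determinism: identical seed, identical bundle bytes
  sim2 <- simulate_session(seed = 14, n_per_bin = 1)
  d1 <- file.path(tempdir(), "sessA"); d2 <- file.path(tempdir(), "sessB")
  write_session(sim$session, d1)
  write_session(sim2$session, d2)
  for (f in c("meta.yaml", "traces.tsv", "trials.tsv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  unlink(c(d1, d2), recursive = TRUE)
  # an infeasible bin names itself
  bad_plan <- data.frame(bin_upper_bound = 60000, direction = "CW", count = 1)
  bad_proto <- protocol_config(bin_upper_bounds = 60000, bin_width = 1000)
  expect_error(simulate_session(protocol = bad_proto, plan = bad_plan,
                                seed = 1), "60000")
})

test_that("healthy and unilateral subjects produce the expected performance contrast", {
  # healthy: near-unit gains, near-perfect reading in every bin
  sim <- simulate_session(seed = 70, n_per_bin = 3)
  a <- analyze_session(sim$session)
  ok <- !a$impulses$excluded
  expect_gt(mean(ok), 0.9)
  expect_lt(max(abs(a$impulses$gain[ok] - 1)), 0.05)
  filled <- a$bins[a$bins$n_thrusts > 0, ]
  expect_true(all(filled$percent_correct >= 80))
  expect_gte(mean(a$impulses$correct[ok]), 0.95)
  # left-deficit-like subject: ipsilesional reading far below contralesional
  subj <- subject_model(gain_cw = 0.15, gain_ccw = 0.75, covert_prob = 0.4,
                        overt_prob = 0.8, slip_sigma = 10)
  simp <- simulate_session(subject = subj, seed = 71, n_per_bin = 5)
  ap <- analyze_session(simp$session)
  ip <- ap$impulses[!ap$impulses$excluded, ]
  pc_cw <- 100 * mean(ip$correct[ip$direction == "CW"], na.rm = TRUE)
  pc_ccw <- 100 * mean(ip$correct[ip$direction == "CCW"], na.rm = TRUE)
  expect_lt(pc_cw, pc_ccw - 20)
  # and per bin the affected side never reads better by a wide margin
  bb <- ap$bins
  for (bnd in unique(bb$bin_upper_bound)) {
    cw <- bb$percent_correct[bb$direction == "CW" & bb$bin_upper_bound == bnd]
    ccw <- bb$percent_correct[bb$direction == "CCW" & bb$bin_upper_bound == bnd]
    if (!is.na(cw) && !is.na(ccw)) expect_lte(cw, ccw + 25)
  }
})

test_that("end-to-end gain recovery within 0.05 at sensor noise SD 2 deg/s", {
  subj <- subject_model(gain_cw = 0.4, gain_ccw = 0.9, covert_prob = 0,
                        overt_prob = 0.8)
  plan <- expand.grid(bin_upper_bound = seq(2000, 7000, by = 1000),
                      direction = c("CW", "CCW"), count = 5,
                      stringsAsFactors = FALSE)
  sim <- simulate_session(subject = subj, plan = plan, seed = 33,
                          gyro_noise_sd = 2, eye_noise_sd = 2)
  a <- analyze_session(sim$session)
  imp <- a$impulses[!a$impulses$excluded, ]
  expect_lt(abs(mean(imp$gain[imp$direction == "CW"]) - 0.4), 0.05)
  expect_lt(abs(mean(imp$gain[imp$direction == "CCW"]) - 0.9), 0.05)
})
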