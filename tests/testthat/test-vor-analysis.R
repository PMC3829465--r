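test_that("VOR gain is the negated eye/head velocity ratio over the window", {
  fs <- 220
  b <- rc_bump(V = 150, A = 3000, fs = fs)
  h <- b$v
  win <- c(b$t_peak_acc, b$t_peak_vel)
  # perfectly compensatory response
  expect_equal(vor_gain(h, -h, fs, win), 1.0, tolerance = 1e-12)
  # linearity
  expect_equal(vor_gain(h, -0.3 * h, fs, win), 0.3, tolerance = 1e-12)
  for (cc in c(0.05, 0.5, 1.1))
    expect_equal(vor_gain(h, -cc * h, fs, win), cc, tolerance = 1e-12)
  # absent response
  expect_equal(vor_gain(h, numeric(length(h)), fs, win), 0.0)
  # anti-compensatory responses keep their sign
  expect_equal(vor_gain(h, 0.4 * h, fs, win), -0.4, tolerance = 1e-12)
  # degenerate window: near-zero head velocity
  expect_error(vor_gain(numeric(1000), numeric(1000), fs, c(0.5, 0.6)),
               "degenerate")
  # NaN inside the window is a contract violation
  e <- -h; e[round(win[1] * fs) + 2] <- NA
  expect_error(vor_gain(h, e, fs, win), "NaN")
})

test_that("bin assignment uses half-open (b - w, b] intervals", {
  p <- protocol_config()
  expect_equal(assign_bin(2500, p), 3000)
  expect_equal(assign_bin(2000, p), 2000)   # boundary falls in lower bin
  expect_true(is.na(assign_bin(7200, p)))
  expect_true(is.na(assign_bin(1000, p)))   # at/below the lowest lower edge
  expect_equal(assign_bin(1000.5, p), 2000)
  expect_equal(assign_bin(7000, p), 7000)
  expect_equal(assign_bin(c(2500, 9999, 6500), p), c(3000, NA, 7000))
})

make_results <- function(direction, bin, gain, correct, excluded = FALSE) {
  data.frame(direction = direction, bin = bin, gain = gain,
             correct = correct, excluded = excluded,
             stringsAsFactors = FALSE)
}

test_that("bin reports aggregate reading performance with the 5/8 rule", {
  p <- protocol_config()
  r <- make_results(direction = c("CW", "CW", "CCW"),
                    bin = c(3000, 3000, 4000),
                    gain = c(0.9, 1.1, 1.0),
                    correct = c(TRUE, FALSE, TRUE))
  b <- bin_reports(r, p)
  row <- b[b$direction == "CW" & b$bin_upper_bound == 3000, ]
  expect_equal(row$n_thrusts, 2)
  expect_equal(row$percent_correct, 50)
  expect_equal(row$required_thrusts, 8L)  # an error escalates 5 -> 8
  expect_equal(row$gain_mean, 1.0)
  row2 <- b[b$direction == "CCW" & b$bin_upper_bound == 4000, ]
  expect_equal(row2$required_thrusts, 5L)
  # empty cells present with zero thrusts
  expect_equal(sum(b$n_thrusts), 3)
  expect_equal(nrow(b), 12)
})

test_that("bin counts are conserved and order-invariant", {
  set.seed(21)
  p <- protocol_config()
  n <- 80
  r <- make_results(direction = sample(c("CW", "CCW"), n, TRUE),
                    bin = sample(c(p$bin_upper_bounds, NA), n, TRUE),
                    gain = stats::runif(n, 0, 1.2),
                    correct = sample(c(TRUE, FALSE, NA), n, TRUE),
                    excluded = stats::runif(n) < 0.15)
  b <- bin_reports(r, p)
  expect_equal(sum(b$n_thrusts), sum(!r$excluded & !is.na(r$bin)))
  b2 <- bin_reports(r[sample(n), ], p)
  expect_equal(b[order(b$direction, b$bin_upper_bound), ]$percent_correct,
               b2[order(b2$direction, b2$bin_upper_bound), ]$percent_correct)
})

test_that("the protocol planner reproduces the published impulse minima", {
  p <- protocol_config()
  full <- plan_protocol(NULL, p, restricted = FALSE)
  expect_equal(full$total_minimum, 60L)
  restr <- plan_protocol(NULL, p, restricted = TRUE)
  expect_equal(restr$total_minimum, 40L)
  expect_equal(restr$bins_planned, c(3000, 4000, 5000, 6000))
  # a bin with one error and 5 thrusts needs 3 more
  r <- make_results(direction = rep("CW", 5), bin = rep(4000, 5),
                    gain = rep(1, 5), correct = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  b <- bin_reports(r, p)
  pl <- plan_protocol(b, p)
  cell <- pl$remaining[pl$remaining$direction == "CW" &
                         pl$remaining$bin_upper_bound == 4000, ]
  expect_equal(cell$remaining, 3L)
})

test_that("the stand-in classifier flags cells with improbably low correct rates", {
  p <- protocol_config()
  r <- make_results(direction = rep(c("CW", "CCW"), each = 8),
                    bin = rep(3000, 16), gain = rep(0.5, 16),
                    correct = c(rep(FALSE, 8), rep(TRUE, 8)))
  cl <- classify_performance(bin_reports(r, p))
  bad <- cl[cl$direction == "CW" & cl$bin_upper_bound == 3000, ]
  good <- cl[cl$direction == "CCW" & cl$bin_upper_bound == 3000, ]
  expect_equal(bad$verdict, "impaired")
  # closed-form binomial tail: P(X <= 0 | n = 8, p = 0.9) = 0.1^8
  expect_equal(bad$p_value, 1e-8, tolerance = 1e-10)
  expect_equal(good$verdict, "not impaired")
  empty <- cl[cl$bin_upper_bound == 7000 & cl$direction == "CW", ]
  expect_equal(empty$verdict, "insufficient data")
})
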