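#' VOR velocity gain over a time window
#'
#' Gain of the angular vestibulo-ocular reflex for one impulse: the ratio of
#' the mean eye velocity to the mean head velocity over the interval between
#' head peak acceleration and head peak velocity (the gain window of a
#' segmented impulse, typically ~40 ms). Eye velocity is negated so a
#' perfectly compensatory response (eye exactly counter-rotating the head)
#' has gain +1; anti-compensatory responses yield negative gain and are
#' reported as such, never clipped.
#'
#' @param head_yaw_velocity head yaw velocity series (deg/s, CCW positive).
#' @param eye_velocity eye-in-head velocity series (deg/s), same length and
#'   time base.
#' @param fs sampling rate (Hz).
#' @param window numeric length-2, `c(t1, t2)` in seconds (inclusive); e.g.
#'   `impulse$gain_window`.
#' @param t0 time of the first sample (s).
#' @return Scalar gain (dimensionless).
#' @export
vor_gain <- function(head_yaw_velocity, eye_velocity, fs, window, t0 = 0) {
  n <- length(head_yaw_velocity)
  i1 <- as.integer(round((window[1] - t0) * fs)) + 1L
  i2 <- as.integer(round((window[2] - t0) * fs)) + 1L
  if (i1 < 1L || i2 > n || i2 < i1) stop("window outside series")
  idx <- i1:i2
  if (length(idx) < 3) stop("window must contain at least 3 samples")
  h <- head_yaw_velocity[idx]
  e <- eye_velocity[idx]
  if (anyNA(h) || anyNA(e))
    stop("NaN inside gain window: impulse must be excluded upstream")
  mh <- mean(h)
  if (abs(mh) < 1) stop("degenerate window: |mean head velocity| < 1 deg/s")
  mean(-e) / mh
}

#' Assign an impulse acceleration to its bin
#'
#' Bins are half-open on the left: acceleration `a` belongs to the bin with
#' upper bound `b` when `a` is in `(b - bin_width, b]`, so an acceleration
#' exactly on a boundary falls in the lower bin. Accelerations outside
#' `(min(bounds) - bin_width, max(bounds)]` are out of range.
#'
#' @param impulse_acceleration numeric vector (deg/s^2, magnitudes).
#' @param protocol a [protocol_config()].
#' @return Numeric vector of bin upper bounds; `NA` for out-of-range.
#' @export
assign_bin <- function(impulse_acceleration, protocol) {
  b <- protocol$bin_upper_bounds
  w <- protocol$bin_width
  lo <- min(b) - w
  out <- rep(NA_real_, length(impulse_acceleration))
  for (k in seq_along(impulse_acceleration)) {
    a <- impulse_acceleration[k]
    if (is.na(a) || a <= lo || a > max(b)) next
    out[k] <- b[which(a <= b)[1]]
  }
  out
}

#' Per-bin reading performance and gain statistics
#'
#' Groups per-impulse results by rotation direction and acceleration bin
#' and reports, for every (direction, bin) cell of the protocol (empty
#' cells included with zero thrusts): the number of non-excluded thrusts,
#' correct answers, percent correct (over trials with a defined response),
#' gain mean and SD, and the required thrust count — the protocol minimum,
#' escalated (5 to 8 by default) as soon as the subject made at least one
#' reading error in the cell. Trials without a response are excluded from
#' the percent-correct denominator and counted separately.
#'
#' @param results data frame with one row per impulse: columns `direction`
#'   (`"CW"`/`"CCW"`), `bin` (upper bound, `NA` if out of range), `gain`,
#'   `correct` (logical, `NA` for no response), `excluded` (logical).
#' @param protocol a [protocol_config()].
#' @return Data frame of class `hitd_bin_report`, one row per
#'   (direction, bin): `direction`, `bin_upper_bound`, `n_thrusts`,
#'   `n_correct`, `n_no_response`, `percent_correct`, `gain_mean`,
#'   `gain_sd`, `required_thrusts`.
#' @export
bin_reports <- function(results, protocol) {
  cells <- expand.grid(direction = c("CW", "CCW"),
                       bin_upper_bound = protocol$bin_upper_bounds,
                       stringsAsFactors = FALSE)
  keep <- !results$excluded & !is.na(results$bin)
  r <- results[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- r$direction == cells$direction[i] &
      r$bin == cells$bin_upper_bound[i]
    g <- r$gain[sel]
    co <- r$correct[sel]
    answered <- co[!is.na(co)]
    n_err <- sum(!answered)
    data.frame(
      direction = cells$direction[i],
      bin_upper_bound = cells$bin_upper_bound[i],
      n_thrusts = sum(sel),
      n_correct = sum(answered),
      n_no_response = sum(is.na(co)),
      percent_correct = if (length(answered) > 0)
        100 * sum(answered) / length(answered) else NA_real_,
      gain_mean = if (any(sel)) mean(g, na.rm = TRUE) else NA_real_,
      gain_sd = if (sum(sel) > 1) stats::sd(g, na.rm = TRUE) else NA_real_,
      required_thrusts = if (n_err > 0) protocol$escalated_thrusts_per_bin
        else protocol$min_thrusts_per_bin,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hitd_bin_report", "data.frame")
  out
}

#' Plan remaining head thrusts and the protocol minimum
#'
#' For each (direction, bin) cell, the number of thrusts still required:
#' `max(0, required - performed)`, where `required` escalates from the
#' protocol minimum (5) to the escalated count (8) once a reading error
#' occurred in that cell. Also reports the total minimum number of impulses
#' an error-free subject needs from scratch:
#' `n_bins x 2 directions x min_thrusts_per_bin` — 60 for the full
#' 2000-7000 deg/s^2 layout, and 40 when restricted to the clinically
#' relevant 3000-6000 deg/s^2 bins.
#'
#' @param reports a [bin_reports()] data frame, or `NULL` for an empty
#'   session.
#' @param protocol a [protocol_config()].
#' @param restricted logical; limit the plan to bins with upper bounds in
#'   3000-6000 deg/s^2.
#' @return List with `remaining` (data frame per direction and bin),
#'   `total_minimum` (integer), and `bins_planned`.
#' @export
plan_protocol <- function(reports = NULL, protocol = protocol_config(),
                          restricted = FALSE) {
  bins <- protocol$bin_upper_bounds
  if (restricted) bins <- bins[bins >= 3000 & bins <= 6000]
  cells <- expand.grid(direction = c("CW", "CCW"),
                       bin_upper_bound = bins, stringsAsFactors = FALSE)
  cells$required <- protocol$min_thrusts_per_bin
  cells$performed <- 0L
  if (!is.null(reports) && nrow(reports) > 0) {
    for (i in seq_len(nrow(cells))) {
      m <- reports$direction == cells$direction[i] &
        reports$bin_upper_bound == cells$bin_upper_bound[i]
      if (any(m)) {
        cells$performed[i] <- reports$n_thrusts[m][1]
        cells$required[i] <- reports$required_thrusts[m][1]
      }
    }
  }
  cells$remaining <- pmax(0L, cells$required - cells$performed)
  list(remaining = cells,
       total_minimum = length(bins) * 2L * protocol$min_thrusts_per_bin,
       bins_planned = bins)
}

#' Classify per-bin reading performance against a control rate
#'
#' Stand-in classifier: the statistical procedure originally used against a
#' control population is not reproducible here, so each (direction, bin)
#' cell is tested with a one-sided exact binomial test of the correct count
#' against a configurable control correct-rate `p_control` (default 0.9),
#' flagging "impaired" when significantly fewer correct answers than
#' controls would produce (p < `alpha`). This is explicitly NOT the original
#' control-population procedure; all parameters are surfaced.
#'
#' @param reports a [bin_reports()] data frame.
#' @param chance chance probability of a correct answer (sanity bound).
#' @param p_control assumed control correct-answer probability.
#' @param alpha significance level.
#' @return `reports` with columns `p_value` and `verdict`
#'   (`"impaired"`, `"not impaired"`, `"insufficient data"`).
#' @export
classify_performance <- function(reports, chance = 0.125, p_control = 0.9,
                                 alpha = 0.05) {
  stopifnot(chance > 0, chance < 1, p_control > chance, p_control < 1)
  out <- reports
  out$p_value <- NA_real_
  out$verdict <- "insufficient data"
  for (i in seq_len(nrow(out))) {
    n <- out$n_thrusts[i] - out$n_no_response[i]
    if (is.na(n) || n < 1) next
    k <- out$n_correct[i]
    pv <- stats::binom.test(k, n, p = p_control,
                            alternative = "less")$p.value
    out$p_value[i] <- pv
    out$verdict[i] <- if (pv < alpha) "impaired" else "not impaired"
  }
  out
}
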