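#' Landolt C optotype geometry for a given acuity and viewing distance
#'
#' The Landolt C is a ring whose gap measures 1/5 of the outer diameter; the
#' subject reports the gap orientation. Acuity is expressed in logMAR: the
#' gap must subtend a minimum angle of resolution of `10^logmar` arcminutes
#' at the eye. The physical gap is therefore
#' `gap = distance * tan(10^logmar / 60 degrees)` and the outer diameter is
#' five gaps. Size scales exactly linearly with distance and strictly
#' increases with both arguments.
#'
#' @param distance viewing distance (m), > 0.
#' @param logmar acuity demand (logMAR); 0 logMAR = 1 arcmin gap.
#' @param orientation optional gap orientation (deg, one of 0, 45, ..., 315).
#' @return An object of class `hitd_optotype`: list with `logmar`,
#'   `distance` (m), `size` (outer diameter, m), `gap` (m), `orientation`.
#' @examples
#' optotype_size(1, 0)$size    # ~1.454 mm at 1 m, 0 logMAR
#' @export
optotype_size <- function(distance, logmar, orientation = NA_real_) {
  if (distance <= 0) stop("distance must be > 0")
  mar_deg <- 10^logmar / 60
  gap <- distance * tan(mar_deg * pi / 180)
  structure(list(logmar = logmar, distance = distance,
                 size = 5 * gap, gap = gap, orientation = orientation),
            class = "hitd_optotype")
}

#' Chance probability of a correct answer
#'
#' With `n` equally likely optotype alternatives a random guess is correct
#' with probability `1/n`: 0.125 for the 8-orientation Landolt C set, 0.1
#' for a 10-letter set.
#'
#' @param n_orientations number of alternatives, >= 2.
#' @return `1 / n_orientations`.
#' @export
chance_probability <- function(n_orientations) {
  if (n_orientations < 2) stop("need at least 2 alternatives")
  1 / n_orientations
}

ORIENTATIONS <- seq(0, 315, by = 45)

#' Draw the next optotype orientation of a pseudo-random sequence
#'
#' Uniform draw over the eight gap orientations (45 deg steps), optionally
#' constrained never to repeat the immediately preceding orientation so
#' consecutive stimuli are always discriminably different. Uses R's global
#' RNG; seed with [set.seed()] for reproducible sequences.
#'
#' @param history numeric vector of previously shown orientations (deg);
#'   only the last element matters.
#' @param orientations candidate set (deg).
#' @param no_repeat logical; forbid immediate repeats (default `TRUE`).
#' @return One orientation (deg).
#' @export
next_orientation <- function(history = numeric(0),
                             orientations = ORIENTATIONS,
                             no_repeat = TRUE) {
  cand <- orientations
  if (no_repeat && length(history) > 0)
    cand <- setdiff(cand, history[length(history)])
  cand[sample.int(length(cand), 1L)]
}

# Weibull psychometric function of the adaptive staircase, in log units:
# probability of a correct report at tested level x for threshold T.
# Larger logMAR = larger optotype = easier, so x - T enters positively.
quest_pf <- function(x, threshold, beta, guess, lapse) {
  guess + (1 - guess - lapse) * (1 - exp(-10^(beta * (x - threshold))))
}

#' Initialize a QUEST static-acuity staircase
#'
#' Bayesian adaptive staircase for the static visual acuity (SVA)
#' threshold. The posterior over the threshold grid starts from a Gaussian
#' prior and is updated after every trial with a Weibull psychometric
#' likelihood; the next test level is the posterior mode and, after the
#' fixed number of trials, the threshold estimate is the posterior mean.
#' The staircase starts testing at 1.0 logMAR and terminates after 20
#' trials.
#'
#' Hyperparameters (slope `beta` = 3.5, lapse 0.01, guess rate 0.125 for
#' the 8-orientation Landolt set, Gaussian prior mean 1.0 / SD 1.0 logMAR,
#' grid 0-2 logMAR in 0.01 steps) follow conventional defaults of the
#' adaptive method.
#'
#' @param start first tested level (logMAR).
#' @param n_trials number of trials before termination.
#' @param grid threshold grid (logMAR).
#' @param prior_mean,prior_sd Gaussian prior on the threshold (logMAR).
#' @param beta Weibull slope.
#' @param guess guess rate (chance probability).
#' @param lapse lapse rate.
#' @return An object of class `hitd_quest` with fields `grid`, `posterior`
#'   (sums to 1), `trial_index`, `history` (data frame of tested level and
#'   correctness), `next_level`, and `estimate` (`NA` until termination).
#' @export
quest_new <- function(start = 1.0, n_trials = 20L,
                      grid = seq(0, 2, by = 0.01),
                      prior_mean = 1.0, prior_sd = 1.0,
                      beta = 3.5, guess = 0.125, lapse = 0.01) {
  post <- stats::dnorm(grid, prior_mean, prior_sd)
  post <- post / sum(post)
  structure(list(grid = grid, posterior = post,
                 trial_index = 0L, n_trials = as.integer(n_trials),
                 history = data.frame(tested = numeric(0), correct = logical(0)),
                 next_level = start, estimate = NA_real_,
                 beta = beta, guess = guess, lapse = lapse),
            class = "hitd_quest")
}

#' Update the QUEST posterior with one trial
#'
#' Multiplies the posterior by the Weibull likelihood of the observed
#' response at the tested level and renormalizes; sets the next test level
#' to the posterior mode. After the final trial the threshold estimate (the
#' posterior mean) is filled in and any further update is refused.
#'
#' @param state a `hitd_quest`.
#' @param tested tested level (logMAR).
#' @param correct logical, was the report correct.
#' @return Updated `hitd_quest`.
#' @export
quest_update <- function(state, tested, correct) {
  if (state$trial_index >= state$n_trials)
    stop("staircase complete: no updates allowed after ", state$n_trials,
         " trials")
  p <- quest_pf(tested, state$grid, state$beta, state$guess, state$lapse)
  lik <- if (isTRUE(correct)) p else 1 - p
  post <- state$posterior * lik
  post <- post / sum(post)
  state$posterior <- post
  state$trial_index <- state$trial_index + 1L
  state$history <- rbind(state$history,
                         data.frame(tested = tested, correct = isTRUE(correct)))
  state$next_level <- state$grid[which.max(post)]
  if (state$trial_index >= state$n_trials)
    state$estimate <- sum(state$grid * post)
  state
}

#' Run a complete QUEST staircase against an observer
#'
#' @param observer function taking a tested level (logMAR) and returning a
#'   logical correctness, e.g. from [quest_observer()].
#' @param ... passed to [quest_new()].
#' @return The terminated `hitd_quest` (with `estimate` filled).
#' @export
quest_run <- function(observer, ...) {
  st <- quest_new(...)
  while (st$trial_index < st$n_trials) {
    lvl <- st$next_level
    st <- quest_update(st, lvl, observer(lvl))
  }
  st
}

#' Simulated psychophysical observer
#'
#' Observer answering according to the same Weibull psychometric model the
#' staircase assumes, with a known true threshold; used to verify threshold
#' recovery. Uses R's global RNG.
#'
#' @param threshold true threshold (logMAR).
#' @param beta,guess,lapse psychometric parameters.
#' @return Function mapping a tested level to a logical correctness.
#' @export
quest_observer <- function(threshold, beta = 3.5, guess = 0.125,
                           lapse = 0.01) {
  function(level)
    stats::runif(1) < quest_pf(level, threshold, beta, guess, lapse)
}

#' Fit a psychometric logistic to correct-rate data
#'
#' Maximum-likelihood logistic fit of the probability of a correct answer
#' versus optotype size increment, with the lower asymptote fixed at the
#' chance level (0.125 for the 8-orientation Landolt set) and the upper
#' asymptote `1 - lapse` with the lapse free in `[0, 0.05]`:
#' `p(x) = chance + (1 - chance - lapse) / (1 + exp(-slope (x - midpoint)))`.
#' The likelihood is binomial per point. Degenerate data (every point at
#' 100% correct, or no point above chance) leave the threshold unidentified;
#' such fits are returned with `converged = FALSE` and an explanatory flag
#' rather than an error. The fit is invariant to the ordering of the input
#' points.
#'
#' @param increment numeric vector of size increments (logMAR).
#' @param n_correct,n_total integer vectors, correct and total trials per
#'   increment.
#' @param chance fixed lower asymptote.
#' @param max_lapse upper bound on the lapse rate.
#' @return An object of class `hitd_psychfit`: `midpoint` (logMAR),
#'   `slope` (per logMAR, positive), `lower_asymptote`, `lapse`,
#'   `converged`, `flag`, `loglik`.
#' @export
fit_psychometric <- function(increment, n_correct, n_total,
                             chance = 0.125, max_lapse = 0.05) {
  if (length(unique(increment)) < 3)
    stop("need at least 3 distinct increments")
  stopifnot(length(increment) == length(n_correct),
            length(n_correct) == length(n_total),
            all(n_correct <= n_total), all(n_total > 0))
  prop <- n_correct / n_total
  res <- structure(list(midpoint = NA_real_, slope = NA_real_,
                        lower_asymptote = chance, lapse = NA_real_,
                        converged = FALSE, flag = "", loglik = NA_real_),
                   class = "hitd_psychfit")
  if (all(n_correct == n_total)) {
    res$flag <- "all correct: threshold below tested range, unidentified"
    return(res)
  }
  se <- sqrt(chance * (1 - chance) / n_total)
  if (all(prop <= chance + 2 * se)) {
    res$flag <- "all at chance: threshold above tested range, unidentified"
    return(res)
  }
  pfun <- function(x, m, s, lam)
    chance + (1 - chance - lam) * stats::plogis(s * (x - m))
  nll <- function(par) {
    m <- par[1]; s <- exp(par[2]); lam <- max_lapse * stats::plogis(par[3])
    p <- pmin(pmax(pfun(increment, m, s, lam), 1e-9), 1 - 1e-9)
    -sum(stats::dbinom(n_correct, n_total, p, log = TRUE))
  }
  # start the midpoint where the observed rate crosses halfway to ceiling
  half <- chance + (1 - chance) / 2
  ord <- order(increment)
  m0 <- tryCatch(stats::approx(prop[ord], increment[ord], xout = half,
                               ties = mean, rule = 2)$y,
                 error = function(e) NA_real_)
  if (!is.finite(m0)) m0 <- stats::median(increment)
  fit <- stats::optim(c(m0, log(10), 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  res$midpoint <- fit$par[1]
  res$slope <- exp(fit$par[2])
  res$lapse <- max_lapse * stats::plogis(fit$par[3])
  res$converged <- fit$convergence == 0
  res$loglik <- -fit$value
  if (!res$converged) res$flag <- "optimizer did not converge"
  res
}

#' Evaluate a fitted psychometric function
#'
#' @param object a `hitd_psychfit`.
#' @param newdata numeric vector of increments (logMAR).
#' @param ... unused.
#' @return Predicted probability of a correct answer.
#' @export
predict.hitd_psychfit <- function(object, newdata, ...) {
  if (!object$converged && is.na(object$midpoint))
    stop("fit did not converge: ", object$flag)
  object$lower_asymptote +
    (1 - object$lower_asymptote - object$lapse) *
      stats::plogis(object$slope * (newdata - object$midpoint))
}

#' @export
print.hitd_psychfit <- function(x, ...) {
  if (is.na(x$midpoint)) {
    cat("Psychometric fit: not identified (", x$flag, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Psychometric logistic: midpoint %.3f logMAR, slope %.1f /logMAR, floor %.3f, lapse %.3f (%s)\n",
      x$midpoint, x$slope, x$lower_asymptote, x$lapse,
      if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
print.hitd_quest <- function(x, ...) {
  cat(sprintf("QUEST staircase: %d/%d trials", x$trial_index, x$n_trials))
  if (!is.na(x$estimate)) cat(sprintf(", threshold estimate %.3f logMAR", x$estimate))
  else cat(sprintf(", next level %.2f logMAR", x$next_level))
  cat("\n")
  invisible(x)
}
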