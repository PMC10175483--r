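#' Method-of-constant-stimuli presentation plan
#'
#' Builds the training-session plan: equally spaced flicker frequencies
#' spanning the range from 5 Hz below to 5 Hz above the baseline threshold,
#' each presented a fixed number of times in shuffled order.
#'
#' @param baseline_threshold Baseline threshold in Hz (must exceed the half
#'   range, so all levels stay positive).
#' @param n_levels Number of levels (default 11, i.e. 1 Hz spacing over a
#'   +/- 5 Hz range).
#' @param reps Presentations per level (default 20).
#' @param half_range Half width of the level range in Hz (default 5).
#' @param rng An [rng_stream()] used to shuffle the presentation order.
#' @return An object of class `cs_plan` with `levels`, `reps` and the
#'   shuffled presentation `order`.
#' @export
build_constant_stimuli_plan <- function(baseline_threshold, n_levels = 11,
                                        reps = 20, half_range = 5, rng) {
  if (n_levels < 2) stop("`n_levels` must be at least 2")
  stopifnot(baseline_threshold > half_range, reps >= 1)
  levels <- seq(baseline_threshold - half_range,
                baseline_threshold + half_range, length.out = n_levels)
  order <- with_rng(rng, sample(rep(levels, each = reps)))
  structure(list(levels = levels, reps = as.integer(reps), order = order),
            class = "cs_plan")
}

#' @export
print.cs_plan <- function(x, ...) {
  cat(sprintf("Constant-stimuli plan: %d levels (%g..%g) x %d reps = %d trials\n",
              length(x$levels), min(x$levels), max(x$levels), x$reps,
              length(x$order)))
  invisible(x)
}

#' Run a constant-stimuli session against an observer
#'
#' @param observer An observer (or responder function of a level).
#' @param plan A [build_constant_stimuli_plan()].
#' @param rng An [rng_stream()].
#' @return A data.frame trial log with columns `trial_index`, `level`,
#'   `correct`.
#' @export
run_constant_stimuli <- function(observer, plan, rng) {
  stopifnot(inherits(plan, "cs_plan"))
  correct <- if (inherits(observer, "observer")) {
    simulate_trials(observer, plan$order, rng)
  } else {
    vapply(plan$order, function(l) as.logical(observer(l)), logical(1))
  }
  data.frame(trial_index = seq_along(plan$order), level = plan$order,
             correct = correct)
}

# Aggregate per-trial data to per-level (k out of n) counts.
.aggregate_trials <- function(level, correct) {
  lev <- sort(unique(level))
  k <- vapply(lev, function(l) sum(correct[level == l]), numeric(1))
  n <- vapply(lev, function(l) sum(level == l), numeric(1))
  data.frame(level = lev, k = k, n = n)
}

#' Maximum-likelihood psychometric (logistic) fit
#'
#' Fits the 2AFC psychometric function
#' \eqn{p(x) = \gamma + (1-\gamma-\lambda) S(x)} to forced-choice data by
#' maximizing the binomial likelihood, with the guess rate \eqn{\gamma}
#' fixed at chance, the lapse rate \eqn{\lambda} free within
#' `[0, lapse_max]`, and \eqn{\alpha}, \eqn{\beta} free.  Optimization uses
#' a fixed multi-start grid followed by bounded local refinement, so the fit
#' is deterministic given the data; ties are broken by higher likelihood
#' then lower \eqn{\lambda}.
#'
#' @param level Numeric vector: stimulus level per trial, or per-group
#'   levels when `k`/`n` are supplied.
#' @param correct Logical vector of per-trial correctness (omit when using
#'   `k`/`n`).
#' @param k,n Optional per-level correct counts and totals (aggregated
#'   input).
#' @param guess Fixed guess rate (default 0.5).
#' @param lapse_max Upper bound for the lapse rate (default 0.06).
#' @param direction Task direction, as in [observer_model()].
#' @param unit Stimulus unit label.
#' @return An object of class `psychfit` with components `alpha`, `beta`,
#'   `lambda`, `guess`, `logLik`, the aggregated `data`, and
#'   `lambda_at_bound`.
#' @seealso [threshold_at_criterion()] to read a criterion threshold off the
#'   fitted curve.
#' @examples
#' r <- rng_stream(1)
#' obs <- observer_model(30, 2)
#' plan <- build_constant_stimuli_plan(30, rng = r)
#' log <- run_constant_stimuli(obs, plan, r)
#' fit <- fit_psychometric(log$level, log$correct)
#' coef(fit)
#' threshold_at_criterion(fit, 0.8)
#' @export
fit_psychometric <- function(level, correct = NULL, k = NULL, n = NULL,
                             guess = 0.5, lapse_max = 0.06,
                             direction = c("decreasing", "increasing"),
                             unit = "Hz") {
  direction <- match.arg(direction)
  dat <- if (!is.null(k)) {
    stopifnot(!is.null(n), length(level) == length(k), length(k) == length(n))
    data.frame(level = level, k = k, n = n)
  } else {
    stopifnot(!is.null(correct), length(level) == length(correct))
    .aggregate_trials(level, as.logical(correct))
  }
  if (nrow(dat) < 2) stop("need responses at >= 2 distinct stimulus levels")
  if (sum(dat$k) == sum(dat$n)) {
    stop("all responses correct: the slope is not identifiable; ",
         "include harder stimulus levels")
  }
  if (sum(dat$k) == 0) {
    stop("all responses incorrect: the slope is not identifiable; ",
         "include easier stimulus levels")
  }

  sgn <- if (direction == "decreasing") -1 else 1
  nll <- function(par) {
    alpha <- par[1]; beta <- exp(par[2]); lambda <- par[3]
    p <- guess + (1 - guess - lambda) *
      stats::plogis(sgn * (dat$level - alpha) / beta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(dat$k * log(p) + (dat$n - dat$k) * log(1 - p))
  }

  rng_lev <- range(dat$level)
  span <- max(diff(rng_lev), 1e-6)
  alpha0 <- stats::quantile(dat$level, c(0.25, 0.5, 0.75),
                            names = FALSE, type = 7)
  beta0 <- span * c(0.1, 0.3)
  lambda0 <- c(0, min(0.03, lapse_max))
  lower <- c(rng_lev[1] - span, log(span * 1e-3), 0)
  upper <- c(rng_lev[2] + span, log(span * 10), lapse_max)

  best <- NULL
  for (a in alpha0) for (b in beta0) for (l in lambda0) {
    fit <- tryCatch(
      stats::optim(c(a, log(b), l), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10 ||
        (abs(fit$value - best$value) <= 1e-10 && fit$par[3] < best$par[3])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("psychometric fit failed to converge")

  lambda_hat <- best$par[3]
  at_bound <- lambda_hat >= lapse_max - 1e-8
  if (at_bound) {
    warning("lapse-rate estimate is at its upper bound (", lapse_max, ")")
  }
  structure(
    list(alpha = best$par[1], beta = exp(best$par[2]), lambda = lambda_hat,
         guess = guess, logLik = -best$value, data = dat,
         direction = direction, unit = unit, lapse_max = lapse_max,
         lambda_at_bound = at_bound),
    class = "psychfit"
  )
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf(
    "Psychometric fit (logistic, %s): alpha = %.4g %s, beta = %.4g, lambda = %.4g\n",
    x$direction, x$alpha, x$unit, x$beta, x$lambda))
  cat(sprintf("  guess fixed at %g; logLik = %.4f on %d levels\n",
              x$guess, x$logLik, nrow(x$data)))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, gamma = object$guess,
    lambda = object$lambda)
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$logLik, df = 3, class = "logLik")
}

#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$level else newdata
  sgn <- if (object$direction == "decreasing") -1 else 1
  object$guess + (1 - object$guess - object$lambda) *
    stats::plogis(sgn * (x - object$alpha) / object$beta)
}

#' @export
summary.psychfit <- function(object, ...) {
  d <- object$data
  d$prop <- d$k / d$n
  d$fitted <- predict(object, d$level)
  out <- list(coef = coef(object), table = d, logLik = object$logLik,
              lambda_at_bound = object$lambda_at_bound)
  class(out) <- "summary.psychfit"
  out
}

#' @export
print.summary.psychfit <- function(x, ...) {
  cat("Coefficients:\n")
  print(x$coef)
  cat("\nPer-level data:\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.psychfit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$level, d$k / d$n, ylim = c(0, 1),
                 xlab = paste0("level (", x$unit, ")"),
                 ylab = "proportion correct", ...)
  xx <- seq(min(d$level), max(d$level), length.out = 200)
  graphics::lines(xx, predict(x, xx))
  graphics::abline(h = x$guess, lty = 3)
  invisible(x)
}

#' Stimulus level at a criterion percent correct
#'
#' Inverts a fitted (or generating) psychometric function at a criterion
#' probability on the full performance curve, including guess and lapse
#' rates: the level where the curve crosses e.g. 80% correct.
#'
#' @param object A `psychfit` or an `observer`.
#' @param criterion Target probability, strictly between the guess rate and
#'   `1 - lambda`.
#' @return The stimulus level, closed form.
#' @export
threshold_at_criterion <- function(object, criterion) {
  UseMethod("threshold_at_criterion")
}

.invert_curve <- function(alpha, beta, guess, lapse, direction, criterion) {
  if (criterion <= guess || criterion >= 1 - lapse) {
    stop(sprintf(
      "criterion %.3g is unattainable: the curve spans (%g, %g)",
      criterion, guess, 1 - lapse))
  }
  q <- (criterion - guess) / (1 - guess - lapse)
  if (direction == "decreasing") alpha - beta * stats::qlogis(q)
  else alpha + beta * stats::qlogis(q)
}

#' @export
threshold_at_criterion.psychfit <- function(object, criterion) {
  .invert_curve(object$alpha, object$beta, object$guess, object$lambda,
                object$direction, criterion)
}

#' @export
threshold_at_criterion.observer <- function(object, criterion) {
  .invert_curve(object$threshold, object$slope, object$guess, object$lapse,
                object$direction, criterion)
}

#' Simulate a multi-session training course
#'
#' Runs the full training loop: for each session the observer's threshold is
#' advanced by the learning schedule, a constant-stimuli plan is centred on
#' the current threshold estimate (the baseline for session 1, thereafter
#' the previous session's estimate), a session is simulated, the logistic is
#' fitted, and the criterion threshold is extracted.
#'
#' @param observer Session-1 observer.
#' @param schedule A [learning_schedule()].
#' @param rng An [rng_stream()].
#' @param baseline_threshold Centre of the session-1 plan; defaults to the
#'   observer's true threshold (in practice the baseline staircase
#'   estimate).
#' @param n_levels,reps,half_range Plan geometry per session.
#' @param criterion Percent-correct criterion for the session threshold
#'   (default 0.8).
#' @return An object of class `training_course`: data.frame `sessions`
#'   (session, threshold), plus per-session `fits` and trial `logs`.
#' @export
run_training_course <- function(observer, schedule, rng,
                                baseline_threshold = observer$threshold,
                                n_levels = 11, reps = 20, half_range = 5,
                                criterion = 0.8) {
  stopifnot(inherits(observer, "observer"),
            inherits(schedule, "learning_schedule"))
  centre <- baseline_threshold
  thresholds <- numeric(schedule$n_sessions)
  fits <- vector("list", schedule$n_sessions)
  logs <- vector("list", schedule$n_sessions)
  for (s in seq_len(schedule$n_sessions)) {
    obs_s <- apply_learning(observer, schedule, s)
    plan <- build_constant_stimuli_plan(centre, n_levels, reps, half_range, rng)
    log <- run_constant_stimuli(obs_s, plan, rng)
    fit <- fit_psychometric(log$level, log$correct, guess = observer$guess,
                            direction = observer$direction,
                            unit = observer$unit)
    thresholds[s] <- threshold_at_criterion(fit, criterion)
    fits[[s]] <- fit
    logs[[s]] <- cbind(session = s, log)
    centre <- thresholds[s]
  }
  structure(
    list(sessions = data.frame(session = seq_len(schedule$n_sessions),
                               threshold = thresholds),
         fits = fits, logs = logs, criterion = criterion),
    class = "training_course"
  )
}

#' @export
print.training_course <- function(x, ...) {
  cat(sprintf("Training course (%d sessions, %.0f%% criterion):\n",
              nrow(x$sessions), 100 * x$criterion))
  print(x$sessions, row.names = FALSE)
  invisible(x)
}

#' @export
plot.training_course <- function(x, ...) {
  graphics::plot(x$sessions$session, x$sessions$threshold, type = "b",
                 xlab = "session", ylab = "criterion threshold", ...)
  invisible(x)
}
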