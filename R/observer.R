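#' Parametric 2AFC observer model
#'
#' A simulated observer for two-alternative forced-choice (2AFC) tasks,
#' defined by a four-parameter psychometric function
#' \deqn{p(x) = \gamma + (1 - \gamma - \lambda)\, S(x)}
#' where \eqn{S} is a logistic in the stimulus value \eqn{x}:
#' \eqn{S(x) = 1 / (1 + e^{-(\alpha - x)/\beta})} for tasks where performance
#' falls as the stimulus value rises (critical flicker fusion: higher flicker
#' frequency is harder to tell from a fused reference), and
#' \eqn{S(x) = 1 / (1 + e^{-(x - \alpha)/\beta})} where performance rises
#' (stereo: larger disparity is easier).  \eqn{\alpha} is the point where
#' \eqn{S = 1/2}, i.e. performance is halfway between the guess rate
#' \eqn{\gamma} and the lapse ceiling \eqn{1 - \lambda}.
#'
#' @param threshold Psychometric midpoint \eqn{\alpha}, in stimulus units
#'   (Hz for flicker frequency, arcsec for disparity).
#' @param slope Logistic scale \eqn{\beta > 0}, same units as `threshold`.
#'   Smaller values give a steeper function.
#' @param guess Guess rate \eqn{\gamma} (0.5 for 2AFC, 1/3 for 3AFC).
#' @param lapse Lapse rate \eqn{\lambda \in [0, 0.1]}.
#' @param direction `"decreasing"` if percent correct falls with increasing
#'   stimulus value (flicker frequency), `"increasing"` if it rises
#'   (disparity).
#' @param unit Stimulus unit label, `"Hz"` or `"arcsec"`.
#' @return An object of class `observer`.
#' @seealso [p_correct()], [simulate_trials()], [apply_learning()]
#' @examples
#' obs <- observer_model(threshold = 30, slope = 2)
#' p_correct(obs, c(25, 30, 35))
#' @export
observer_model <- function(threshold, slope, guess = 0.5, lapse = 0,
                           direction = c("decreasing", "increasing"),
                           unit = "Hz") {
  direction <- match.arg(direction)
  stopifnot(is.finite(threshold), is.finite(slope), slope > 0,
            guess >= 0, guess < 1, lapse >= 0, lapse <= 0.1,
            guess + lapse < 1)
  structure(
    list(threshold = threshold, slope = slope, guess = guess, lapse = lapse,
         direction = direction, unit = unit),
    class = "observer"
  )
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf(
    "2AFC observer: alpha = %g %s, beta = %g, guess = %g, lapse = %g (%s)\n",
    x$threshold, x$unit, x$slope, x$guess, x$lapse, x$direction))
  invisible(x)
}

#' Probability of a correct response
#'
#' Evaluates the observer's psychometric function at one or more stimulus
#' values.  The result is bounded in `[guess, 1 - lapse]` and monotone in the
#' observer's declared direction.
#'
#' @param observer An [observer_model()] or [binocular_observer()].
#' @param stimulus Numeric vector of stimulus values (finite).
#' @return Numeric vector of probabilities.
#' @export
p_correct <- function(observer, stimulus) UseMethod("p_correct")

#' @export
p_correct.observer <- function(observer, stimulus) {
  if (!is.numeric(stimulus) || any(!is.finite(stimulus))) {
    stop("`stimulus` must be finite numeric")
  }
  s <- .logistic_core(observer, stimulus)
  observer$guess + (1 - observer$guess - observer$lapse) * s
}

.logistic_core <- function(observer, stimulus) {
  x <- if (observer$direction == "decreasing") {
    (observer$threshold - stimulus) / observer$slope
  } else {
    (stimulus - observer$threshold) / observer$slope
  }
  stats::plogis(x)
}

#' Binocular observer by probability summation
#'
#' Combines two monocular observers into a binocular (OU) observer under
#' independent probability summation: the binocular stimulus is detected if
#' either eye's channel detects it,
#' \deqn{p_{OU}(x) = \gamma + (1-\gamma-\lambda)\,[1 - (1 - S_L(x))(1 - S_R(x))].}
#' The guess and lapse rates are taken from the left-eye observer; both eyes
#' must share task direction and unit.
#'
#' @param left,right Monocular [observer_model()] objects.
#' @return An object of class `c("binocular_observer", "observer")`.
#' @export
binocular_observer <- function(left, right) {
  stopifnot(inherits(left, "observer"), inherits(right, "observer"),
            left$direction == right$direction, left$unit == right$unit)
  structure(
    list(left = left, right = right,
         guess = left$guess, lapse = left$lapse,
         direction = left$direction, unit = left$unit),
    class = c("binocular_observer", "observer")
  )
}

#' @export
p_correct.binocular_observer <- function(observer, stimulus) {
  if (!is.numeric(stimulus) || any(!is.finite(stimulus))) {
    stop("`stimulus` must be finite numeric")
  }
  sl <- .logistic_core(observer$left, stimulus)
  sr <- .logistic_core(observer$right, stimulus)
  s <- 1 - (1 - sl) * (1 - sr)
  observer$guess + (1 - observer$guess - observer$lapse) * s
}

#' @export
print.binocular_observer <- function(x, ...) {
  cat("Binocular (OU) observer, probability summation over:\n  L: ")
  print(x$left)
  cat("  R: ")
  print(x$right)
  invisible(x)
}

#' Simulate forced-choice trials
#'
#' Draws Bernoulli correct/incorrect responses from the observer's
#' psychometric function.  Reproducible for a fixed stream state.
#'
#' @param observer An observer.
#' @param stimulus Numeric vector of stimulus values, one trial each.
#' @param rng An [rng_stream()].
#' @return Logical vector of per-trial correctness.
#' @export
simulate_trials <- function(observer, stimulus, rng) {
  p <- p_correct(observer, stimulus)
  with_rng(rng, stats::runif(length(p)) < p)
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(observer, stimulus, rng) {
  stopifnot(length(stimulus) == 1L)
  simulate_trials(observer, stimulus, rng)
}

#' Session-to-session learning schedule
#'
#' Describes multiplicative threshold change across training sessions:
#' after session \eqn{k} the threshold is scaled by
#' \eqn{(1 + g)^{k-1}} where \eqn{g} is the per-session fractional gain.
#' For flicker fusion a positive gain means improvement (higher fusion
#' frequency); for disparity thresholds improvement is a negative gain.
#'
#' @param n_sessions Number of training sessions (default 5).
#' @param per_session_gain Signed fractional threshold change per session.
#' @param eye_scope Which eye(s) the schedule applies to: the trained eye
#'   only, both, or none.
#' @return An object of class `learning_schedule`.
#' @export
learning_schedule <- function(n_sessions = 5, per_session_gain = 0,
                              eye_scope = c("trained", "both", "none")) {
  eye_scope <- match.arg(eye_scope)
  stopifnot(n_sessions >= 1, is.finite(per_session_gain),
            per_session_gain > -1)
  structure(
    list(n_sessions = as.integer(n_sessions),
         per_session_gain = per_session_gain, eye_scope = eye_scope),
    class = "learning_schedule"
  )
}

#' Apply a learning schedule to an observer
#'
#' Returns the observer as it stands at the start of a given session:
#' `threshold` scaled by `(1 + per_session_gain)^(session_index - 1)`,
#' all other parameters unchanged.  Gains compound multiplicatively, so
#' applying sessions one at a time equals one application of the compounded
#' gain.
#'
#' @param observer An [observer_model()].
#' @param schedule A [learning_schedule()].
#' @param session_index Session number in `1:n_sessions`.
#' @return A new `observer`.
#' @export
apply_learning <- function(observer, schedule, session_index) {
  stopifnot(inherits(observer, "observer"),
            inherits(schedule, "learning_schedule"))
  if (length(session_index) != 1L || !is.finite(session_index) ||
      session_index < 1 || session_index > schedule$n_sessions) {
    stop("`session_index` must lie in 1..n_sessions (", schedule$n_sessions, ")")
  }
  out <- observer
  out$threshold <- observer$threshold *
    (1 + schedule$per_session_gain)^(session_index - 1)
  out
}
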