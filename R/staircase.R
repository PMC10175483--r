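#' Transformed up-down staircase configuration
#'
#' Configuration of a 3-down-1-up (3:1) adaptive staircase: after
#' `rule_up` consecutive correct responses the stimulus steps one
#' `step_size` in the *harder* direction; after any error it steps one
#' `step_size` easier.  This rule converges where the probability of a
#' correct response satisfies \eqn{p^3 = 0.5}, i.e. about 79.4% correct.
#' A run stops after `n_reversals_stop` reversals and the threshold is the
#' arithmetic mean of the last `n_reversals_avg` reversal levels.
#'
#' @param start_level Starting stimulus level.
#' @param step_size Fixed step, in stimulus units (2 Hz for flicker
#'   frequency; 1 pixel = 55 arcsec for disparity).
#' @param n_reversals_stop Reversals needed to finish a run (default 8).
#' @param n_reversals_avg Late reversals averaged into the threshold
#'   (default 6).
#' @param rule_up Consecutive-correct count that makes the task harder
#'   (default 3).
#' @param rule_down Errors that make it easier (default 1; only 1 is
#'   supported).
#' @param floor_level,ceiling_level Hard bounds; levels clamp here.
#' @param harder Direction of the harder step: `"up"` when a larger
#'   stimulus value is harder (flicker frequency), `"down"` when smaller is
#'   harder (disparity).
#' @param n_repetitions Repetitions averaged by [run_repeated_staircase()]
#'   (default 2).
#' @param max_trials Safety cap per track; runs hitting it are invalid.
#' @param unit Stimulus unit label.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_level, step_size = 2,
                             n_reversals_stop = 8, n_reversals_avg = 6,
                             rule_up = 3, rule_down = 1,
                             floor_level = -Inf, ceiling_level = Inf,
                             harder = c("up", "down"),
                             n_repetitions = 2, max_trials = 200,
                             unit = "Hz") {
  harder <- match.arg(harder)
  stopifnot(step_size > 0, n_reversals_avg <= n_reversals_stop,
            rule_up >= 1, rule_down == 1,
            floor_level < start_level, start_level < ceiling_level,
            n_repetitions >= 1, max_trials > 0)
  structure(
    list(start_level = start_level, step_size = step_size,
         n_reversals_stop = as.integer(n_reversals_stop),
         n_reversals_avg = as.integer(n_reversals_avg),
         rule_up = as.integer(rule_up), rule_down = as.integer(rule_down),
         floor_level = floor_level, ceiling_level = ceiling_level,
         harder = harder, n_repetitions = as.integer(n_repetitions),
         max_trials = as.integer(max_trials), unit = unit),
    class = "staircase_config"
  )
}

#' Initialize staircase state
#'
#' @param config A [staircase_config()].
#' @return A `staircase_state` list: current `level`, consecutive-correct
#'   `streak`, last movement direction, reversal levels, trial history and
#'   termination fields.
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(config = config, level = config$start_level, streak = 0L,
         last_direction = 0L, reversal_levels = numeric(0),
         levels = numeric(0), responses = logical(0),
         terminated = FALSE, terminated_by = NA_character_),
    class = "staircase_state"
  )
}

#' Advance a staircase by one trial
#'
#' Applies the transformed up-down rule to one response at the current
#' level: `rule_up` consecutive correct responses move one step in the
#' harder direction and reset the counter; any error moves one step easier.
#' A reversal is recorded at the level where the movement direction flips;
#' trials before the first movement have no direction and cannot produce
#' one.  Levels are clamped to `[floor_level, ceiling_level]`.
#'
#' @param state A `staircase_state` (not yet terminated).
#' @param correct Logical response for the trial presented at
#'   `state$level`.
#' @return The updated state; `terminated` becomes `TRUE` once the reversal
#'   criterion or the trial cap is met.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$terminated) stop("staircase already terminated")
  stopifnot(is.logical(correct), length(correct) == 1L, !is.na(correct))
  cfg <- state$config
  harder <- if (cfg$harder == "up") 1L else -1L

  state$levels <- c(state$levels, state$level)
  state$responses <- c(state$responses, correct)

  move <- 0L
  if (correct) {
    state$streak <- state$streak + 1L
    if (state$streak == cfg$rule_up) {
      move <- harder
      state$streak <- 0L
    }
  } else {
    state$streak <- 0L
    move <- -harder
  }

  if (move != 0L) {
    if (state$last_direction != 0L && move != state$last_direction) {
      state$reversal_levels <- c(state$reversal_levels, state$level)
    }
    state$last_direction <- move
    state$level <- min(cfg$ceiling_level,
                       max(cfg$floor_level, state$level + move * cfg$step_size))
  }

  if (length(state$reversal_levels) >= cfg$n_reversals_stop) {
    state$terminated <- TRUE
    state$terminated_by <- "reversals_met"
  } else if (length(state$levels) >= cfg$max_trials) {
    state$terminated <- TRUE
    state$terminated_by <-
      if (state$level <= cfg$floor_level || state$level >= cfg$ceiling_level)
        "bound_hit" else "trial_cap"
  }
  state
}

.as_responder <- function(responder, rng) {
  if (inherits(responder, "observer")) {
    obs <- responder
    if (is.null(rng)) stop("an observer responder requires `rng`")
    function(level) simulate_trial(obs, level, rng)
  } else {
    stopifnot(is.function(responder))
    responder
  }
}

#' Run one adaptive staircase to completion
#'
#' Presents trials until the reversal criterion is met (or the trial cap is
#' hit), then computes the threshold as the mean of the last
#' `n_reversals_avg` reversal levels.
#'
#' @param responder Either a function mapping a stimulus level to a logical
#'   correctness flag (e.g. a replayed trial log via [replay_responder()]),
#'   or an [observer_model()] (then `rng` is required).
#' @param config A [staircase_config()].
#' @param rng An [rng_stream()]; needed only for observer responders.
#' @return An object of class `staircase_run` with the full trial
#'   trajectory, the reversal levels, `threshold` (`NA` unless the run
#'   terminated by `reversals_met`) and `terminated_by`.
#' @export
run_staircase <- function(responder, config, rng = NULL) {
  respond <- .as_responder(responder, rng)
  state <- staircase_init(config)
  while (!state$terminated) {
    state <- staircase_update(state, as.logical(respond(state$level)))
  }
  threshold <- if (state$terminated_by == "reversals_met") {
    mean(utils::tail(state$reversal_levels, config$n_reversals_avg))
  } else {
    NA_real_
  }
  structure(
    list(trials = data.frame(level = state$levels, correct = state$responses),
         reversal_levels = state$reversal_levels,
         threshold = threshold, terminated_by = state$terminated_by,
         config = config),
    class = "staircase_run"
  )
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf(
    "Staircase run: %d trials, %d reversals, threshold = %s %s (%s)\n",
    nrow(x$trials), length(x$reversal_levels),
    if (is.na(x$threshold)) "invalid" else format(x$threshold),
    x$config$unit, x$terminated_by))
  invisible(x)
}

#' @export
plot.staircase_run <- function(x, ...) {
  graphics::plot(seq_len(nrow(x$trials)), x$trials$level, type = "s",
                 xlab = "trial", ylab = paste0("level (", x$config$unit, ")"),
                 ...)
  graphics::points(seq_len(nrow(x$trials)), x$trials$level,
                   pch = ifelse(x$trials$correct, 16, 1))
  if (!is.na(x$threshold)) graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Repeat a staircase and average the thresholds
#'
#' The full procedure is repeated `config$n_repetitions` times and the
#' threshold is the mean of the per-repetition thresholds, increasing
#' test-retest reliability.  Any invalid repetition (bound hit or trial cap)
#' makes the combined result invalid, with the reason propagated.
#'
#' @inheritParams run_staircase
#' @return A list of class `staircase_threshold`: `threshold`, `valid`,
#'   `reason` and the per-repetition `runs`.
#' @export
run_repeated_staircase <- function(responder, config, rng = NULL) {
  runs <- lapply(seq_len(config$n_repetitions), function(i) {
    run_staircase(responder, config, rng)
  })
  th <- vapply(runs, `[[`, numeric(1), "threshold")
  invalid <- vapply(runs, `[[`, character(1), "terminated_by") != "reversals_met"
  structure(
    list(threshold = if (any(invalid)) NA_real_ else mean(th),
         valid = !any(invalid),
         reason = if (any(invalid)) {
           paste("invalid repetition:",
                 paste(which(invalid), collapse = ", "))
         } else NA_character_,
         runs = runs),
    class = "staircase_threshold"
  )
}

#' @export
print.staircase_threshold <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("Threshold over %d repetitions: %g\n", length(x$runs),
                x$threshold))
  } else {
    cat("Invalid threshold:", x$reason, "\n")
  }
  invisible(x)
}

#' Random interleaving of eye conditions
#'
#' Assigns each trial independently and uniformly to one of the given
#' conditions, as when the stimulus is presented at random to either eye or
#' to both eyes within one test.
#'
#' @param conditions Non-empty character vector of condition labels.
#' @param n_trials Number of trials to assign.
#' @param rng An [rng_stream()].
#' @return Character vector of length `n_trials`.
#' @export
interleave_conditions <- function(conditions, n_trials, rng) {
  stopifnot(length(conditions) >= 1, n_trials >= 0)
  if (length(conditions) == 1L) return(rep(conditions, n_trials))
  with_rng(rng, sample(conditions, n_trials, replace = TRUE))
}

#' Run independent staircases under randomly interleaved conditions
#'
#' Each condition keeps its own staircase track, advanced only on the trials
#' assigned to it; assignment is uniform at random among the tracks still
#' running.
#'
#' @param responders Named list (one per condition) of responder functions
#'   or observers.
#' @param config A [staircase_config()] shared by all tracks (or a named
#'   list of per-condition configs).
#' @param rng An [rng_stream()].
#' @return Named list of [run_staircase()]-style results, each with an extra
#'   `n_trials` field equal to the number of trials that track received.
#' @export
run_interleaved_staircases <- function(responders, config, rng) {
  stopifnot(is.list(responders), length(names(responders)) == length(responders))
  cfgs <- if (inherits(config, "staircase_config")) {
    stats::setNames(rep(list(config), length(responders)), names(responders))
  } else config
  respond <- lapply(names(responders),
                    function(nm) .as_responder(responders[[nm]], rng))
  names(respond) <- names(responders)
  states <- lapply(names(responders), function(nm) staircase_init(cfgs[[nm]]))
  names(states) <- names(responders)

  active <- names(states)
  while (length(active)) {
    nm <- if (length(active) == 1L) active else
      with_rng(rng, sample(active, 1L))
    states[[nm]] <- staircase_update(states[[nm]],
                                     as.logical(respond[[nm]](states[[nm]]$level)))
    if (states[[nm]]$terminated) active <- setdiff(active, nm)
  }

  lapply(states, function(state) {
    cfg <- state$config
    threshold <- if (state$terminated_by == "reversals_met") {
      mean(utils::tail(state$reversal_levels, cfg$n_reversals_avg))
    } else NA_real_
    structure(
      list(trials = data.frame(level = state$levels, correct = state$responses),
           reversal_levels = state$reversal_levels, threshold = threshold,
           terminated_by = state$terminated_by, config = cfg,
           n_trials = length(state$levels)),
      class = "staircase_run")
  })
}

#' Responder that replays a recorded trial log
#'
#' Returns the logged responses in order, for re-running a staircase from a
#' saved session; the replayed levels are checked against the log.
#'
#' @param log A data.frame with columns `level` and `response_correct` (or
#'   `correct`).
#' @param check_levels Stop if the staircase presents a level differing from
#'   the logged one (default TRUE).
#' @return A responder function.
#' @export
replay_responder <- function(log, check_levels = TRUE) {
  correct <- if ("response_correct" %in% names(log)) {
    log$response_correct
  } else log$correct
  lev <- log$level
  i <- 0L
  function(level) {
    i <<- i + 1L
    if (i > length(correct)) stop("replay log exhausted at trial ", i)
    if (check_levels && abs(level - lev[i]) > 1e-9) {
      stop(sprintf("replayed level %g disagrees with logged level %g at trial %d",
                   level, lev[i], i))
    }
    as.logical(correct[i])
  }
}

#' Disparity staircase in whole-pixel steps
#'
#' Runs the same 3-down-1-up engine on a random-dot disparity task where the
#' disparity is quantized to whole pixels and larger disparity is easier
#' (harder direction is down).  The threshold is reported in arcsec as pixel
#' count times the pixel pitch.
#'
#' @param observer A disparity observer (stimulus unit arcsec,
#'   `direction = "increasing"`), or a responder function taking a disparity
#'   in arcsec.
#' @param config A [staircase_config()] whose levels are in *pixels*
#'   (`step_size` 1, integer start/floor/ceiling); `harder` is forced to
#'   `"down"`.
#' @param rng An [rng_stream()].
#' @param arcsec_per_pixel Pixel pitch in arcsec (default 55).
#' @return A `staircase_threshold` with `threshold` in arcsec and an extra
#'   `threshold_px` field.
#' @export
run_disparity_staircase <- function(observer, config, rng = NULL,
                                    arcsec_per_pixel = 55) {
  stopifnot(inherits(config, "staircase_config"))
  if (config$harder != "down") {
    config$harder <- "down"
  }
  if (abs(config$step_size - round(config$step_size)) > 1e-9 ||
      abs(config$start_level - round(config$start_level)) > 1e-9) {
    stop("disparity levels are quantized to whole pixels")
  }
  base <- .as_responder(observer, rng)
  respond_px <- function(level_px) base(level_px * arcsec_per_pixel)
  res <- run_repeated_staircase(respond_px, config, rng)
  res$threshold_px <- res$threshold
  res$threshold <- res$threshold * arcsec_per_pixel
  res$unit <- "arcsec"
  res
}
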