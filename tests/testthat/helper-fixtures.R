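# Shared fixtures: canonical observers, scripted responders, and an
# independent minimal re-implementation of the transformed up-down rule used
# as an oracle against the package's staircase engine.

std_observer <- function(lapse = 0) {
  observer_model(threshold = 30, slope = 2, guess = 0.5, lapse = lapse,
                 direction = "decreasing", unit = "Hz")
}

cff_config <- function(start_level = 25, ...) {
  staircase_config(start_level = start_level, step_size = 2, floor_level = 5,
                   ceiling_level = 60, harder = "up", unit = "Hz", ...)
}

# responder that replays a fixed correctness sequence, ignoring the level
scripted_responder <- function(responses) {
  i <- 0L
  function(level) {
    i <<- i + 1L
    responses[i]
  }
}

# Independent oracle for the 3-down-1-up rule: a plain loop over a scripted
# response vector, written without reference to the package internals.
# Returns the presented levels and the reversal levels.
oracle_staircase <- function(responses, start, step, harder_sign,
                             n_stop = 8, lo = -Inf, hi = Inf) {
  level <- start
  run_correct <- 0
  dir_prev <- 0
  levels <- c()
  revs <- c()
  for (resp in responses) {
    levels <- c(levels, level)
    step_dir <- 0
    if (resp) {
      run_correct <- run_correct + 1
      if (run_correct == 3) {
        step_dir <- harder_sign
        run_correct <- 0
      }
    } else {
      run_correct <- 0
      step_dir <- -harder_sign
    }
    if (step_dir != 0) {
      if (dir_prev != 0 && step_dir != dir_prev) revs <- c(revs, level)
      dir_prev <- step_dir
      level <- max(lo, min(hi, level + step_dir * step))
    }
    if (length(revs) >= n_stop) break
  }
  list(levels = levels, reversals = revs)
}

quiet_fit <- function(...) suppressWarnings(fit_psychometric(...))

# small processed epoch built directly from a sum of sinusoids (4 s @ 1 kHz)
tone_epoch <- function(freqs, amps, phases = 0, fs = 1000, dur = 4,
                       stim_freq = 15, condition = "AE") {
  t <- (seq_len(fs * dur) - 1) / fs
  phases <- rep_len(phases, length(freqs))
  x <- numeric(length(t))
  for (i in seq_along(freqs)) {
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
  }
  structure(list(samples = x, sampling_rate = fs, stim_freq = stim_freq,
                 condition = condition),
            class = "processed_epoch")
}
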