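# Study protocol configuration: one validated list drives the whole
# synthetic study (group sizes, task battery, staircase and training
# geometry, ssVEP block, learning schedule, and the generating population).

.protocol_schema <- list(
  seed = NULL,
  groups = c("amblyopic", "normal"),
  tasks = NULL,
  staircase = c("step_size", "n_reversals_stop", "n_reversals_avg", "rule_up",
                "n_repetitions", "start_offset", "floor_level",
                "ceiling_level", "max_trials"),
  constant_stimuli = c("n_levels", "reps", "half_range", "criterion"),
  stereo = c("step_px", "start_px", "floor_px", "ceiling_px",
             "arcsec_per_pixel", "n_repetitions", "max_trials"),
  ssvep = c("stim_freq", "epoch_duration", "sampling_rate", "n_epochs",
            "noise_sd", "noise_exponent", "gap_duration"),
  learning = c("n_sessions", "eye_scope"),
  measurement = c("cff_slope", "stereo_slope", "lapse", "va_noise",
                  "randot_noise"),
  population = c("amblyopic", "normal"),
  output_dir = NULL
)

.pop_block_keys <- c("cff", "training", "stereo", "va", "vep")

#' Default study protocol
#'
#' The default protocol encodes the study conditions the package emulates:
#' two groups of six subjects (amblyopic and normally sighted), a battery of
#' monocular/binocular CFF staircases (2 Hz steps, 8 reversals, threshold =
#' mean of the last 6, two repetitions), five constant-stimuli training
#' sessions (11 levels over threshold +/- 5 Hz, 20 repetitions per level,
#' 80% criterion), pixel-quantized disparity staircases (55 arcsec per
#' pixel), and 15 Hz / 5 s / 1 kHz ssVEP blocks.  The `population` block
#' holds the generating group means ([reference_group_means()]) with
#' between-subject spreads.
#'
#' @param seed Study-level seed recorded in the config.
#' @return A validated list of class `protocol_config`.
#' @seealso [validate_protocol()], [simulate_study()]
#' @export
default_protocol <- function(seed = 1) {
  p <- list(
    seed = as.integer(seed),
    groups = list(amblyopic = 6L, normal = 6L),
    tasks = c("cff_staircase", "training", "stereo", "va", "ssvep"),
    staircase = list(step_size = 2, n_reversals_stop = 8, n_reversals_avg = 6,
                     rule_up = 3, n_repetitions = 2, start_offset = -5,
                     floor_level = 5, ceiling_level = 60, max_trials = 200),
    constant_stimuli = list(n_levels = 11, reps = 20, half_range = 5,
                            criterion = 0.8),
    stereo = list(step_px = 1, start_px = 16, floor_px = 1, ceiling_px = 40,
                  arcsec_per_pixel = 55, n_repetitions = 1, max_trials = 200),
    ssvep = list(stim_freq = 15, epoch_duration = 5, sampling_rate = 1000,
                 n_epochs = 8, noise_sd = 9, noise_exponent = 1,
                 gap_duration = 0.5),
    learning = list(n_sessions = 5, eye_scope = "trained"),
    measurement = list(cff_slope = 2, stereo_slope = 80, lapse = 0.02,
                       va_noise = 0.02, randot_noise = 15),
    population = list(
      amblyopic = list(
        cff = list(pre = c(AE = 27.3, FE = 30.1),
                   post = c(AE = 30.6, FE = 31.7),
                   sd = 3.4, jitter = 1),
        training = list(pre = 22.8, post = 26.7, sd = 3.4),
        stereo = list(pre = c(flicker = 618.4, static = 409.3, randot = 280),
                      post = c(flicker = 533.6, static = 348.04, randot = 137),
                      sd = 150, jitter = 40),
        va = list(pre = c(AE = 0.38, FE = 0.02, OU = -0.01),
                  post = c(AE = 0.26, FE = -0.03, OU = -0.05),
                  sd = 0.08, jitter = 0.02),
        vep = list(amplitude_pre = c(AE = 2.63, FE = 3.4, OU = 2.8),
                   amplitude_post = c(AE = 3.54, FE = 3.8, OU = 3.6),
                   amplitude_sd = 0.4, amplitude_jitter = 0.2,
                   delay_pre = 8.8, delay_post = 3.0,
                   delay_sd = 2.2, delay_jitter = 1)
      ),
      normal = list(
        cff = list(pre = c(NDE = 31.41, DE = 31.41),
                   post = c(NDE = 33.02, DE = 32.0),
                   sd = 2.5, jitter = 1),
        training = list(pre = 30.34, post = 30.7, sd = 0.5 * sqrt(6)),
        stereo = list(pre = c(flicker = 200, static = 100, randot = 40),
                      post = c(flicker = 165, static = 86, randot = 37),
                      sd = 40, jitter = 15),
        va = list(pre = c(NDE = -0.07, DE = -0.07, OU = -0.10),
                  post = c(NDE = -0.10, DE = -0.08, OU = -0.12),
                  sd = 0.03, jitter = 0.02),
        vep = list(amplitude_pre = c(NDE = 3.17, DE = 3.12, OU = 4.01),
                   amplitude_post = c(NDE = 3.5, DE = 3.45, OU = 4.03),
                   amplitude_sd = 0.4, amplitude_jitter = 0.2,
                   delay_pre = 2.6, delay_post = 2.6,
                   delay_sd = 2.0, delay_jitter = 1)
      )
    ),
    output_dir = NULL
  )
  validate_protocol(p)
}

#' Validate a protocol configuration
#'
#' Checks the configuration against the fixed schema, rejecting unknown
#' keys and inconsistent values with an error that lists every offending
#' field.
#'
#' @param p A protocol list (e.g. parsed from JSON).
#' @return The validated list, classed `protocol_config`.
#' @export
validate_protocol <- function(p) {
  stopifnot(is.list(p))
  problems <- character(0)
  unknown <- setdiff(names(p), names(.protocol_schema))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown field(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  for (blk in c("staircase", "constant_stimuli", "stereo", "ssvep",
                "learning", "measurement")) {
    if (!is.null(p[[blk]])) {
      bad <- setdiff(names(p[[blk]]), .protocol_schema[[blk]])
      if (length(bad)) {
        problems <- c(problems, paste0(blk, ": unknown key(s) ",
                                       paste(bad, collapse = ", ")))
      }
    }
  }
  if (!is.null(p$groups)) {
    bad <- setdiff(names(p$groups), .protocol_schema$groups)
    if (length(bad)) {
      problems <- c(problems, paste0("groups: unknown group(s) ",
                                     paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(p$population)) {
    for (g in names(p$population)) {
      bad <- setdiff(names(p$population[[g]]), .pop_block_keys)
      if (length(bad)) {
        problems <- c(problems, paste0("population$", g, ": unknown key(s) ",
                                       paste(bad, collapse = ", ")))
      }
    }
  }
  known_tasks <- c("cff_staircase", "training", "stereo", "va", "ssvep")
  if (!is.null(p$tasks) && length(setdiff(p$tasks, known_tasks))) {
    problems <- c(problems, paste0("tasks: unknown task(s) ",
                                   paste(setdiff(p$tasks, known_tasks),
                                         collapse = ", ")))
  }
  sc <- p$staircase
  if (!is.null(sc) && !is.null(sc$n_reversals_avg) &&
      sc$n_reversals_avg > sc$n_reversals_stop) {
    problems <- c(problems, "staircase: n_reversals_avg > n_reversals_stop")
  }
  ss <- p$ssvep
  if (!is.null(ss)) {
    n <- ss$sampling_rate * ss$epoch_duration
    if (abs(n - round(n)) > 1e-9) {
      problems <- c(problems,
                    "ssvep: sampling_rate * epoch_duration is not an integer")
    }
    if (ss$stim_freq >= ss$sampling_rate / 2) {
      problems <- c(problems, "ssvep: stim_freq at or above Nyquist")
    }
  }
  if (length(problems)) {
    stop("invalid protocol config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(p) <- "protocol_config"
  p
}

#' Read a protocol configuration from JSON
#'
#' @param path Path to a JSON file with the [default_protocol()] structure.
#' @return A validated `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (g in names(p$population)) {
    for (blk in names(p$population[[g]])) {
      p$population[[g]][[blk]] <- lapply(p$population[[g]][[blk]], unlist)
    }
  }
  p$groups <- lapply(p$groups, as.integer)
  validate_protocol(p)
}

#' Write a resolved protocol configuration as JSON
#'
#' Named numeric vectors (per-eye means and the like) are written as JSON
#' objects so their names survive the round trip.
#'
#' @param p A `protocol_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protocol_config <- function(p, path) {
  named_to_list <- function(x) {
    if (is.list(x)) lapply(x, named_to_list)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(named_to_list(unclass(p)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
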