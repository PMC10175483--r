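# End-to-end synthetic subjects: draw per-subject ground truth from the
# protocol's population block, then push it through the same measurement
# machinery a real study would use (staircases, training sessions with
# psychometric fits, disparity staircases, ssVEP synthesis + analysis).

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw one subject's ground truth from the population block
#'
#' A per-subject offset (shared between pre and post, so individual
#' differences persist across phases) is added to the group means; post
#' values get an extra independent jitter so training effects vary across
#' subjects.
#'
#' @param subject_id Subject identifier.
#' @param group `"amblyopic"` or `"normal"`.
#' @param protocol A `protocol_config`.
#' @param rng An [rng_stream()].
#' @return A list of class `subject_truth`.
#' @export
simulate_subject_truth <- function(subject_id, group, protocol, rng) {
  pop <- protocol$population[[group]]
  if (is.null(pop)) stop("no population block for group ", group)
  app <- protocol$stereo$arcsec_per_pixel
  norm <- function(n, sd) with_rng(rng, stats::rnorm(n, 0, sd))

  eyes <- names(pop$cff$pre)
  e_cff <- norm(1, pop$cff$sd)
  cff_pre <- pop$cff$pre + e_cff
  cff_post <- pop$cff$post + e_cff + norm(length(eyes), pop$cff$jitter)
  names(cff_post) <- eyes

  e_tr <- norm(1, pop$training$sd)
  tr_pre <- max(pop$training$pre + e_tr, protocol$constant_stimuli$half_range + 2)
  tr_post <- max(pop$training$post + e_tr, tr_pre * 0.8)

  e_st <- norm(1, pop$stereo$sd)
  st_pre <- .clip(pop$stereo$pre + e_st, 2 * app, Inf)
  st_post <- .clip(pop$stereo$post + e_st + norm(length(pop$stereo$post),
                                                 pop$stereo$jitter),
                   2 * app, Inf)
  names(st_post) <- names(pop$stereo$post)

  e_va <- norm(length(pop$va$pre), pop$va$sd)
  va_pre <- pop$va$pre + e_va
  va_post <- pop$va$post + e_va + norm(length(pop$va$pre), pop$va$jitter)
  names(va_post) <- names(pop$va$pre)

  e_amp <- norm(1, pop$vep$amplitude_sd)
  amp_pre <- .clip(pop$vep$amplitude_pre + e_amp, 0.3, Inf)
  amp_post <- .clip(pop$vep$amplitude_post + e_amp +
                      norm(length(pop$vep$amplitude_post),
                           pop$vep$amplitude_jitter), 0.3, Inf)
  names(amp_post) <- names(pop$vep$amplitude_pre)

  e_d <- norm(1, pop$vep$delay_sd)
  delay_pre <- .clip(pop$vep$delay_pre + e_d, 0.2, 30)
  delay_post <- .clip(pop$vep$delay_post + e_d + norm(1, pop$vep$delay_jitter),
                      0.2, 30)

  structure(
    list(subject = subject_id, group = group, eyes = eyes,
         trained_eye = eyes[1],
         cff = list(pre = cff_pre, post = cff_post),
         training = list(pre = tr_pre, post = tr_post),
         stereo = list(pre = st_pre, post = st_post),
         va = list(pre = va_pre, post = va_post),
         vep_amplitude = list(pre = amp_pre, post = amp_post),
         vep_delay = list(pre = delay_pre, post = delay_post)),
    class = "subject_truth"
  )
}

.measure_rows <- function(truth, measure, condition, phase, value, unit) {
  data.frame(subject = truth$subject, group = truth$group, measure = measure,
             condition = condition, phase = phase, value = value, unit = unit,
             stringsAsFactors = FALSE)
}

.log_rows <- function(truth, session, task, condition, trials, unit, track_id,
                      seed) {
  if (!nrow(trials)) return(NULL)
  data.frame(subject = truth$subject, session = session, task = task,
             condition = condition, trial_index = seq_len(nrow(trials)),
             level = trials$level, unit = unit,
             response_correct = trials$correct, track_id = track_id,
             seed = seed, stringsAsFactors = FALSE)
}

#' Simulate one subject's complete pre/post dataset
#'
#' Runs every task enabled in the protocol against the subject's ground
#' truth, with the same machinery the analysis stage expects: interleaved
#' repeated CFF staircases per eye condition (binocular condition by
#' probability summation), the five-session constant-stimuli training
#' course, pixel-quantized disparity staircases for the flickering and
#' static stereo tests (plus a direct noisy graded-circles measure), acuity
#' as a direct noisy measure, and synthesized ssVEP recordings pushed
#' through the spectral analysis pipeline.
#'
#' @param truth A [simulate_subject_truth()] result.
#' @param protocol A `protocol_config`.
#' @param rng An [rng_stream()].
#' @param keep_recordings Keep the synthesized [eeg_recording()]s in the
#'   result (default FALSE; they are large).
#' @details
#' Measurement randomness uses common random numbers across phases: each
#' task draws from a stream seeded from the subject seed and the task name
#' only, so the pre- and post-training measurements of a task replay the
#' same draw sequence.  Pre/post differences therefore reflect the true
#' change (plus the population jitter), not independent measurement noise
#' twice over, and a zero-gain, zero-jitter configuration reproduces its
#' pre measures exactly at post.
#' @return A list of class `subject_dataset`: `measures` (long data.frame),
#'   `logs` (trial-log data.frame), `training` (the `training_course` or
#'   NULL), `recordings`, and the embedded `truth`.
#' @export
simulate_subject_dataset <- function(truth, protocol, rng,
                                     keep_recordings = FALSE) {
  stopifnot(inherits(truth, "subject_truth"))
  m <- protocol$measurement
  eyes <- truth$eyes
  conds <- c(eyes, "OU")
  seed <- rng$seed
  # one seed per task, shared between phases (common random numbers)
  task_stream <- function(task) rng_stream(child_rng(rng, task)$seed)
  measures <- NULL
  logs <- NULL
  training <- NULL
  recordings <- list()

  make_cff_obs <- function(phase) {
    obs <- lapply(eyes, function(e)
      observer_model(truth$cff[[phase]][[e]], m$cff_slope, 0.5, m$lapse,
                     "decreasing", "Hz"))
    names(obs) <- eyes
    obs$OU <- binocular_observer(obs[[1]], obs[[2]])
    obs
  }

  if ("cff_staircase" %in% protocol$tasks) {
    sc <- protocol$staircase
    assumed <- c(protocol$population[[truth$group]]$cff$pre,
                 OU = max(protocol$population[[truth$group]]$cff$pre))
    cfgs <- lapply(conds, function(cn)
      staircase_config(start_level = assumed[[cn]] + sc$start_offset,
                       step_size = sc$step_size,
                       n_reversals_stop = sc$n_reversals_stop,
                       n_reversals_avg = sc$n_reversals_avg,
                       rule_up = sc$rule_up, harder = "up",
                       floor_level = sc$floor_level,
                       ceiling_level = sc$ceiling_level,
                       max_trials = sc$max_trials, unit = "Hz"))
    names(cfgs) <- conds
    for (phase in c("pre", "post")) {
      r_task <- task_stream("cff_staircase")
      obs <- make_cff_obs(phase)
      th_reps <- matrix(NA_real_, sc$n_repetitions, length(conds),
                        dimnames = list(NULL, conds))
      for (r in seq_len(sc$n_repetitions)) {
        runs <- run_interleaved_staircases(obs, cfgs, r_task)
        for (cn in conds) {
          th_reps[r, cn] <- runs[[cn]]$threshold
          logs <- rbind(logs, .log_rows(
            truth, 0L, "cff_staircase", cn, runs[[cn]]$trials, "Hz",
            paste0("cff_", phase, "_rep", r, "_", cn), seed))
        }
      }
      measures <- rbind(measures, .measure_rows(
        truth, "cff_staircase", conds, phase, colMeans(th_reps), "Hz"))
    }
  }

  if ("training" %in% protocol$tasks) {
    cs <- protocol$constant_stimuli
    n_se <- protocol$learning$n_sessions
    gain <- if (n_se > 1) {
      (truth$training$post / truth$training$pre)^(1 / (n_se - 1)) - 1
    } else 0
    obs1 <- observer_model(truth$training$pre, m$cff_slope, 0.5, m$lapse,
                           "decreasing", "Hz")
    schedule <- learning_schedule(n_se, gain, protocol$learning$eye_scope)
    training <- run_training_course(obs1, schedule, task_stream("training"),
                                    baseline_threshold = truth$training$pre,
                                    n_levels = cs$n_levels, reps = cs$reps,
                                    half_range = cs$half_range,
                                    criterion = cs$criterion)
    measures <- rbind(measures, .measure_rows(
      truth, "cff_training", truth$trained_eye, c("pre", "post"),
      c(training$sessions$threshold[1], training$sessions$threshold[n_se]),
      "Hz"))
    for (s in seq_len(n_se)) {
      lg <- training$logs[[s]]
      logs <- rbind(logs, .log_rows(
        truth, s, "training", truth$trained_eye,
        data.frame(level = lg$level, correct = lg$correct), "Hz",
        paste0("train_s", s), seed))
    }
  }

  if ("stereo" %in% protocol$tasks) {
    st <- protocol$stereo
    cfg <- staircase_config(start_level = st$start_px, step_size = st$step_px,
                            n_reversals_stop = protocol$staircase$n_reversals_stop,
                            n_reversals_avg = protocol$staircase$n_reversals_avg,
                            rule_up = protocol$staircase$rule_up,
                            harder = "down", floor_level = st$floor_px,
                            ceiling_level = st$ceiling_px,
                            n_repetitions = st$n_repetitions,
                            max_trials = st$max_trials, unit = "px")
    for (phase in c("pre", "post")) {
      r_task <- task_stream("stereo")
      for (test in c("flicker", "static")) {
        obs <- observer_model(truth$stereo[[phase]][[test]], m$stereo_slope,
                              0.5, m$lapse, "increasing", "arcsec")
        res <- run_disparity_staircase(obs, cfg, r_task,
                                       arcsec_per_pixel = st$arcsec_per_pixel)
        measures <- rbind(measures, .measure_rows(
          truth, paste0("stereo_", test), "OU", phase, res$threshold,
          "arcsec"))
        for (r in seq_along(res$runs)) {
          logs <- rbind(logs, .log_rows(
            truth, 0L, paste0("stereo_", test), "OU", res$runs[[r]]$trials,
            "px", paste0("stereo_", test, "_", phase, "_rep", r), seed))
        }
      }
      randot <- .clip(truth$stereo[[phase]][["randot"]] +
                        with_rng(r_task, stats::rnorm(1, 0, m$randot_noise)),
                      20, 400)
      measures <- rbind(measures, .measure_rows(
        truth, "stereo_randot", "OU", phase, randot, "arcsec"))
    }
  }

  if ("va" %in% protocol$tasks) {
    for (phase in c("pre", "post")) {
      r_task <- task_stream("va")
      v <- truth$va[[phase]] +
        with_rng(r_task, stats::rnorm(length(truth$va[[phase]]), 0,
                                      m$va_noise))
      measures <- rbind(measures, .measure_rows(
        truth, "va", names(truth$va$pre), phase, unname(v), "logMAR"))
    }
  }

  if ("ssvep" %in% protocol$tasks) {
    sv <- protocol$ssvep
    for (phase in c("pre", "post")) {
      r_task <- task_stream("ssvep")
      amp <- truth$vep_amplitude[[phase]]
      # the delayed response belongs to the trained (amblyopic/non-dominant)
      # eye, which is eyes[1]; synthesize_ssvep delays its second recording
      params <- ssvep_params(stim_freq = sv$stim_freq,
                             amplitude = amp[[eyes[2]]],
                             epoch_duration = sv$epoch_duration,
                             sampling_rate = sv$sampling_rate,
                             n_epochs = sv$n_epochs,
                             interocular_delay = truth$vep_delay[[phase]],
                             noise_sd = sv$noise_sd,
                             noise_exponent = sv$noise_exponent)
      pair <- synthesize_ssvep(params, r_task, conditions = rev(eyes),
                               gap_duration = sv$gap_duration,
                               amplitude_b = amp[[eyes[1]]])
      res <- analyze_ssvep_pair(pair, stim_freq = sv$stim_freq)
      params_ou <- ssvep_params(stim_freq = sv$stim_freq,
                                amplitude = amp[["OU"]],
                                epoch_duration = sv$epoch_duration,
                                sampling_rate = sv$sampling_rate,
                                n_epochs = sv$n_epochs,
                                interocular_delay = 0,
                                noise_sd = sv$noise_sd,
                                noise_exponent = sv$noise_exponent)
      ou <- synthesize_ssvep(params_ou, r_task,
                             conditions = c("OU", "OU"),
                             gap_duration = sv$gap_duration)$a
      ou_avg <- average_epochs(lapply(segment_epochs(ou), preprocess_epoch,
                                      stim_freq = sv$stim_freq))
      ord <- match(eyes, res$measures$condition)
      amp_meas <- c(res$measures$amplitude_uV[ord],
                    as.numeric(ssvep_amplitude(ou_avg)))
      snr_meas <- c(res$measures$snr[ord],
                    as.numeric(suppressWarnings(ssvep_snr(ou_avg))))
      measures <- rbind(measures,
        .measure_rows(truth, "vep_amplitude", conds, phase, amp_meas, "uV"),
        .measure_rows(truth, "vep_snr", conds, phase, snr_meas, "ratio"),
        .measure_rows(truth, "vep_delay", "interocular", phase,
                      res$delay$delay_ms, "ms"))
      if (keep_recordings) {
        recordings[[phase]] <- list(a = pair$a, b = pair$b, ou = ou,
                                    ground_truth = pair$ground_truth)
      }
    }
  }

  rownames(measures) <- NULL
  if (!is.null(logs)) rownames(logs) <- NULL
  structure(
    list(subject = truth$subject, group = truth$group, measures = measures,
         logs = logs, training = training, recordings = recordings,
         truth = truth),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("Subject dataset %s (%s): %d measures, %d logged trials\n",
              x$subject, x$group,
              if (is.null(x$measures)) 0L else nrow(x$measures),
              if (is.null(x$logs)) 0L else nrow(x$logs)))
  invisible(x)
}

#' Simulate a complete two-group study
#'
#' Draws every subject's ground truth and dataset.  Each subject gets a
#' deterministic child stream of the study seed, so any subject can be
#' re-simulated independently.
#'
#' @param protocol A `protocol_config` (default [default_protocol()]).
#' @param rng An [rng_stream()]; defaults to one seeded from
#'   `protocol$seed`.
#' @param keep_recordings Passed to [simulate_subject_dataset()].
#' @return A list of class `study_simulation`: `measures` and `logs`
#'   pooled across subjects, the per-subject `datasets`, `truths`, and the
#'   resolved `protocol`.
#' @export
simulate_study <- function(protocol = default_protocol(), rng = NULL,
                           keep_recordings = FALSE) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (is.null(rng)) rng <- rng_stream(protocol$seed)
  datasets <- list()
  for (group in names(protocol$groups)) {
    for (i in seq_len(protocol$groups[[group]])) {
      sid <- sprintf("%s_%02d", substr(group, 1, 1), i)
      r_subj <- child_rng(rng, paste0(group, "_", i))
      truth <- simulate_subject_truth(sid, group, protocol, r_subj)
      datasets[[sid]] <- simulate_subject_dataset(truth, protocol, r_subj,
                                                  keep_recordings)
    }
  }
  measures <- do.call(rbind, lapply(datasets, `[[`, "measures"))
  logs <- do.call(rbind, lapply(datasets, `[[`, "logs"))
  rownames(measures) <- rownames(logs) <- NULL
  structure(
    list(measures = measures, logs = logs, datasets = datasets,
         truths = lapply(datasets, `[[`, "truth"), protocol = protocol),
    class = "study_simulation"
  )
}

#' @export
print.study_simulation <- function(x, ...) {
  cat(sprintf("Synthetic study: %d subjects, %d measures, %d logged trials\n",
              length(x$datasets), nrow(x$measures),
              if (is.null(x$logs)) 0L else nrow(x$logs)))
  invisible(x)
}
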