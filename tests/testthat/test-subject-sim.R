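# scaled-down protocol used where full study conditions are not the point
small_protocol <- function(seed = 1, tasks = c("cff_staircase", "stereo",
                                               "va", "ssvep")) {
  p <- default_protocol(seed)
  p$groups <- list(amblyopic = 1L, normal = 1L)
  p$tasks <- tasks
  p$ssvep$n_epochs <- 2
  p$staircase$n_repetitions <- 1
  validate_protocol(unclass(p))
}

# zero-gain, zero-jitter variant: post truths pinned to pre truths.  With
# the common-random-number design each task replays the same draws in both
# phases, so identical truths must reproduce identical measures.
frozen_protocol <- function(seed = 1) {
  p <- small_protocol(seed)
  p$measurement$va_noise <- 0
  p$measurement$randot_noise <- 0
  p$ssvep$noise_sd <- 0
  for (g in names(p$population)) {
    pop <- p$population[[g]]
    pop$cff$post <- pop$cff$pre; pop$cff$jitter <- 0
    pop$training$post <- pop$training$pre
    pop$stereo$post <- pop$stereo$pre; pop$stereo$jitter <- 0
    pop$va$post <- pop$va$pre; pop$va$jitter <- 0
    pop$vep$amplitude_post <- pop$vep$amplitude_pre
    pop$vep$amplitude_jitter <- 0
    pop$vep$delay_post <- pop$vep$delay_pre; pop$vep$delay_jitter <- 0
    p$population[[g]] <- pop
  }
  validate_protocol(unclass(p))
}

test_that("zero gain and zero noise leave every measure unchanged", {
  p <- frozen_protocol()
  r <- rng_stream(21)
  truth <- simulate_subject_truth("a_01", "amblyopic", p, r)
  ds <- simulate_subject_dataset(truth, p, r)
  m <- ds$measures
  for (key in unique(paste(m$measure, m$condition))) {
    pre <- m$value[paste(m$measure, m$condition) == key & m$phase == "pre"]
    post <- m$value[paste(m$measure, m$condition) == key & m$phase == "post"]
    expect_equal(post, pre, tolerance = 1e-9,
                 label = paste("post", key), expected.label = paste("pre", key))
  }
})

test_that("fixed seeds reproduce trial logs byte-for-byte", {
  p <- small_protocol(seed = 7, tasks = c("cff_staircase", "va"))
  s1 <- simulate_study(p)
  s2 <- simulate_study(p)
  expect_identical(s1$logs, s2$logs)
  expect_identical(s1$measures, s2$measures)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(s1$logs, f1)
  write_trial_log(s2$logs, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the draws
  s3 <- simulate_study(small_protocol(seed = 8,
                                      tasks = c("cff_staircase", "va")))
  expect_false(identical(s1$measures$value, s3$measures$value))
})

test_that("six simulated amblyopes recover the programmed training gain", {
  p <- default_protocol(seed = 11)
  p$groups <- list(amblyopic = 6L)
  p$tasks <- "training"
  p <- validate_protocol(unclass(p))
  sim <- suppressWarnings(simulate_study(p))
  m <- sim$measures[sim$measures$measure == "cff_training", ]
  pre <- m$value[m$phase == "pre"]
  post <- m$value[m$phase == "post"]
  gain <- mean(percent_change(pre, post))
  # programmed group ramp is 22.8 -> 26.7 Hz, i.e. ~17%
  expect_lt(abs(gain - percent_change(22.8, 26.7)), 5)
})

test_that("subject datasets embed their ground truth for recovery checks", {
  p <- small_protocol(seed = 3)
  r <- rng_stream(33)
  truth <- simulate_subject_truth("n_01", "normal", p, r)
  expect_equal(truth$eyes, c("NDE", "DE"))
  ds <- simulate_subject_dataset(truth, p, r)
  expect_identical(ds$truth, truth)
  # measured staircase CFF sits near the truth's 79.4% point
  obs <- observer_model(truth$cff$pre[["NDE"]], p$measurement$cff_slope,
                        lapse = p$measurement$lapse)
  anchor <- threshold_at_criterion(obs, 0.5^(1/3))
  got <- ds$measures$value[ds$measures$measure == "cff_staircase" &
                           ds$measures$condition == "NDE" &
                           ds$measures$phase == "pre"]
  expect_lt(abs(got - anchor), 4)
  # delay measurement near the injected truth
  d <- ds$measures$value[ds$measures$measure == "vep_delay" &
                         ds$measures$phase == "pre"]
  expect_lt(abs(d - truth$vep_delay$pre), 3)
})

test_that("the cli pipeline is deterministic and report-shaped", {
  p <- small_protocol(seed = 5)
  cfg <- withr::local_tempfile(fileext = ".json")
  write_protocol_config(p, cfg)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--config", cfg, "--seed", "7",
               "--out", out1))), 0L)
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--config", cfg, "--seed", "7",
               "--out", out2))), 0L)
  expect_identical(readLines(file.path(out1, "trial_logs.csv")),
                   readLines(file.path(out2, "trial_logs.csv")))
  expect_identical(readLines(file.path(out1, "measures.csv")),
                   readLines(file.path(out2, "measures.csv")))
  eeg1 <- list.files(file.path(out1, "eeg"))
  expect_identical(eeg1, list.files(file.path(out2, "eeg")))
  expect_gt(length(eeg1), 0)
  # resolved config is written beside the outputs
  expect_true(file.exists(file.path(out1, "config.json")))

  # staircase replay reproduces the simulated thresholds
  th_file <- file.path(out1, "staircase.csv")
  expect_equal(suppressMessages(
    cli_main(c("staircase", "--config", cfg, "--in", out1,
               "--out", th_file))), 0L)
  th <- read.csv(th_file)
  measures <- read.csv(file.path(out1, "measures.csv"))
  sc <- measures[measures$measure == "cff_staircase", ]
  for (i in seq_len(nrow(sc))) {
    phase <- sc$phase[i]
    rows <- th[th$subject == sc$subject[i] & th$condition == sc$condition[i] &
               grepl(paste0("_", phase, "_"), th$track_id), ]
    expect_equal(mean(rows$threshold), sc$value[i], tolerance = 1e-9)
  }

  # ssvep stage recomputes measures from the EEG files on disk
  sv_file <- file.path(out1, "ssvep.csv")
  expect_equal(suppressMessages(
    cli_main(c("ssvep", "--config", cfg, "--in", out1,
               "--out", sv_file))), 0L)
  sv <- read.csv(sv_file)
  amp <- measures[measures$measure == "vep_amplitude", ]
  for (i in seq_len(nrow(amp))) {
    got <- sv$amplitude_uV[sv$subject == amp$subject[i] &
                           sv$phase == amp$phase[i] &
                           sv$condition == amp$condition[i]]
    expect_equal(got, amp$value[i], tolerance = 1e-6)
  }

  # report writes a non-empty pre/post summary table
  rep_dir <- file.path(out1, "report")
  expect_equal(suppressMessages(
    cli_main(c("report", "--in", out1, "--out", rep_dir))), 0L)
  smry <- read.csv(file.path(rep_dir, "summary.csv"))
  expect_gt(nrow(smry), 0)
  expect_true(all(c("pre_mean", "post_mean", "change", "p_value") %in%
                    names(smry)))

  # a failing stage exits nonzero with a diagnostic
  expect_equal(suppressMessages(cli_main(c("report", "--in",
                                           "/nonexistent", "--out",
                                           rep_dir))), 1L)
  expect_equal(suppressMessages(cli_main("frobnicate")), 1L)
})
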