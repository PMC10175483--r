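test_that("single update steps follow the 3-down-1-up rule", {
  cfg <- cff_config()
  st <- staircase_init(cfg)
  st$level <- 28
  st$streak <- 2L
  # third consecutive correct: one step harder, counter reset
  st <- staircase_update(st, TRUE)
  expect_equal(st$level, 30)
  expect_equal(st$streak, 0L)
  expect_length(st$reversal_levels, 0)
  # moving upward, an error flips direction: step easier, reversal at 30
  st <- staircase_update(st, FALSE)
  expect_equal(st$level, 28)
  expect_equal(st$reversal_levels, 30)
  # updates after termination are rejected
  st$terminated <- TRUE
  expect_error(staircase_update(st, TRUE), "terminated")
})

test_that("engine reproduces an independent hand-simulated track", {
  # hand-checked: start 26, responses CCC CCC X CCC X X CCC
  resp <- c(T,T,T, T,T,T, F, T,T,T, F, F, T,T,T)
  hand_reversals <- c(30, 28, 30, 26)
  orc <- oracle_staircase(resp, start = 26, step = 2, harder_sign = +1,
                          n_stop = 4)
  expect_equal(orc$reversals, hand_reversals)

  cfg <- staircase_config(start_level = 26, step_size = 2,
                          n_reversals_stop = 4, n_reversals_avg = 2,
                          floor_level = 5, ceiling_level = 60, harder = "up")
  run <- run_staircase(scripted_responder(resp), cfg)
  expect_equal(run$reversal_levels, hand_reversals)
  expect_equal(run$trials$level, orc$levels)
  expect_equal(run$threshold, mean(c(30, 26)))

  # longer pseudo-random scripts agree with the oracle trial for trial
  for (seed in 1:5) {
    set.seed(seed)
    resp <- runif(300) < 0.75
    orc <- oracle_staircase(resp, 25, 2, +1, n_stop = 8, lo = 5, hi = 60)
    run <- run_staircase(scripted_responder(resp),
                         cff_config(max_trials = 300))
    expect_equal(run$reversal_levels, orc$reversals)
    expect_equal(run$trials$level, orc$levels[seq_len(nrow(run$trials))])
  }
})

test_that("threshold is exactly the mean of the last six reversals", {
  # deterministic responder: correct up to 28 Hz, wrong at 30 -> the track
  # oscillates and reversal levels alternate 30, 28
  run <- run_staircase(function(level) level < 29,
                       cff_config(start_level = 24))
  expect_equal(run$terminated_by, "reversals_met")
  expect_length(run$reversal_levels, 8)
  expect_identical(run$threshold,
                   mean(utils::tail(run$reversal_levels, 6)))
  expect_equal(run$threshold, 29)
  # all levels confined to the configured bounds
  expect_true(all(run$trials$level >= 5 & run$trials$level <= 60))
})

test_that("degenerate responders terminate invalid", {
  # an always-correct responder rides the ceiling: no reversals
  run <- run_staircase(function(level) TRUE, cff_config(max_trials = 120))
  expect_equal(run$terminated_by, "bound_hit")
  expect_length(run$reversal_levels, 0)
  expect_true(is.na(run$threshold))
  # repeated procedure propagates invalid runs with a reason
  rep_res <- run_repeated_staircase(function(level) TRUE,
                                    cff_config(max_trials = 120,
                                               n_repetitions = 2))
  expect_false(rep_res$valid)
  expect_true(is.na(rep_res$threshold))
  expect_match(rep_res$reason, "invalid repetition")
})

test_that("staircase levels never exit the configured bounds", {
  obs <- std_observer(lapse = 0.02)
  r <- rng_stream(17)
  cfg <- staircase_config(start_level = 27, step_size = 2, floor_level = 25,
                          ceiling_level = 31, harder = "up", max_trials = 150)
  for (i in 1:20) {
    run <- run_staircase(obs, cfg, r)
    expect_true(all(run$trials$level >= 25 & run$trials$level <= 31))
  }
})

test_that("staircase converges near the 79.4%-correct point", {
  obs <- std_observer(lapse = 0.02)
  target <- threshold_at_criterion(obs, 0.5^(1/3))
  r <- rng_stream(101)
  th <- replicate(1000, run_staircase(obs, cff_config(), r)$threshold)
  expect_true(all(!is.na(th)))
  expect_lt(abs(mean(th) - target), 0.5)
})

test_that("two repetitions average and reduce variance", {
  expect_equal(mean(c(28, 30)), 29)  # the averaging contract
  obs <- std_observer(lapse = 0.02)
  cfg <- cff_config(n_repetitions = 2)
  r <- rng_stream(23)
  singles <- replicate(300, run_staircase(obs, cfg, r)$threshold)
  pairs <- replicate(300, run_repeated_staircase(obs, cfg, r)$threshold)
  expect_lt(sd(pairs), sd(singles))
  # a single-repetition config returns that run's threshold unchanged
  one <- run_repeated_staircase(obs, cff_config(n_repetitions = 1), r)
  expect_equal(one$threshold, one$runs[[1]]$threshold)
})

test_that("condition interleaving is uniform and tracks advance independently", {
  expect_equal(interleave_conditions("AE", 5, rng_stream(1)),
               rep("AE", 5))
  seqs <- interleave_conditions(c("AE", "FE", "OU"), 3000, rng_stream(5))
  counts <- table(seqs)
  se <- sqrt(3000 * (1/3) * (2/3))
  expect_true(all(abs(counts - 1000) < 3 * se))

  obs <- list(AE = observer_model(27, 2, lapse = 0.02),
              FE = observer_model(30, 2, lapse = 0.02),
              OU = observer_model(31, 2, lapse = 0.02))
  runs <- run_interleaved_staircases(obs, cff_config(), rng_stream(9))
  for (nm in names(runs)) {
    expect_equal(runs[[nm]]$n_trials, nrow(runs[[nm]]$trials))
    expect_equal(runs[[nm]]$terminated_by, "reversals_met")
  }
})

test_that("disparity staircases work in pixels and report arcsec", {
  # scripted run whose last six reversal levels are 10,12,10,12,10,12 px
  resp <- c(rep(TRUE, 9), F, F, rep(c(rep(TRUE, 6), F, F), 3), rep(TRUE, 3))
  cfg <- staircase_config(start_level = 13, step_size = 1, floor_level = 1,
                          ceiling_level = 40, harder = "down",
                          n_repetitions = 1, unit = "px")
  res <- run_disparity_staircase(scripted_responder(resp), cfg)
  expect_equal(utils::tail(res$runs[[1]]$reversal_levels, 6),
               c(10, 12, 10, 12, 10, 12))
  expect_equal(res$threshold_px, 11)
  expect_equal(res$threshold, 11 * 55)

  # at zero disparity performance is chance, so the track drifts easier
  zero_obs <- observer_model(533.6, 80, direction = "increasing",
                             unit = "arcsec")
  expect_lt(abs(p_correct(zero_obs, 0) - 0.5), 0.005)

  # Monte-Carlo recovery: mean threshold within 1 pixel of the 79.4% point
  r <- rng_stream(31)
  obs <- observer_model(533.6, 80, lapse = 0.02, direction = "increasing",
                        unit = "arcsec")
  target <- threshold_at_criterion(obs, 0.5^(1/3))
  cfg <- staircase_config(start_level = 16, step_size = 1, floor_level = 1,
                          ceiling_level = 40, harder = "down",
                          n_repetitions = 1, unit = "px")
  th <- replicate(400, run_disparity_staircase(obs, cfg, r)$threshold)
  expect_lt(abs(mean(th) - target), 55)
  expect_error(
    run_disparity_staircase(obs, staircase_config(start_level = 13.5,
                                                  step_size = 1,
                                                  harder = "down"), r),
    "whole pixels")
})
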