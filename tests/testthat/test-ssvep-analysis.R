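test_that("segmentation yields one epoch per trigger and drops truncated ones", {
  fs <- 1000
  p <- ssvep_params(amplitude = 1, n_epochs = 3, noise_sd = 0.5)
  rec <- synthesize_ssvep(p, rng_stream(4))$a
  eps <- segment_epochs(rec)
  expect_length(eps, 3)
  expect_true(all(vapply(eps, function(e) length(e$samples), numeric(1)) ==
                    5 * fs))
  # round-trip: epoch k equals the generator's epoch k sample-for-sample
  s <- rec$trigger_indices[2]
  expect_identical(eps[[2]]$samples, rec$samples[s:(s + 5 * fs - 1)])
  # a trigger 2 s before the end loses its epoch
  rec2 <- rec
  rec2$trigger_indices <- c(rec$trigger_indices[1],
                            length(rec$samples) - 2 * fs)
  rec2$condition_labels <- c("AE", "AE")
  expect_warning(eps2 <- segment_epochs(rec2), "truncated")
  expect_length(eps2, 1)
})

test_that("preprocessing detrends, filters in-band, and trims one second", {
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  pure <- list(samples = 2 * sin(2 * pi * 15 * t), sampling_rate = fs)
  out <- preprocess_epoch(pure)
  expect_length(out$samples, 4 * fs)
  # passband identity: a 15 Hz sine keeps its amplitude within 1%
  expect_lt(abs(as.numeric(ssvep_amplitude(out, 15)) - 2) / 2, 0.01)
  # an added linear ramp is removed (low-frequency residual down > 20 dB)
  ramp <- list(samples = pure$samples + seq(0, 40, length.out = 5 * fs),
               sampling_rate = fs)
  out_r <- preprocess_epoch(ramp)
  slope_resid <- abs(coef(lm(out_r$samples ~ t[1:(4 * fs)]))[2])
  expect_lt(slope_resid, 8 / 10)      # raw ramp slope was 8 uV/s
  expect_lt(abs(mean(out_r$samples)), 0.01)
  expect_lt(abs(as.numeric(ssvep_amplitude(out_r, 15)) - 2) / 2, 0.015)
  expect_error(preprocess_epoch(list(samples = rnorm(1500),
                                     sampling_rate = fs)), "shorter")
  expect_error(preprocess_epoch(list(samples = rnorm(1500),
                                     sampling_rate = 100)), "200 Hz")
})

test_that("epoch averaging is linear and cancels noise as 1/sqrt(n)", {
  e1 <- tone_epoch(15, 2)
  expect_identical(average_epochs(list(e1, e1))$samples, e1$samples)
  # opposite-sign noise cancels exactly, signal intact
  noise <- rnorm(length(e1$samples))
  ep <- e1; ep$samples <- e1$samples + noise
  em <- e1; em$samples <- e1$samples - noise
  expect_equal(average_epochs(list(ep, em))$samples, e1$samples,
               tolerance = 1e-12)
  # residual noise shrinks as 1/sqrt(n)
  set.seed(60)
  resid_sd <- vapply(c(4, 16, 64), function(n) {
    eps <- lapply(seq_len(n), function(i) {
      e <- e1; e$samples <- e1$samples + rnorm(length(e1$samples)); e
    })
    sd(average_epochs(eps)$samples - e1$samples)
  }, numeric(1))
  expect_equal(resid_sd / resid_sd[1], 1 / sqrt(c(4, 16, 64) / 4),
               tolerance = 0.25)
  bad <- tone_epoch(15, 2, condition = "FE")
  expect_error(average_epochs(list(e1, bad)), "conditions")
  short <- e1; short$samples <- short$samples[1:100]
  expect_error(average_epochs(list(e1, short)), "length")
})

test_that("spectral amplitude is exact and linear on integer-cycle sinusoids", {
  expect_equal(as.numeric(ssvep_amplitude(tone_epoch(15, 2), 15)), 2,
               tolerance = 1e-9)
  # orthogonality: a pure 10 Hz tone leaves nothing in the 15 Hz bin
  expect_lt(as.numeric(ssvep_amplitude(tone_epoch(10, 2), 15)), 1e-9)
  # superposition: 3 uV @ 15 Hz + 1 uV @ 30 Hz reads 3 uV at 15 Hz
  mix <- tone_epoch(c(15, 30), c(3, 1))
  expect_equal(as.numeric(ssvep_amplitude(mix, 15)), 3, tolerance = 1e-9)
  expect_equal(as.numeric(ssvep_amplitude(mix, 30)), 1, tolerance = 1e-9)
  # linearity in amplitude
  expect_equal(as.numeric(ssvep_amplitude(tone_epoch(15, 5), 15)), 5,
               tolerance = 1e-9)
  # non-integer cycle counts are refused
  e <- tone_epoch(15, 2)
  expect_error(ssvep_amplitude(e, 15.1), "integer number of cycles")
})

test_that("SNR is the signal bin over mean neighbour amplitude", {
  # 2 uV signal over a constructed flat 0.1 uV neighbour comb -> exactly 20
  nb <- seq(13, 17, by = 0.25)
  nb <- nb[abs(nb - 15) > 0.25 + 1e-9]
  ep <- tone_epoch(c(15, nb), c(2, rep(0.1, length(nb))))
  expect_equal(as.numeric(ssvep_snr(ep, 15)), 20, tolerance = 1e-6)
  # doubling noise at fixed amplitude lowers SNR monotonically
  snrs <- vapply(c(2, 4, 8, 16, 32), function(ns) {
    p <- ssvep_params(amplitude = 2, n_epochs = 4, noise_sd = ns)
    pair <- synthesize_ssvep(p, rng_stream(77))
    eps <- lapply(segment_epochs(pair$a), preprocess_epoch)
    as.numeric(ssvep_snr(average_epochs(eps)))
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
  # pure noise: SNR distributed around 1
  vals <- vapply(1:200, function(s) {
    r <- rng_stream(9000 + s)
    e <- tone_epoch(15, 0)
    e$samples <- flickerlearn:::colored_noise(4000, 1, 1, r)
    as.numeric(ssvep_snr(e, 15))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1), 3 * sd(vals) / sqrt(200))
  # noiseless synthetic data caps with a flag
  expect_warning(capped <- ssvep_snr(tone_epoch(15, 2), 15), "capped")
  expect_true(attr(capped, "capped"))
})

test_that("cross-correlation delay is exact, antisymmetric, and noise-robust", {
  a <- tone_epoch(15, 2)
  expect_equal(interocular_delay(a, a)$delay_ms, 0)
  expect_equal(interocular_delay(a, a)$peak_correlation, 1, tolerance = 1e-9)
  # a 10-sample shift at 1 kHz reads 10 ms
  b <- tone_epoch(15, 2, phases = -2 * pi * 15 * 10 / 1000)
  est <- interocular_delay(b, a)
  expect_equal(est$delay_ms, 10, tolerance = 0.05)
  # antisymmetry under operand swap
  expect_equal(interocular_delay(a, b)$delay_ms, -est$delay_ms,
               tolerance = 1e-6)
  # sub-sample delays across the window recovered to 0.2 ms at zero noise
  for (d in c(-30, -8.8, -0.4, 3.3, 12.7, 30)) {
    bd <- tone_epoch(15, 2, phases = -2 * pi * 15 * d / 1000)
    expect_lt(abs(interocular_delay(bd, a)$delay_ms - d), 0.2)
  }
  # with noise at working SNR, recovery stays within 1 ms
  errs <- vapply(1:60, function(s) {
    r <- rng_stream(4000 + s)
    d <- 8.8
    na <- a; na$samples <- a$samples +
      flickerlearn:::colored_noise(4000, 1, 0.35, r)
    nb <- tone_epoch(15, 2, phases = -2 * pi * 15 * d / 1000)
    nb$samples <- nb$samples + flickerlearn:::colored_noise(4000, 1, 0.35, r)
    abs(interocular_delay(nb, na)$delay_ms - d)
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("the pipeline order matters: filtering precedes the 1 s trim", {
  # an onset step inside the first second bleeds into later samples if the
  # trim were applied before filtering; the fixed order confines it
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  x <- 2 * sin(2 * pi * 15 * t)
  x[1:200] <- x[1:200] + 30           # crude onset transient
  ep <- list(samples = x, sampling_rate = fs)
  standard <- preprocess_epoch(ep)
  # permuted order: trim first, then detrend + filter
  permuted <- preprocess_epoch(list(samples = x[-(1:fs)],
                                    sampling_rate = fs),
                               discard_seconds = 0)
  permuted$samples <- permuted$samples[seq_along(standard$samples)]
  expect_gt(max(abs(standard$samples - permuted$samples)), 1e-3)
})
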