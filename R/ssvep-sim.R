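#' Parameters for synthetic steady-state VEP epochs
#'
#' @param stim_freq Flicker/stimulation frequency in Hz (default 15).
#' @param amplitude Sinusoidal response amplitude in microvolts.
#' @param epoch_duration Epoch length in seconds (default 5).
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param n_epochs Number of stimulation epochs per eye.
#' @param interocular_delay Delay, in milliseconds, applied to the second
#'   eye's sinusoidal response.  Must be smaller than half the stimulus
#'   period (33.3 ms at 15 Hz), beyond which a lag search cannot identify it.
#' @param noise_sd Standard deviation of the additive noise, in microvolts.
#' @param noise_exponent Spectral slope k of the 1/f^k noise (power
#'   spectrum), default 1.
#' @param phase Sinusoid phase offset in radians.
#' @return An object of class `ssvep_params`.
#' @export
ssvep_params <- function(stim_freq = 15, amplitude = 2, epoch_duration = 5,
                         sampling_rate = 1000, n_epochs = 10,
                         interocular_delay = 0, noise_sd = 1,
                         noise_exponent = 1, phase = 0) {
  n <- sampling_rate * epoch_duration
  stopifnot(abs(n - round(n)) < 1e-9,
            stim_freq > 0, stim_freq < sampling_rate / 2,
            n_epochs >= 1, amplitude >= 0, noise_sd >= 0)
  if (abs(interocular_delay) >= 1000 / (2 * stim_freq)) {
    stop("interocular_delay must be below half the stimulus period (",
         format(1000 / (2 * stim_freq), digits = 4), " ms)")
  }
  structure(
    list(stim_freq = stim_freq, amplitude = amplitude,
         epoch_duration = epoch_duration, sampling_rate = sampling_rate,
         n_epochs = as.integer(n_epochs),
         interocular_delay = interocular_delay, noise_sd = noise_sd,
         noise_exponent = noise_exponent, phase = phase),
    class = "ssvep_params"
  )
}

#' Single-channel EEG recording container
#'
#' Holds one channel (by convention Oz referenced to Fz) at a fixed sampling
#' rate together with stimulus triggers marking epoch starts and one eye
#' condition label per trigger.
#'
#' @param samples Numeric vector of amplitudes in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param trigger_indices Strictly increasing 1-based sample indices of
#'   epoch onsets.
#' @param condition_labels Character vector, one label per trigger
#'   (e.g. `"AE"`, `"FE"`, `"OU"` or `"NDE"`, `"DE"`, `"OU"`).
#' @param epoch_duration Epoch length in seconds implied by each trigger.
#' @param channel Channel label.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, trigger_indices,
                          condition_labels, epoch_duration = 5,
                          channel = "Oz-Fz") {
  trigger_indices <- as.integer(trigger_indices)
  if (length(trigger_indices) > 1 && any(diff(trigger_indices) <= 0)) {
    stop("trigger_indices must be strictly increasing")
  }
  if (length(condition_labels) != length(trigger_indices)) {
    stop("condition_labels and trigger_indices must have equal length")
  }
  n_ep <- round(sampling_rate * epoch_duration)
  if (length(trigger_indices) &&
      any(trigger_indices < 1 | trigger_indices + n_ep - 1 > length(samples))) {
    stop("every epoch must fit inside the sample sequence")
  }
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         trigger_indices = trigger_indices,
         condition_labels = as.character(condition_labels),
         epoch_duration = epoch_duration, channel = channel),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "EEG recording [%s]: %d samples @ %g Hz, %d triggers (%s)\n",
    x$channel, length(x$samples), x$sampling_rate,
    length(x$trigger_indices),
    paste(unique(x$condition_labels), collapse = ", ")))
  invisible(x)
}

# Gaussian noise shaped to a 1/f^k power spectrum, scaled to sd `sd`.
# DC is zeroed; k = 0 reduces to white noise.
colored_noise <- function(n, exponent, sd, rng) {
  if (sd == 0) return(numeric(n))
  w <- with_rng(rng, stats::rnorm(n))
  if (exponent == 0) return(w * sd / stats::sd(w))
  spec <- stats::fft(w)
  # frequency index of each FFT bin, symmetric for the negative half
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  scale <- c(0, k[-1]^(-exponent / 2))
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Synthesize a pair of steady-state VEP recordings
#'
#' Generates one recording per eye.  Each holds `n_epochs` epochs of
#' `amplitude * sin(2 pi stim_freq t + phase)` plus 1/f^k noise; the second
#' eye's sinusoid is shifted later in time by `interocular_delay`
#' milliseconds.  Triggers mark epoch starts and epochs are separated by a
#' noise-only gap so segmentation is non-trivial.  The generating parameters
#' are retained as ground truth alongside the recordings.
#'
#' @param params An [ssvep_params()].
#' @param rng An [rng_stream()].
#' @param conditions Length-2 character vector of eye condition labels for
#'   the (reference, delayed) recordings.
#' @param gap_duration Inter-epoch gap in seconds (noise only).
#' @param amplitude_b Response amplitude of the second (delayed) eye;
#'   defaults to `params$amplitude`, allowing an interocular amplitude
#'   imbalance.
#' @return A list with elements `a` and `b` ([eeg_recording()]s; `b` carries
#'   the delayed response), and `ground_truth` (the `params`).
#' @export
synthesize_ssvep <- function(params, rng, conditions = c("AE", "FE"),
                             gap_duration = 0.5, amplitude_b = NULL) {
  stopifnot(inherits(params, "ssvep_params"), length(conditions) == 2L)
  fs <- params$sampling_rate
  n_ep <- round(fs * params$epoch_duration)
  n_gap <- round(fs * gap_duration)
  n_tot <- params$n_epochs * n_ep + (params$n_epochs + 1) * n_gap
  starts <- n_gap + (seq_len(params$n_epochs) - 1L) * (n_ep + n_gap) + 1L

  t_ep <- (seq_len(n_ep) - 1) / fs
  make_eye <- function(delay_ms, condition, amplitude) {
    sig <- amplitude *
      sin(2 * pi * params$stim_freq * (t_ep - delay_ms / 1000) + params$phase)
    x <- colored_noise(n_tot, params$noise_exponent, params$noise_sd, rng)
    for (s in starts) x[s:(s + n_ep - 1)] <- x[s:(s + n_ep - 1)] + sig
    eeg_recording(x, fs, starts, rep(condition, params$n_epochs),
                  epoch_duration = params$epoch_duration)
  }
  if (is.null(amplitude_b)) amplitude_b <- params$amplitude
  list(a = make_eye(0, conditions[1], params$amplitude),
       b = make_eye(params$interocular_delay, conditions[2], amplitude_b),
       ground_truth = c(unclass(params), amplitude_b = amplitude_b))
}
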