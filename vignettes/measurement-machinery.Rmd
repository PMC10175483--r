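---
title: "Measurement machinery for temporal perceptual learning: models, procedures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement machinery for temporal perceptual learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickerlearn)
```

## What this package models

Flicker-based perceptual-learning studies of amblyopia measure, before and
after a short training course, a battery of temporal and spatio-temporal
visual functions: the critical flicker fusion frequency (CFF) of each eye,
visual acuity, stereo thresholds under static and flickering presentation,
and steady-state visual evoked potentials (ssVEP) driven by a 15 Hz
flickering light.  `flickerlearn` implements the measurement machinery of
such a study — the adaptive staircases, the constant-stimuli training task
with sigmoid fitting, the EEG spectral analysis, and the pre/post
statistics — together with a synthetic observer and EEG generator, so that
every stage can be verified against known ground truth without human
subjects.

## The observer model

All forced-choice behaviour derives from a four-parameter psychometric
function

$$p(x) \;=\; \gamma + (1 - \gamma - \lambda)\, S(x), \qquad
S(x) = \frac{1}{1 + e^{-(\alpha - x)/\beta}},$$

with guess rate $\gamma$ (0.5 for 2AFC), lapse rate $\lambda$, midpoint
$\alpha$ and scale $\beta$.  We use a logistic core because it is the
standard choice and closed-form invertible; nothing downstream depends on
the particular sigmoid family.  Task direction is explicit: for CFF
discrimination against a fused 120 Hz reference, higher flicker frequency
is *harder*, so $S$ falls with $x$; for disparity discrimination larger
disparity is *easier*, so $S$ rises.  The binocular (OU) condition is
modelled by independent probability summation over the two monocular
channels,
$p_{OU} = \gamma + (1-\gamma-\lambda)\bigl[1 - (1-S_L)(1-S_R)\bigr]$.
This is a genuinely open design choice — binocular combination could
equally be modelled by quadratic summation — and simulated OU thresholds
should be read as "at least as good as the better eye", not as a validated
binocular model.

Learning is multiplicative: a schedule with per-session gain $g$ scales
$\alpha$ by $(1+g)^{k-1}$ at session $k$.  The default amblyopic ramp is
derived from the published group means of the training course
(22.8 Hz at session 1 rising to 26.7 Hz at session 5, i.e.
$g = (26.7/22.8)^{1/4} - 1 \approx 0.040$); the normal-control ramp is
essentially flat (30.34 to 30.7 Hz).

```{r}
obs <- observer_model(threshold = 30, slope = 2, guess = 0.5, lapse = 0.02)
p_correct(obs, c(25, 29, 30, 35))
```

## Threshold procedures

**Adaptive staircase.**  The CFF test is a transformed up-down (3-down-1-up)
staircase: three consecutive correct responses step the stimulus one fixed
step (2 Hz) in the harder direction, any error steps it easier.  This rule
converges where $p^3 = 0.5$, i.e. $p \approx 79.4\%$ correct.  A run stops
at 8 reversals and the threshold is the mean of the last 6 reversal levels;
the whole procedure is repeated twice and averaged.  Implementation
decisions where the procedure is conventionally underspecified:

* the 3:1 rule applies from the first trial (no accelerated initial phase);
* a reversal is logged at the level where the direction of level movement
  changes sign; the pre-first-movement phase has no direction and cannot
  produce a reversal;
* levels clamp at configurable floor/ceiling bounds, a 200-trial safety cap
  guarantees termination, and capped or bound-riding runs are flagged
  invalid rather than given a threshold;
* the starting level sits 5 Hz on the easy side of the assumed threshold.

With 2 Hz steps the mean estimate carries a small bias: over thousands of
simulated runs against a known observer the grand-mean threshold sits a
fraction of a step on the easy side of the exact 79.4% point, so the true
percent correct at the grand-mean threshold evaluates near 80–81% rather
than 79%.  This is a property of fixed-step up-down rules at this step
size, not an implementation error, and the convergence test asserts the
0.5 Hz band around the exact point.

**Disparity staircase.**  The stereo tests reuse the same engine with
harder = smaller disparity, levels quantized to whole pixels at 55 arcsec
per pixel, and thresholds reported in arcsec.

**Constant stimuli and sigmoid fitting.**  Each training session presents
11 equally spaced frequencies spanning the baseline threshold ±5 Hz, 20
times each in shuffled order (the level count is a package choice; range
and repetitions follow the study design).  The session threshold is read
off a maximum-likelihood logistic fit at the 80%-correct criterion of the
full performance curve (including $\gamma$ and $\lambda$), inverted in
closed form.  Fitting fixes $\gamma$ at chance, bounds
$\lambda \in [0, 0.06]$, and maximizes the binomial likelihood from a fixed
multi-start grid with bounded local refinement, so refitting identical data
is bit-for-bit deterministic; ties break toward higher likelihood, then
lower $\lambda$.  Degenerate data (all correct, all incorrect, a single
level) are rejected with guidance, and a lapse estimate pinned at its bound
warns.  Whether the criterion belongs on the fitted curve or on raw
proportions is not conventionally fixed; we use the fitted curve, which is
what "the frequency yielding 80% correct" means for a fitted sigmoid.

## ssVEP synthesis and analysis

The generator produces, per eye, `n_epochs` five-second epochs of
$A \sin(2\pi \cdot 15\,t + \varphi)$ at 1 kHz plus Gaussian noise shaped to
a $1/f^k$ power spectrum ($k = 1$ by default; the EEG noise spectrum is a
generator choice, as is the default `noise_sd = 9` µV which puts
single-condition SNRs in the mid-teens, the plausible range for this kind
of recording).  Epochs are separated by noise-only gaps and marked by
triggers; the second eye's sinusoid is shifted by the interocular delay.
Delays at or beyond half the stimulus period (33.3 ms at 15 Hz) are
rejected at construction because a lag search cannot identify them.

The analysis pipeline runs in fixed order: segment at triggers → linear
detrend → zero-phase band-pass 0.1–100 Hz → delete the first second (onset
transient) → time-locked average within condition → measure.  Order
matters: filtering before the trim lets the filter absorb the onset
transient inside the discarded second, and the test suite asserts that
permuting these stages changes the result.  The band-pass is a fourth-order
Butterworth run forward–backward; zero net phase is essential because any
phase distortion would bias the delay estimate.

**Amplitude** is the single-sided discrete-spectrum amplitude at the 15 Hz
bin of the 4-s averaged wave.  Four seconds hold exactly 60 stimulus
cycles, so the bin is exact: a pure sinusoid of amplitude $A$ returns
exactly $A$, and non-integer cycle counts are refused rather than
zero-padded.  Whether a published "VEP amplitude" is spectral or a
time-domain peak-to-trough is often ambiguous; this package implements the
spectral reading.

**SNR** is the signal-bin amplitude divided by the mean amplitude of
neighbour bins within ±2 Hz, excluding bins within ±0.25 Hz of the signal.
Published SNR values rarely state their formula; this neighbour-bin
convention is the standard one in the steady-state literature and is
flagged here prominently because other conventions (power ratios, wider
bands) scale differently.  Pure noise gives SNR ≈ 1; noiseless synthetic
data would divide by zero and instead return a capped, flagged ratio.

**Interocular delay** is the lag maximizing the normalized cross-correlation
between the two per-eye averaged waves (not per-epoch pairs), searched
within ±half a stimulus period to avoid the periodic ambiguity of a
near-sinusoidal response, and refined by parabolic interpolation around the
integer-sample peak.  Sub-sample interpolation matters: 1 kHz sampling
alone only resolves whole milliseconds, yet group means are reported to
0.1 ms.  Peaks at the window edge are flagged unreliable.  Noiseless
round-trips recover injected delays to better than 0.2 ms across the
window; at working SNR the error stays near 1 ms.

```{r}
p <- ssvep_params(amplitude = 2.63, n_epochs = 3, interocular_delay = 8.8,
                  noise_sd = 0)
pair <- synthesize_ssvep(p, rng_stream(1))
analyze_ssvep_pair(pair)$delay
```

## Statistics and reporting

Planned pre/post comparisons use the paired two-tailed t-test; group
comparisons use Welch's t; factorial questions use a two-factor
within-subject ANOVA (phase × eye condition) with per-subject error strata.
Zero-variance differences are an error, not an infinite statistic, and
degenerate ANOVA tables (zero effect or zero residual sum of squares)
report F = 0 or a capped/flagged unbounded F instead of NaN.  Because
published tables mix "mean ± SD" and "mean ± SE", every report column is
labelled and both dispersions are emitted.  Percent changes are reported
under both conventions — percent change of group means, and mean of
per-subject percent changes — because they genuinely differ on
heterogeneous baselines and only the latter matches per-subject-normalized
figures.  Planned comparisons are uncorrected by design; a Holm adjustment
is available behind a flag.  A Shapiro–Wilk p-value on the paired
differences accompanies each comparison as the numerical counterpart of the
usual quantile–quantile normality check.

The `reference_group_means()` table ships the published group-level means
that the generator's population block defaults to, and the report-stage
arithmetic on that table reproduces the headline published effects (the
~17% training gain, the 0.12 logMAR acuity change, the 85 arcsec
flickering-stereopsis gain, the ~15% pre-training CFF deficit, the 5.8 ms
delay improvement) as exact subtractions and ratios.

## The synthetic study and what it does not emulate

`simulate_study()` draws two groups of six subjects.  Each subject's ground
truth adds a persistent individual offset (shared between phases) to the
group means, plus an independent post-phase jitter controlling how much
training effects vary across subjects.  Group spreads not published
directly are set once to plausible values (e.g. normal-control stereo
baselines, between-subject delay spread from the reported standard errors)
and documented in the population block of `default_protocol()`.

Measurement randomness uses **common random numbers**: each task's stream
is seeded from the subject seed and task name only, so pre and post
measurements replay the same draw sequence.  Pre/post differences then
isolate true change plus population jitter rather than doubling up
independent measurement noise — and a zero-gain, zero-jitter protocol
reproduces its pre measures exactly at post, which the test suite exploits
as a strong end-to-end invariant.  The cost is that simulated test–retest
noise is understated; set distinct task labels per phase if independent
measurement noise is wanted.

The generator deliberately does not emulate: luminance dependence of CFF
(luminance enters only as a condition label), realistic EEG artifacts
(blinks, line noise, amplifier drift), attentional lapses beyond the
stationary lapse rate, or learning within a session.  Passing recovery
tests therefore demonstrates that the measurement machinery is unbiased
and consistent under the stated observer model — not that real amblyopic
data would satisfy the same tolerances.

## Problem sizes and numerical tolerances

The test suite and acceptance script use sizes chosen to make Monte-Carlo
assertions sharp at desk scale: 1000–2000 staircase runs for convergence
(0.5 Hz band), 2000 repetitions per level for psychometric recovery (0.1 Hz
band on $\alpha$), 200-replicate null distributions for SNR and delay
robustness, and 800–2000 replicates for type-I calibration (accepted band
3–7% at nominal 5%).  Amplitude exactness is asserted at $10^{-9}$;
noiseless delay recovery at 0.2 ms; filter passband identity at 1%.
Training-course recovery uses 25 seeded courses and asserts the mean
session-5/session-1 ratio within 2% of the programmed ramp.

## Known limitations

* The binocular summation rule and the EEG noise model are package choices,
  not validated physiology.
* The staircase estimator inherits the small fixed-step bias discussed
  above; comparisons across conditions share the bias and are unaffected.
* Welch and paired t-tests assume approximate normality of (differences
  of) measures; the summary table's Shapiro–Wilk column is a diagnostic,
  not a gate.
* The ANOVA is the classical within-subject decomposition without
  sphericity correction; with two-level factors this is moot, but
  three-level condition factors inherit the assumption.
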