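---
title: "Methods: simulating and analysing oscillatory correlates of discrete auditory representation"
author: "oscrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing oscillatory correlates of discrete auditory representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscrep)
```

## The scientific problem

A listener asked to count 4--7 white-noise bursts presented at rates
between 3 and 38 Hz can only succeed if each burst is individuated — held
as a discrete perceptual event separate from the next. If cortical
oscillations provide time-limited opportunities for representational
neuronal assemblies to form, then (i) counting accuracy across
presentation rates should track the prevalence of oscillatory activity in
auditory cortex across the same frequencies, (ii) cortical oscillations
should entrain to the burst rate over a broad frequency range, and
(iii) the oscillatory state before and during a trial should differ
between successfully and unsuccessfully counted trials.

`oscrep` implements the three corresponding analyses as a reusable
pipeline, driven by a synthetic virtual-sensor generator with known ground
truth so every stage can be validated by parameter recovery and null
calibration — no MEG recordings are required to test the machinery.

## The experimental design being emulated

Each participant completes 4 blocks of 144 trials. Within a block every
presentation rate in {3, 4, 6, 8, 10, 12, 14, 16, 18, 22, 28, 38} Hz
appears at least 8 times, the two high-prevalence rates (10 and 14 Hz) 32
times, and within every rate the four burst counts (4--7) are equally
prevalent; order is randomised per block. Over 20 participants that is
11,520 trials, with each rate seen at least 32 times per participant and
the high-prevalence rates 128 times. A fraction of trials (default 6.8%)
is flagged as rejected to emulate artifact screening. Epochs span
[-800, 800) ms around the trigger at 1,200 Hz (1,920 samples, half-open so
no boundary sample is duplicated), and every window-based measure applies
a +30 ms audio-transmission offset, i.e. the stimulus is taken to arrive
at +30 ms epoch time.

## The synthetic virtual sensor

`simulate_study()` generates, per trial,

* **1/f background**: a circular Gaussian process whose amplitude
  spectrum scales as `f^-alpha` (default `alpha = 1`, floored below 1 Hz).
  The mean Hilbert envelope then also scales as `f^-alpha` across the
  3--100 Hz analysis range; a regression of log mean envelope on log
  frequency recovers `alpha` to within 0.1. Participants vary in `alpha`
  (sd 0.05) and overall scale (log-normal sd 0.1).
* **Evoked transient**: a Hann-windowed 8 Hz sinusoid with identical
  phase on every trial, starting at stimulus onset (amplitude 1.5 times
  the background envelope at 8 Hz).
* **Induced entrainment**: a sinusoid at the presentation rate, gated by
  the burst envelope (duty cycle 0.5, rectangular: the trains are discrete
  noise bursts separated by silences, and no amplitude ramp is applied), with random phase per trial and amplitude
  `g x` the participant's background envelope at that rate. The default
  gain `g = 1.5` was calibrated once, at design time, so that the
  matched/unmatched contrast has essentially full power at the reduced
  simulation scales used in the tests; it is a free parameter of the
  generator.
* **Gamma-band success coupling**: a 71.5 Hz component spanning
  [-650, 0] ms whose phase at the -450 ms reference is drawn from a von
  Mises (kappa = 1) centred on the preferred angle for to-be-successful
  trials and on the opposite angle otherwise — an angular separation of
  pi between outcomes. Its prestimulus amplitude is reduced by 40% on
  successful trials (desynchronisation) and a poststimulus burst is
  enhanced by 40% (synchronisation), reproducing the qualitative
  amplitude pattern that accompanies the phase effect.
* **Behaviour**: P(correct) = 0.25 + 0.75 x clip(intercept + slope x
  a_norm) where `a_norm` is the participant's min-max-normalised expected
  amplitude profile at the 12 presentation rates and 0.25 is the guessing
  floor among four response options; wrong answers are uniform over the
  other three counts. The trial-level success state drawn here is what
  conditions the gamma phase above, which is how success couples to the
  prestimulus oscillatory state.

The behavioural coupling uses the *expected measured* profile: the
analytic Rice-mean envelope of background plus band-filtered evoked and
induced components, mixed over the prevalence weights of the trial mix
(`expected_profile()`). Components with random relative phase are
combined incoherently (noncentrality is the root sum of squared moduli),
an approximation that is exact for each component alone. Coupling
behaviour to this quantity, rather than to a bare `f^-alpha` curve, makes
"slope = 1" a true property of the generative model: the amplitude-
spectrum measurement is an unbiased estimate of the profile that produced
the behaviour.

Setting `entrain_gain = 0`, `behaviour$slope = 0` and the gamma coupling
to zero (`null_truth()`) produces pure null data: accuracy is 0.25 and
all downstream stages should fire only at their nominal error rates.

What the generator does *not* emulate: the acoustic waveform itself (only
its envelope drives the cortical response), sensor-level noise and
artifacts, head movement, beamformer leakage, heteroskedastic or
non-Gaussian background activity, and between-trial drift. Passing the
recovery suites therefore shows that the analysis code measures what it
claims to measure on data of known structure — not that real recordings
satisfy the model.

## Spectral decomposition

All amplitude and phase estimates come from a Hilbert filter bank:
centres 3--100 Hz in 1 Hz steps (98 bands, never silently dropped), 6 Hz
bandwidth read as centre +/- 3 Hz, with the lower edge of the 3 Hz band
clipped at 0.5 Hz to keep a valid high-pass edge. Filtering is zero-phase
Butterworth: the bank applies the squared magnitude response of an
order-3 analog Butterworth band-pass prototype — the steady-state
response of bidirectional (forward-backward) filtering — with zero phase
in the frequency domain, after 100 ms mirror padding that is trimmed
afterwards to suppress edge distortion. A `signal::filtfilt` path is
available in `bandpass()` and agrees with the spectral path away from the
epoch edges; the spectral form is the default because the digital design
of a 0.5--6 Hz band-pass at 1,200 Hz is numerically ill-conditioned and
because it vectorises across trials and bands. By construction
`amplitude * cos(phase)` reconstructs each band-passed series exactly.

Envelope time series can be decimated (pure subsampling of the analytic
signal, so amplitude and phase at the retained instants are unchanged);
the success-contrast maps default to 100 Hz (factor 12).

Windows, in epoch time with the +30 ms offset applied: the correlation
stage's active period is [80, 430) ms; the subtractive baseline (the form
chosen here; only that a baseline is applied is prescribed) is the final
350 ms before stimulus onset, [-320, 30) ms. The entrainment windows are
frequency-specific: from onset until 200 ms after the end of a
seven-burst train, limited to 800 ms; the equal-duration baseline ends
50 ms before onset. For the slowest rates the 800 ms cap would push the
active window past the epoch end and the baseline before the epoch start,
so the common duration is additionally capped to fit the epoch (770 ms),
preserving the equal-duration invariant.

## The three stages

**Correlation.** Per participant, the spectral profile is the mean raw
envelope over the active window at the band matching each presentation
rate, pooled over all usable trials (prevalence of oscillatory activity:
no baseline, no trial selection), and the behavioural profile is the
proportion correct per rate. Both are min-max normalised per participant.
Normalised accuracy is regressed on normalised amplitude with
participants partialled out as a categorical covariate: the common slope
is tested on (1, N - k - 1) df — (1, 219) for 20 participants by 12
rates — the within-subject correlation comes from the partial sums of
squares, and per-participant intercepts under the common slope are tested
against zero with a one-sample t on k - 1 df. JZS Bayes factors
(prior scale sqrt(0.5), adaptive quadrature over the g-prior in log
space, relative tolerance 1e-8) are attached to the slope and intercept
t-statistics. The intercept BF uses N = k participants. The slope's
effective N in the JZS formula is not uniquely defined for a partialled
regression; it is reported with nu set to the slope's residual df and
flagged as such. No BF is computed for the participant factor (a
multi-df F has no JZS t-equivalent).

**Entrainment.** Per participant and rate f, the matched value is the
mean baselined induced amplitude (active minus baseline window mean, at
band f, entrainment windows) across trials presented at f; the unmatched
value is the identical measurement on an equal-size random subsample of
trials from the other eleven rates — band, windows, baseline and trial
counts all match, only trial provenance differs. Chauvenet's criterion
(0.5) is applied once to participants' mean matched-unmatched
differences; survivors enter a 2 x 12 repeated-measures ANOVA
(main effect on (1, n-1) df, interaction on (11, 11(n-1))), with the main
effect's BF from t = sqrt(F). Because injected induced amplitudes scale
with the 1/f background, their absolute differences vary across rates and
the simulated interaction term is typically large; the generator makes no
attempt to calibrate interaction flatness across rates, so a flat
interaction should not be expected of it.

**Success contrast.** Successful and unsuccessful trial sets are drawn
from the pooled high-prevalence rates (10 and 14 Hz), down-sampled once
per participant to equal counts; participants with no trials in either
outcome are dropped with a warning. Four cluster analyses run on the full
3--100 Hz x [-800, 800) ms grid: amplitude with and without baseline
(paired t), the across-trial PLV difference (paired t on per-participant
PLV maps), and the circular mean phase angle (Watson's U-squared on the
participant means, which is also the unit the group-level permutations
swap). Rayleigh maps per condition test group-level phase concentration
across the 20 participant mean angles.

## Inference engines and their numerical choices

* **PLV** is the modulus of the mean unit phasor across trials; under
  uniform phases its expectation is about sqrt(pi / (4N)).
* **Rayleigh**: z = n R-bar^2 with the standard exponential
  approximation for p, capped at 1; n < 4 is flagged.
* **Watson-Williams** uses the 1 + 3/(8 kappa) correction; a weighted
  mean resultant below 0.45 or group concentration ratios above 2 raise
  assumption flags and a recommendation to switch to the nonparametric
  U-squared test instead.
* **Watson's U-squared** uses the cumulative-fraction form with tie
  weighting (identical samples give exactly 0) and a permutation null:
  within-pair label swaps when the samples are paired, pooled reshuffles
  otherwise; p = (1 + #{permuted >= observed}) / (n_permutations + 1), so
  p never reaches 0.
* **Chauvenet** excludes a value when N x P(|Z| >= |z|) under a normal
  fit falls below 0.5, applied once, non-iteratively; a zero-variance
  sample excludes nothing.
* **Cluster permutation**: per-bin statistics are thresholded (two-tailed
  t critical value at the inclusion alpha; per-bin permutation quantile
  for U-squared), connected components are formed under 8-way adjacency
  over time and frequency (4-way available), a cluster's mass is its
  summed statistic with positive and negative clusters handled
  separately, and the null is the maximum absolute cluster mass over
  sign-flip (t) or label-swap (U-squared) permutations within
  participants, with the +1 p-value correction.

One design choice deserves emphasis. The per-bin Chauvenet exclusion for
t-maps could be computed once on the observed data and reused across
permutations, which is faster. Calibration shows that choice is not
merely fast but wrong: trimming outliers from the observed statistic
while permuted statistics inherit a fixed mask inflates the family-wise
error from ~0.05 to ~0.19 (measured on 100 null studies at 500
permutations). The engine therefore recomputes the exclusion inside every
permutation; since the criterion reduces to |d - mean| > z* sd with a
constant z*, this vectorises and costs little.

## Simulation scales used by the test suite

The validation suites run at reduced but honest scales, chosen once:

* Cluster-engine FWE: 200 null studies x 500 permutations, 20
  participants, a 30 x 40 decimated grid of lightly smoothed Gaussian
  maps; the acceptance band is [0.02, 0.08] at alpha = 0.05.
* Rayleigh type-I: 10,000 uniform samples of n = 20; Watson U-squared
  type-I: 2,000 paired null samples at 199 permutations; both within
  0.05 +/- 0.015.
* Entrainment recovery: 50 studies of 20 participants x 96 trials
  (1 block, 8 repetitions per rate); detection of the main effect at
  p < 0.05 in at least 90%.
* Gamma-phase recovery: 25 studies of 20 participants x 72 trials (16
  high-prevalence repetitions); a significant prestimulus U-squared
  cluster overlapping 60--85 Hz in at least 70%.
* Correlation recovery: 50 studies of 20 participants x 576 trials (48
  repetitions per rate); slope within [0.9, 1.1] in at least 80%.

The correlation scale is the largest because min-max normalisation of
binomially noisy accuracy is biased: the observed minimum across the
near-floor rates underestimates the true minimum, inflating the range and
compressing normalised accuracy, which attenuates the recovered slope
(~0.85 at 24 trials per rate, ~0.93 at 48, ~0.98 at 96). The same
mechanism biases the mean intercept upward by a few hundredths with a
standard error that shrinks at the same rate as the bias, so the
intercept t does not converge to zero with more trials. A related
analytic fact limits what an intercept Bayes factor can certify: with 20
participants the JZS BF10 falls below 1/3 only for |t| below about 0.93,
an event with probability ~0.62 even for an exactly central t with 19 df.
A high rate of studies with intercept BF10 < 1/3 is therefore not
attainable under this (or any binomial-accuracy) generator at this
participant count, and the corresponding acceptance expectation is
expected to fail; it is retained unmodified rather than loosened, and the
slope expectation passes. On real data a single observed intercept BF in
the null-favouring range remains perfectly possible.

## Limitations

* The generator's effects are stylised (single gamma component, fixed
  evoked shape, stationary background); it validates the analysis code,
  not the physiological model.
* Watson's U-squared on participant mean angles assumes every retained
  participant contributes both conditions; alternatives operating on
  pooled trials are not implemented.
* JZS Bayes factors for the partialled slope and the participant factor
  require an effective-N convention that is not uniquely determined for
  those statistics; they are reported with explicit caveats and excluded
  from validation.
* Runtime: the full 5,000-permutation success contrast on the undecimated
  grid is supported but slow; the decimated default (100 Hz envelope) is
  the intended operating point.
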