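# oscrep

Oscillatory correlates of discrete auditory representation: a simulation
and analysis pipeline for burst-counting MEG experiments.

## The problem

When white-noise bursts are played at 3–38 Hz and a listener must count
4–7 of them, counting succeeds only while each burst is individuated as a
discrete perceptual event. If cortical oscillations provide time-limited
opportunities for representations to form, three things should be
observable in auditory-cortex activity: counting accuracy across
presentation rates should mirror the amplitude spectrum of ongoing
oscillatory activity; oscillations should entrain to the stimulation rate
over a broad frequency range; and pre-/peri-stimulus oscillatory state
should differ between successfully and unsuccessfully counted trials.

`oscrep` implements the three corresponding analyses and a synthetic
virtual-sensor generator with controllable ground truth (1/f background,
evoked transient, burst-gated induced oscillation, gamma-band
phase/amplitude states coupled to trial success, behaviour coupled to the
amplitude spectrum), so every stage is verifiable by parameter recovery
and null calibration without any recordings.

## Methods at its core

* Hilbert filter bank: zero-phase Butterworth bands, centres 3–100 Hz
  (1 Hz step, 6 Hz bandwidth), amplitude `A(t,f)` and phase `θ(t,f)` from
  the analytic signal; subtractive prestimulus baselines; the +30 ms
  audio-transmission offset on all windows.
* Within-subject ANCOVA (participants partialled out) of normalised
  accuracy on the normalised amplitude spectrum, with JZS Bayes factors
  `BF₁₀` from t-statistics under a Cauchy(0, √0.5) effect-size prior.
* Matched vs unmatched induced-amplitude contrast with equal-n
  down-sampling, Chauvenet exclusion (criterion 0.5) and a 2×12
  repeated-measures ANOVA.
* Success contrast on equal-n successful/unsuccessful high-prevalence
  trials: amplitude t-maps, phase-locking value
  `PLV(t) = |N⁻¹ Σₙ exp(i θ(t,n))|`, Rayleigh tests (`z = n R̄²`) and
  two-sample Watson's U² with a within-participant permutation null, all
  corrected by maximum-cluster-mass permutation (8-way connectivity over
  time × frequency, inclusion p < 0.05).

## Worked example

```r
library(oscrep)

truth <- ground_truth()          # defaults: 1/f background, gain 1.5, gamma coupling
study <- simulate_study(truth, n_participants = 12, n_blocks = 1,
                        base_reps = 8, high_prev_reps = 16, seed = 1)
study
#> Synthetic study: 12 participant(s), 1344 trials, 98 rejected
#>   overall accuracy 0.455 (chance 0.25); fs 1200 Hz, epoch 1920 samples

run_entrainment_stage(study)
#> Entrainment stage: matched vs unmatched induced amplitude
#>   main effect F(1,11) = 21.43, p = 0.000729, BF10 = 52.4 (mean diff 0.001897)
#>   interaction F(11,121) = 11.76, p = 1.05e-14

sc <- run_success_contrast_stage(study, n_permutations = 200, decim = 24)
sc
#> Success-contrast stage (equal-n successful vs unsuccessful trials)
#>   12 participants, mean 11.5 trials per condition
#>   amplitude_raw: 101 cluster(s), 2 significant at p <= 0.05
#>     negative mass -1251.3, 67-77 Hz, -800..-20 ms, p = 0.00498
#>     positive mass 553.3, 68-75 Hz, 20..460 ms, p = 0.0398
#>   amplitude_baselined: 105 cluster(s), 1 significant at p <= 0.05
#>     positive mass 1868.1, 68-75 Hz, -100..780 ms, p = 0.00498
#>   plv_difference: 209 cluster(s), 0 significant at p <= 0.05
#>   phase_angle: 105 cluster(s), 1 significant at p <= 0.05
#>     positive mass 94.2, 64-78 Hz, -680..20 ms, p = 0.00498
```

The entrainment F (21.43 on 1 and 11 df, Bayes factor 52) says induced
amplitude at the presented rate exceeds the identical measurement on
other-rate trials. The success-contrast clusters recover the injected
gamma-band (66–77 Hz) effects: prestimulus desynchronisation (the
negative amplitude cluster), poststimulus synchronisation (the positive
clusters), and the prestimulus phase-angle separation (the U² cluster at
64–78 Hz, −680…20 ms); at 12 participants and ~11 trials per condition
the PLV difference is not reliably detected on this draw. A
file-based pipeline (`run_pipeline()`, or `inst/cli/oscrep.R` from a
shell) runs simulate → decompose → correlate → entrain → contrast →
report with deterministic, config-hashed artifacts.

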