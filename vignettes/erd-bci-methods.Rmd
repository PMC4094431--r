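---
title: "Auto-calibrating co-adaptive ERD-based BCI training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-calibrating co-adaptive ERD-based BCI training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdbci)
```

## The problem

Motor imagery modulates the sensorimotor rhythms of the EEG: imagining a hand
movement attenuates band-limited oscillatory power (event-related
desynchronization, ERD) in the mu (9–13 Hz) and beta (16–26 Hz) bands over
the contralateral sensorimotor cortex. A brain–computer interface (BCI) can
turn this attenuation into a control signal. This package implements a fully
automatic, online variant of that idea: the system starts with no
user-specific model, collects cue-aligned trials of *left-hand imagery*,
*right-hand imagery* and a *non-control* (relax) state, calibrates itself as
soon as enough clean trials exist, and from then on re-calibrates regularly
while giving real-time feedback. A second, self-paced paradigm reuses the
last model as a brain-switch with a dwell-time activation rule.

Because the package targets closed-loop behaviour rather than a human study,
it ships a seeded synthetic user model that stands in for participants; every
paradigm can be driven end-to-end against it and evaluated with the same
statistics one would apply to recorded sessions.

## Signal model and features

EEG is processed at 256 Hz. All filtering is **causal** (online operation
forbids zero-phase filtering): a 4th-order Butterworth band-pass 0.5–100 Hz
plus a 2nd-order 50 Hz notch per electrode, then three bipolar derivations
C3 = FC3 − CP3, Cz = FCz − CPz, C4 = FC4 − CP4. Six features are computed
per sample: for each derivation and band, the signal is band-pass filtered
(again 4th-order Butterworth), squared, averaged with a causal rectangular
1 s window, and log-transformed (natural log; the choice of base is
convention only, applied consistently everywhere). The first second after a
cold start is filter/average warm-up and is excluded from classification.
The filter family and order are not dictated by the method itself; any
stable causal IIR meeting the passband contract behaves equivalently, and
the implementation verifies the realized frequency response in its tests
rather than assuming one.

Feature identity is always the pair (derivation, band) — e.g. `"C3-mu"` —
never a column index, and the column order is fixed: C3-mu, Cz-mu, C4-mu,
C3-beta, Cz-beta, C4-beta.

## Artifact handling

Two independent mechanisms:

* **Trial screening** (`screen_trial_stats()`): a trial is artifactual if
  (i) any sample exceeds ±100 µV, or (ii) the per-channel kurtosis or mean
  Gaussian log-likelihood ("probability") statistic is more than 5 SD from
  its distribution over the trial history. The literature this screening
  follows states the statistics but not the thresholds; ±100 µV and z = 5
  are standard screening practice and are configurable
  (`artifact_config()`). With fewer than 4 history trials only the amplitude
  rule applies. The "probability" statistic has no canonical formula; here
  it is the per-channel mean log-likelihood of the trial's samples under a
  Gaussian fitted to the pooled history of that channel, z-scored against
  the same statistic of each history trial.
* **Feature-outlier rejection** (`reject_feature_outliers()`), run inside
  every calibration: a trial is rejected when any of its six trial-averaged
  features falls outside mean ± 3 SD of the *remaining* trials of its class
  (leave-one-out, so a gross outlier cannot mask itself). `k = Inf` disables
  the rule; zero-variance classes reject nothing.
* **Real-time detection** (`fit_ar()` / `detect_artifact_online()`): each
  calibration fits an AR(11) model per bipolar channel (Yule–Walker, hence
  always stable) on all artifact-free trials. Online, the inverse transfer
  function whitens the stream and a sample is flagged when any channel's
  residual magnitude exceeds its threshold. Thresholds are the 99th
  percentile of training residuals, rescaled by the 99th percentile of the
  per-sample cross-channel maximum ratio so that the *union* false-flag rate
  is 1 % on training data by construction (a per-channel percentile alone
  would give ~3 % for three channels). Flags are held 0.5 s past offset,
  matching the on-screen indicator.

The AR model is fitted on the three bipolar channels because those are the
only signals the online system observes.

## Auto-calibration

`bci_calibrate()` is the package's central fitting function. Given a trial
store it:

1. rejects feature outliers (leave-one-out, per class);
2. selects the single feature maximizing the Fisher criterion
   \((\mu_a-\mu_b)^2/(\sigma_a^2+\sigma_b^2)\) of the trial-averaged
   features over the classification period \([3, 7)\) s (the trial average is
   used because the method statement leaves the within-period aggregation
   open; averaging reduces variance without changing the ranking in the
   stationary case);
3. splits \([3,7)\) into eight 0.5 s windows and, per window, computes a
   leave-one-out cross-validated accuracy curve: an LDA trained on the
   window-averaged feature is applied *sample-wise* over the whole period of
   the held-out trial, and fold-averaged. The window with the highest
   *median* curve accuracy wins; ties go to the earliest window;
4. trains the final LDA on the winning window. The discriminant is the
   closed-form pooled-variance solution \(w=(\mu_1-\mu_0)/s^2\); the pooled
   variance is the maximum-likelihood estimate so the model depends on class
   statistics only (duplicating every trial changes nothing). A variance
   floor of `1e-12` guards degenerate features;
5. normalizes the output affinely so the two training-class means map to
   exactly −1 (non-control) and +1 (imagery). The published description only
   promises outputs "approximately −1 to 1"; making the contract exact is
   what gives the self-paced threshold of 0.5 a stable meaning, and is
   testable;
6. fits the AR artifact model.

The *initial* calibration (at 9 artifact-free trials per class, TPC) runs
this pipeline for left-vs-NC and right-vs-NC and keeps the class with the
higher median cross-validated accuracy (ties: higher Fisher score of the
selected feature, then right — fixed for determinism). Re-calibration runs
after every 5 new clean TPC of the two active classes, on all accumulated
clean trials, and replaces the model atomically. Feature selection precedes
window selection (nesting it inside the cross-validation would be the more
conservative design, but the method's stated order is followed). If outlier
rejection leaves fewer than 5 trials in a class the calibration is deferred
until the next trial — a no-op, not an error.

Calibration is a pure function of the clean-trial multiset; the counter of
new clean trials resets after every calibration, and trials rejected as
outliers still count as consumed.

## The two paradigms

**Co-adaptive (cue-guided)**: 4 runs × 36 trials; fixation cross at 0 s, cue
at 2 s, imagery until 7 s, pause uniform in 2–3 s (so a session schedules
21.6–24 minutes; the nominal description "six minutes per run" corresponds
to the upper edge). Cues come in permuted balanced blocks — three classes
before the first calibration, the selected class plus non-control after.
Balanced blocks rather than i.i.d. draws are a deliberate choice: they
guarantee the printed per-run class balance and a first calibration within
five minutes, which unconstrained randomization cannot. Feedback is
positive-only: between 3.75 s and 7 s a bar proportional to \(|o|\)
(clipped at 1) is shown only while the predicted label matches the cue; a
reward event fires when prediction and cue match for a cumulative > 2 s
within \([3,7)\) s. Artifactual trials are excluded from the store but still
presented — the paradigm timing never changes. Audio, smiley and rendering
are represented as log events only; the paradigms are event-stream state
machines by design.

**Self-paced (brain-switch)**: an arrow rotates over 6 segments, 4 s per
segment. Run 1 (60 s of non-control) only adapts the classifier bias: the
output shift is set so the 90th percentile of the run's outputs equals 0.
The exact published adaptation rule is not stated; the percentile rule is
one concrete reading with a direct interpretation (the detector stays below
the boundary 90 % of relaxed time) and is idempotent. Runs 2–3 (420 s each):
targets appear 2–5 segments clockwise after the last target; the simulated
user performs the trained imagery in target segments (after its reaction
latency, applied from segment entry) and relaxes otherwise. An activation is
one full uninterrupted second of output above 0.5; a 4 s super-threshold
span therefore yields 4 activations — forced by the "maximum of four points"
rule — and the dwell clock resets at segment boundaries. Non-target segments
show sham feedback (Gaussian arrow lengths, mean 0.25, SD 0.08, clipped at
0.45 < threshold) so false positives are *logged but never displayed*.
Scored target segments are followed by a 3 s refractory stop whose time is
excluded from counting.

## Evaluation statistics

* `samplewise_accuracy()`: fraction of trials correctly predicted at each
  time point of \([3,7)\) s; the headline number is the curve's **peak**.
* `youden_index()`: over a grid of thresholds × dwell times (dwell 0.5–4 s
  in 0.5 s steps; the threshold grid is not prescribed anywhere, so the
  default spans the normalized output scale, `seq(-0.75, 0.75, 0.25)`), a
  trial is "activated" when it contains one uninterrupted above-threshold
  dwell; J = TPR − FPR, maximized over the grid and reported in-sample
  (optimism noted: the optimizing cell is chosen on the same data it is
  evaluated on).
* `chance_threshold()`: one-sided adjusted-Wald upper bound on chance (50 %)
  accuracy at \(N = 2\times\)TPC and significance α (z = 2.326 at α = 0.01).
  At 54 TPC this gives 60.9 %, reproducing the printed 61.0 % threshold.
* `balanced_accuracy()` and `selfpaced_chance_threshold()`: the self-paced
  confusion matrix is row-normalized (mean of TPR and TNR), which fixes the
  theoretical chance level at 50 % regardless of the ~31 % target
  prevalence; the significance bound is computed conservatively on the
  number of target segments only.

### A caution about peak statistics

The adjusted-Wald band is exact for a *single* accuracy. The reported peak,
however, is a maximum over ~1000 time points whose accuracy values
decorrelate within a few hundred milliseconds (roughly 20–25 effectively
independent points per session in simulation). A no-control (null) user's
peak therefore exceeds the single-accuracy 61 % band far more often than the
nominal 1 % — about one session in four or five in this package's
simulations. The acceptance suite asserts the single-accuracy band as the
method defines it and documents the resulting failure rather than widening
the band; any analysis that wants a calibrated null for the *peak* should
derive it by permutation or Monte-Carlo of the peak statistic itself.

## The synthetic user

`sim_user()` generates six-electrode EEG as: 1/f background noise (classic
three-pole pinking filter, RMS 8 µV per electrode) plus a white floor
(2 µV, which keeps AR fitting well-posed), plus band-limited mu and beta
rhythms on the anterior electrode of each pair — amplitude-modulated
narrowband Gaussian noise rather than sinusoids, for realistic spectra with
controllable power (mu 10 µV RMS, beta 8 µV RMS). ERD multiplies a rhythm's
amplitude by \(\sqrt{1-d}\) while the mapped class is active (contralateral
mapping: right-hand imagery attenuates C3, left C4), after a response
latency of 0.5 s. With these amplitudes the in-band background is ≲10 % of
rhythm power, so a planted depth \(d=0.5\) shows up in the log feature as a
drop of ≈ log 0.5 — the property the generator's tests pin down. Artifacts
are Poisson-timed raised-cosine transients (0.2–0.5 s, 500 µV) on random
electrodes with an exact ground-truth event list.

What the generator does *not* emulate: eye-movement and EMG spectral
structure (artifacts are broadband transients only), non-stationary drifts
of rhythm amplitude, learning effects within a session, and any biophysical
head model. Passing closed-loop tests therefore demonstrates the *system's*
correctness and its behaviour under idealized ERD, not performance on real
recordings.

Preset conditions: `strong` (right C3-mu depth 0.5, C3-beta 0.3; left C4-mu
0.3; no artifacts), `weak` (right C3-mu 0.2, left C4-mu 0.1, 1 artifact/min),
`null` (no ERD), `artifacty` (weak with 6 large artifacts/min). Under the
strong condition the closed-loop co-adaptive peak accuracy is ~80 % and the
self-paced balanced accuracy averages ~64–70 % — the latter close to the
64 % human average the paradigm was reported to reach, and frequently below
the conservative per-session significance threshold (~65 % at ~53 target
segments), exactly as roughly half the human sample was.

## Numerical and design details

* Times are seconds from session start; sample indices are 0-based in
  window/segment arithmetic; windows are half-open \([a,b)\).
* All randomness flows from the session seed; schedules, sessions and
  generated EEG are bit-reproducible.
* Streaming equals batch: every filter (IIR stages, moving averages, AR
  whitening, flag hold) carries explicit state, and block-wise processing is
  asserted to equal whole-stream processing to 1e-9.
* Problem sizes in the tests and acceptance script — 10 closed-loop sessions
  per condition, 20 planted-recovery calibrations, 10⁴ Monte-Carlo
  replicates — were chosen so the whole suite runs in a few minutes while
  keeping the binomial noise of the measured rates well inside the asserted
  margins.
* Degenerate inputs: constant features fall back to window 0 with a warning;
  zero-variance LDA uses the variance floor; an all-rejected trial set is an
  error ("unusable data"); sessions with a missing model error out before
  any EEG is generated.
* EDF I/O is a minimal continuous-recording reader/writer (16-bit physical
  scaling, whole-record zero padding); the session logs are plain CSV/JSON
  with a fixed `t, kind, label, value` schema.

## Known limitations

* The Youden threshold grid and the exact probability-screening statistic
  are package choices where the method description is silent; both are
  configurable and documented above.
* Peak-accuracy significance is optimistic (see the caution above).
* The self-paced arrow is an event-stream abstraction; no psychophysical
  display timing is simulated.
* The synthetic user's artifacts are amplitude transients; detector
  performance on ocular/muscular artifacts with structured spectra is
  untested by construction.
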