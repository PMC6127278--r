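---
title: "Methods: simulating and detecting self-paced movement imagination from MRCPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting self-paced movement imagination from MRCPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`mrcpdetect` implements an offline analysis chain for a self-paced
reach-and-grasp movement-imagination (MI) paradigm in which the imagination
onset (IO) is recovered Libet-style from a reported scroller number.  The
chain is: session simulation → cleaning (notch, trial rejection, PCA + ICA,
back-projection) → cue-locked ERP statistics → IO-locked MRCP analysis →
time-locked MI-vs-REST classification → simulated-online asynchronous
detection.  Because the matching experimental recordings are not publicly
released, the first-class synthetic-data generator defines the study
conditions every other stage is validated against.

```{r}
library(mrcpdetect)
cfg <- sim_config(channel_names = montage_labels(32))
result <- run_subject(cfg, subject_seed = 1)
result$summary
```

## The paradigm and its simulation

A trial is: 2 s baseline, a condition cue (ID — free target choice,
IDII — choice between two filled glasses, EC — single filled glass), a
scroller of distinct 3-digit numbers every 750 ms for 13.5 s, a self-paced
IO, and a 1.5 s break.  Three 60 s rest runs are appended.  The subject
reports the number displayed at the perceived urge; the IO estimate is the
display onset of that number, so it is quantised to the 750 ms scroller
grid and is systematically *early* by up to one period relative to the true
urge.  The generator keeps the true IO, true blink times and true condition
templates as ground truth so recovery can be tested against them.

Signal content:

* **ERP template** (cue-locked): Gaussians at 0.2 s (4 µV, parieto-occipital
  gain map) and 0.5 s (5 µV, centro-parietal), plus a raised-cosine late
  component supported exactly on 0.6–0.8 s whose amplitude is
  condition-dependent (ID = IDII = 3 µV, EC = 1 µV; a 2 µV difference).
* **MRCP template** (IO-locked): piecewise raised cosine, zero before
  −1 s, −6 µV peak at +0.5 s, back to zero at +2 s.  Morphology landmarks,
  not equations, are what is known about the waveform, so smooth segments
  between the landmarks are a modelling choice.
* **Background**: 1/f Gaussian noise (exponent 1), per-channel RMS 2 µV.
* **Blinks**: 300 ms raised-cosine transients, 4/min at 120 µV, on EOG and
  frontal EEG channels with decaying gains.
* **Reports**: with probability 0.05 a trial's report is invalid (a number
  never shown, or a target violating the condition).

Topographies are abstract gain maps over 10-10 labels, not forward models;
no saccades or EMG are simulated.  The default rate is 250 Hz (all analysis
bands are ≤ 70 Hz) and everything downstream is rate-agnostic.

### Choice of the default parameters

The IO distribution (truncated lognormal on [2, 9] s, median 4 s) and the
reporting-error model are config knobs, not claims: only per-subject IO
spread is known from the study.  Trials per condition default to 60
(≈ the per-condition count remaining after cleaning in the study).  The
background RMS is the one genuinely free scale: it was set once to 2 µV so
that the generator reproduces the qualitative regime the study reports — a
2 µV late-ERP condition difference detectable by the family-wise-corrected
test in ≥ 90% of subjects at 60 trials/condition, a clear single-subject
MRCP, and above-chance single-trial detection.  This plays the role of the
*post-cleaning in-band* background of real EEG, which is why it is smaller
than a typical raw-EEG RMS.  Passing tests on these data show the pipeline
recovers what the generator encodes; they cannot show robustness to real
artifact diversity (muscle, drift, electrode pops) or to non-stationary
backgrounds, which the generator does not emulate.

## Cleaning

Order of operations: (1) bad channels are removed by a robust criterion —
log MAD of each EEG channel over the rest runs, flagged beyond 5 robust SDs
from the median *and* at least a factor-2 scale ratio (the floor prevents
false flags when channels are near-identical; MAD rather than variance so
sparse blinks do not condemn frontal channels) — plus a config override
list.  (2) 50 Hz notch (2nd-order zero-phase Butterworth band-stop,
skipped if the rate makes it meaningless).  (3) a 1–70 Hz 4th-order
zero-phase Butterworth copy is epoched to trial starts and screened
trial-wise: any sample outside ±200 µV, abnormal joint probability, or
abnormal kurtosis, each statistic thresholded at 5 across-trial SDs.  The
joint-probability statistic is the per-channel negative mean log-likelihood
of a trial under the 100-bin histogram pooled over trials — a documented
stand-in for toolbox behaviour that is only cited, not specified, in the
literature.  (4) PCA retaining 99% variance, then extended-Infomax ICA on
the concatenated artifact-free epochs (EEG + EOG).  (5) components whose
activation correlates with any EOG channel above |r| = 0.7 are marked
(automating a visual step; a manual override list is unioned in), and
(6) the remaining components are back-projected onto the *notch-only*
data, rest runs included.

All filters are applied forward–backward (zero phase).  `signal::filtfilt`
does no edge padding, so both passes run on odd-reflection-padded signals
with a padding length of three time constants of the lowest corner; this
matters for the 0.1 Hz high-pass, whose transient would otherwise corrupt
tens of seconds.  Band-passes are realised as high-pass/low-pass cascades
because an 8th-order band-stop/band-pass transfer function with a corner at
0.0008 of Nyquist is numerically fragile in `(b, a)` form.

The ICA is a natural-gradient extended Infomax (tanh nonlinearity with
kurtosis-sign switching) on whitened PCA scores: minibatches of ≥ 2048
samples, learning rate 0.1 annealed by 0.96 per pass with halving on
divergence, pass count adapted to the number of minibatches per pass, fixed
seed recorded in the output.  Whether the original analysis fitted ICA on
concatenated epochs or continuous data is not stated; concatenated
artifact-free epochs are assumed here and documented.  Near-Gaussian
background components are not identifiable by any ICA and do not need to
be — what matters is that the strongly super-Gaussian blink source is
isolated, marked, and removed (validated against ground-truth blink times:
the blink-locked frontal average must shrink by ≥ 80%).

## Event handling and behavioural comparison

A trial is valid iff the reported number was actually shown during the
trial and the reported target is consistent with the condition (EC: the
single filled glass; IDII: one of its two; ID: any of 1–5).  Missing
reports give invalid trials, not errors.  The IO of a valid trial is the
display onset of the reported number.  Epoch windows are half-open
`[start, end)` in seconds, sample indices 0-based, and the lock sample is
`round(event · fs)` — conventions the source material does not state, so
they are fixed here once.

The behavioural IO comparison is pairwise Wilcoxon with
Benjamini–Hochberg adjustment over the three condition pairs.  The source
is ambiguous between the rank-sum and the signed-rank variant ("paired
Wilcoxon rank-sum" is self-contradictory); the unpaired rank-sum is the
default as the methods section names it, with `paired = TRUE` available.

## Cue-locked ERP statistics

Averages are computed on 0.1–15 Hz data.  Confidence intervals use the
nonparametric t-percentile bootstrap: resample trials with replacement,
studentise `(mean* − mean)/se*`, take empirical α/2 and 1−α/2 quantiles,
invert around the observed mean and SE.  Degenerate zero-variance cells
collapse to the mean.

Condition differences are tested with a paired tmax permutation test on
the [0, 2] s window: per permutation the paired differences are sign-flipped
whole-trial-wise (the standard paired construction; the source names only
"permutation tests"), a paired t is computed at every channel × sample, and
the signed value with the largest magnitude enters the reference
distribution, observed labelling included (hence p ≥ 1/(n+1)).  Critical
values cut off 0.025 per tail; per-cell adjusted p-values are the fraction
of the |tmax| distribution at or above the cell's |t|.  When
2^pairs ≤ 4096 the full enumeration replaces sampling and results are
exact and reproducible.  Zero-variance cells get t = 0 when the mean is
also zero (identical inputs must yield an empty mask).  All channels are
tested jointly; the default Monte-Carlo count is 10,000 (not stated in the
source).  Implementation note: under sign-flipping the per-pair squares are
invariant, so each permutation's t-map follows from the fixed
sum-of-squares and the permuted mean — one matrix product per permutation
chunk.

## IO-locked MRCP analysis

Averages on 0.1–1 Hz data; the peak negativity is the argmin of the
average in the closed [−2, 2] s window, ties broken toward the earliest
latency.  No channel-space baseline subtraction is applied (the 0.1 Hz
high-pass detrends); a baseline option exists in the epoching layer.  Each
reported peak carries a CI-overlap flag (bootstrap CI at the peak
containing zero) rather than an MRCP-presence verdict — how "no
characteristic slope" was adjudicated for one subject in the study is
unstated, and argmin selection biases the flag toward significance on pure
noise, so the flag marks only unambiguous cases.

Two conventions matter when interpreting latencies.  Locked to the
*estimated* IO (the study's convention and the pipeline default), the
scroller quantisation shifts the apparent peak late by ~+0.4 s on average,
because the estimate precedes the true urge by U(0, 0.75) s.  Parameter
*recovery* is therefore asserted against epochs locked to the generator's
true IO, where the 0.1–1 Hz filtered template is the oracle: the filter
attenuates the −6 µV peak to about −4.2 µV without moving the (symmetric)
peak, so recovered amplitudes are compared against the filtered-template
value, and latencies against the configured truth.

## Time-locked detection

Features: cleaned 0.1–1 Hz data, anti-alias filtered (4th-order low-pass
at 4 Hz) and decimated to 10 Hz, 26 sensorimotor channels (the published
montage is shown only graphically; `sensorimotor_channels()` is a
documented fronto-central/centro-parietal approximation), 1 s windows → 10
amplitudes × 26 channels = 260 features.  Per trial there is one MI window
(starting −1 or 0 s relative to the IO) and one REST window ([4, 5] s
after the IO, or [−5, −4] s when `io + 5` would exceed the trial end —
boundary inclusive).  The MI start is chosen *within each training split*
from the training-average MRCP at Cz: peak latency strictly before 0.5 s →
−1 s, otherwise 0 s.

The classifier is an LDA whose pooled within-class covariance is shrunk
toward νI (ν = tr(S)/d) with the analytic Ledoit–Wolf intensity
γ = (Σᵢ‖xᵢxᵢᵀ − S‖²_F / n²) / ‖S − νI‖²_F, clipped to [0, 1] — estimated
from training data only, well-defined when features outnumber
observations.  Class probabilities are a logistic map of the decision
value (a documented calibration choice; only the 0.5 threshold is
required).  Evaluation is 10 × 5-fold cross-validation with trial-level
folds stratified by condition (stratification is not stated in the source
and is a design choice here); accuracy, TPR/FPR/FNR/TNR are averaged over
the 50 evaluations.  The chance level is the adjusted-Wald interval at the
subject's trial count.

## Asynchronous detection

Training uses three consecutive 1 s windows per class per trial (MI from
the subject's MI start; REST from +4 s, or −5 s when the 3 s block would
cross the trial end).  Per repetition and fold, 3 folds train, 1 validates,
1 tests.  On each test trial the classifier slides over the 12 s
evaluation period starting 1 s after the cue, on every 10 Hz sample, with
features from the trailing 1 s window `[sᵢ − 1, sᵢ)` (121 samples — both
endpoints of the period are evaluated; the window convention matches the
training windows, whose first sample sits at the window start).  An MI is
detected at sᵢ iff that sample and its x predecessors all have P(MI)
strictly above 0.5; x ∈ [5, 15] is chosen on the validation fold to
maximise correct trials, ties toward the smallest x (faster detection).
Detection timestamps are the trailing-edge sample of the qualifying run.

The MI period is `[IO + MI_start, IO + MI_start + 3]`; the true-positive
window is that period shifted by +0.5 s (half the sliding window), and
detections in the first half-second of the MI period count as false
positives — implemented literally from the evaluation scheme's definition.
A trial is correct iff ≥ 1 detection falls inside the TP window and none
outside.  The chance level is a structured permutation: the observed IOs
are shuffled across trials without replacement (preserving the IO
marginal; a uniform-redraw variant is config-switchable), TP windows are
recomputed, and the *fixed* detections are re-scored, 500 times.  The
study instead re-ran the whole cross-validation per permutation; fixing
the detections is a deliberate simplification that isolates the evaluation
logic and costs a fraction of the compute.  Permuted assignments whose TP
window would leave the evaluation period are redrawn (they cannot occur
under the default timing).

## Numerical choices and degenerate inputs

* Zero-variance cells: bootstrap CIs collapse to the mean; permutation t
  is 0 when the mean difference is also 0, ±(large) otherwise.
* `select_mi_window` at exactly 0.5 s latency → 0 s ("before" is strict);
  `select_rest_window` at exactly `io + 5 = trial_end` → [4, 5]
  (boundary inclusive).
* Probability exactly 0.5 never triggers a detection (strict threshold).
* Identical trials produce no joint-probability/kurtosis flags (zero
  across-trial SD is treated as "no deviation").
* Fewer than 3 trials make the rejection statistics undefined → error;
  fewer than 2 valid trials per condition skip that behavioural pair with
  an `NA`.

## Problem sizes used in the shipped checks

The shipped verification uses desk-scale sizes chosen to exercise every
code path at the study conditions: unit fixtures of 5–30 trials at
50–100 Hz on a 16-channel montage; calibration checks with 200 null
datasets (12 pairs × 4 channels × 2 s at 100 Hz), 50 simulated subjects
for ERP sensitivity and MRCP recovery (60 trials at 250 Hz), and an
end-to-end run of three subjects × 180 trials × 32 channels at 250 Hz.
The acceptance script reruns the end-to-end chain on two such subjects
plus reduced-size calibration sweeps.

## Known limitations

* The generator's backgrounds are stationary 1/f noise with blinks only;
  real EEG non-stationarities, muscle and movement artifacts are absent,
  so rejection thresholds and ICA behaviour on real data are untested.
* Topographies are gain maps; no volume conduction structure, so
  source-space analyses are (deliberately) out of scope.
* The published accuracy figures depend on the unreleased recordings and
  are structural references only; nothing in this package is tuned to
  reproduce their numeric values.
* ICA separability of the neural background is not claimed — only the
  artifact subspace is validated.
* The asynchronous chance level fixes detections across permutations (see
  above); it matches the evaluation-logic oracle, not the study's costlier
  re-training scheme.
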