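---
title: "Fear recognition from electrodermal and heart-rate-variability features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fear recognition from electrodermal and heart-rate-variability features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fear has a well-defined autonomic signature: sympathetic sudomotor
activation raises the tonic skin conductance level (SCL) and the rate of
discrete skin conductance responses (SCRs), while vagal withdrawal reduces
beat-to-beat heart-rate variability.  `physiofear` implements a complete
binary fear-recognition pipeline over these two peripheral channels --
skin conductance (GSR, in microsiemens) and the photoplethysmogram-derived
inter-beat intervals -- from raw multichannel recordings to cross-validated
classification reports.

Fear is defined on the dimensional emotion model: a trial rated on 1--9
scales is labeled fearful exactly when

    valence <= 5  AND  arousal > 5  AND  dominance <= 5,

i.e. unpleasant, activating, and experienced with low control.  The
boundaries are inclusive for valence and dominance and strict for arousal;
`label_fear()` implements exactly this conjunction.

Because the reference recordings this design emulates are under restricted
access, the package ships a first-class synthetic session generator with
full ground truth, and every downstream stage is specified and tested
against that ground truth.

## Session model and the synthetic generator

A session consists of `n_trials` (default 40) trials, each a 5 s neutral
fixation baseline followed by a 60 s stimulus interval, recorded at 512
samples/s on three channels: conductance, pulse, and an integer status
channel marking each baseline onset (code 1) and stimulus onset (code 4).
The status codes are constants of this package's CSV dialect; the sessions
round-trip through `write_session_csv()` / `read_session_csv()`.

`generate_session()` synthesises:

* **Conductance** = tonic level + SCR train + Gaussian noise.  The tonic
  level is drawn from `tonic_level_range` (default 2--12 uS, inside the
  physiological 2--20 uS SCL range) with a slow sinusoidal drift.  Each SCR
  is a bi-exponential (Bateman-type) kernel with rise/decay constants
  0.75 s / 2.0 s -- the conventional response shape used by
  deconvolution-based decomposition -- normalised to unit peak so an event
  of amplitude *a* produces a trough-to-peak excursion of *a*.  Event
  onsets form a homogeneous Poisson process over the stimulus interval;
  amplitudes are uniform on `scr_amp_range` (default 0.1--1.3 uS, the
  textbook SCR amplitude band).
* **Pulse** = a train of Gaussian bumps centred on the ground-truth beat
  times.  Inter-beat intervals are `ibi_mean` (0.85 s) plus a slow 0.1 Hz
  modulation (giving the tachogram its low-frequency content) plus Gaussian
  jitter.
* **Ratings** consistent with the fear flag: fear trials are drawn
  uniformly inside the fear region of the rating cube, non-fear trials
  uniformly over its complement by rejection, so all three violation modes
  (including boundary values such as valence exactly 5) occur.

Fear trials differ from non-fear trials in three controlled channels: the
SCR rate (`scr_rate_fear` = 6/min vs `scr_rate_nofear` = 2/min), the
inter-beat variability (`ibi_sd_fear` = 0.03 s vs `ibi_sd_nofear` =
0.06 s), and a multiplicative tonic raise (`tonic_fear_gain` = 1.3).
These defaults were fixed once as the package's study conditions: a
three-fold SCR-rate increase and a halved inter-beat variability are
squarely inside the effect range the stress-physiology literature reports
for fear-grade arousal, and the proportion of fear trials
(`fear_fraction` = 0.15) matches the label prevalence such dimensional
fear rules produce on rating-based corpora (about one trial in seven).

`simulate_trial_records()` is a trial-level shortcut that emits segmented
16 samples/s `trial_record` objects from the same trial model, skipping
the megasample raw stage; cohort-scale experiments (hundreds to a thousand
trials) use it so that feature extraction, not raw synthesis, dominates
the runtime.

What the generator deliberately does **not** model: habituation across
trials, motion artifacts, electrode drift or detachment, superimposed SCR
bursts at pathological rates, and any EEG/EMG/respiration/temperature
channel.  Passing tests therefore demonstrate correctness of the pipeline
arithmetic and recoverability of planted physiological effects -- not
classifier performance on real recordings.

## Preprocessing

The conductance channel is low-pass filtered and decimated to 16
samples/s.  The filter is a 512-order FIR designed by the window method
(Hamming taper, 5 Hz cutoff): linear phase preserves the SCR waveshape,
and the taps are renormalised to exact unity DC gain so absolute
conductance levels survive filtering.  `filter_decimate()` compensates the
integer group delay (order/2 samples) with edge-replication padding before
keeping every 32nd sample, so output sample *i* corresponds to input time
32·*i*/512 s and window boundaries stay aligned.  The processed rate was
chosen as 16 samples/s because electrodermal activity carries no usable
energy above a few hertz.

`segment_trials()` cuts one record per stimulus-onset marker: an
80-sample baseline and a 960-sample stimulus trace, the trial's ratings,
the rule-derived fear label, and beats detected from the raw pulse channel
over the trial span.  The baseline is filtered and decimated identically
to the stimulus interval.  Trials containing non-finite samples are
excluded and logged rather than propagated.  `detect_beats()` is a simple
local-maximum detector with an adaptive threshold (median plus 40% of the
median-to-maximum excursion) and a 0.3 s refractory period -- adequate for
clean pulse signals; it is not an artifact-robust clinical beat detector.

## Tonic/phasic decomposition

`decompose_eda()` splits the 16 Hz trace into SCL, SCR and a discrete
event list, with the output contract of continuous
deconvolution-based decomposition: SCL + SCR reconstructs the input
exactly, the phasic trace is near-nonnegative, and events carry onsets and
amplitudes.  The method is a two-pass procedure:

1. a coarse tonic estimate (rolling 10th percentile over a +/-4 s window,
   smoothed) exposes a provisional phasic trace on which candidate SCRs
   are found by *sequential kernel peeling*: peaks are detected on a
   lightly smoothed copy, each candidate's onset is the latest
   near-baseline trough in a short pre-peak region (the kernel rise lasts
   about 1.2 s), and its amplitude is the least-squares projection of the
   residual -- after subtracting the fitted bi-exponential tails of the
   responses already accepted -- onto the response kernel, jointly with a
   free local baseline offset so a single noisy trough sample cannot bias
   the estimate;
2. the tonic level is then re-estimated by interpolating the conductance
   through response-free samples (everything outside
   [onset − 0.5 s, onset + 10 s] of any provisional event) and smoothing;
   the phasic trace is the exact remainder, and events are re-measured on
   it.

The provisional detection floor is a fixed 0.05 uS, independent of the
user-facing `amp_min`, so the tonic estimate -- and with it the event list
before the final amplitude filter -- does not move when `amp_min` does;
raising `amp_min` then strictly filters a fixed list and can only remove
events.  The default `amp_min` = 0.05 uS is the common minimum-SCR
criterion; it is configurable because no single threshold suits all
electrode setups.  On noiseless synthetic trials with onsets separated by
at least 5 s the detector attains perfect precision/recall with about 2%
mean amplitude error (see the test suite); closely superimposed responses
are the known failure mode, which is why the simpler peeling scheme was
preferred over a full non-negative deconvolution: it meets the same
contract at a small fraction of the cost on thousand-trial assemblies.

Decomposition is run per trial, on the concatenated baseline + stimulus
trace, so the tonic estimate is continuous across the boundary and the
baseline's own SCL/SCR segments are available for the ratio features.

## The 40-feature registry

Each analysis window yields 40 named features: for each of the GSR, SCL
and SCR traces the time-domain set *mav* (mean absolute value), *mar*
(mav over the trial's 5 s baseline mav), *std* (sample standard deviation,
n−1 denominator), *str* (std over baseline std), *wl* (waveform length),
*ssc* (slope sign changes, threshold 0.001 uS), *wamp* (Willison
amplitude, threshold 0.5 uS), and the spectral set *fmd*, *fmn*, *hlr*
(30 features); the SCR-event set *nimp*, *avimp*, *maximp* (3); and seven
HRV features: *HR_std*, *HRV_std*, *NN50*, *pNN50*, *NN20*, *pNN20*,
*HRV_hlr*.

Numerical conventions worth spelling out:

* **Waveform length squares its differences** (`sum(diff(x)^2)`).  This is
  unconventional -- the electromyography literature sums absolute
  differences -- but it is the definition this registry standardises on;
  `wl_squared = FALSE` switches to the conventional form.
* **Threshold comparisons are inclusive** (`>=`) for both *ssc* and
  *wamp*.
* **The spectrum estimator** is a mean-removed, zero-padded one-sided
  periodogram evaluated on the exact 801-line grid 0, 0.01, ..., 8.00 Hz
  (pad length fs/df = 1600 makes the grid a subset of the DFT bins).
  Mean removal matters: conductance windows are offset-dominated, and
  with the DC line included the median and mean frequencies of every
  GSR/SCL window collapse towards 0 Hz, degenerating both features.
* **Median frequency** is the first grid line at which cumulative power
  reaches half the total.  The half-energy split objective
  |sum(P[0..Q−1]) − sum(P[Q..])| is minimised by this crossing line up to
  one 0.01 Hz grid step, and the crossing convention is the only one that
  stays well-defined on degenerate spectra (for a single spectral line
  every split index ties on the objective; the crossing rule returns that
  line's frequency, as it should).
* **Band edges are half-open** [low, high): the electrodermal ratio uses
  [0.01, 0.2) vs [0.2, 2) Hz, the tachogram ratio [0.04, 0.15) vs
  [0.15, 0.4) Hz, so no line is counted twice.
* **pNN50/pNN20 divide by the interval count H**, not H−1, exactly as the
  registry defines them; `HRV_std` uses the H−2 denominator over the H−1
  successive differences.
* **The tachogram** for `HRV_hlr` is built by cubic-spline interpolation
  of the (beat time, interval) pairs, resampled at 4 samples/s, then fed
  through the same periodogram machinery on a 0--0.5 Hz grid.  4 Hz
  comfortably oversamples a sub-0.5 Hz band; the construction is a
  package choice since tachogram handling admits many conventions.
* **Empty-event windows** report nimp = avimp = maximp = 0 by convention,
  and an SCR event belongs to the window containing its *onset*
  (half-open membership), so overlapping windows may each claim the same
  event.
* **Degenerate inputs become `NA`**, never errors, inside a window:
  zero-variance baselines (str), zero total power (fmd/fmn), zero
  low-band power (hlr), too few beats (std features need 3 intervals, NN
  counts 2, the spectral ratio 4).  `assemble_dataset()` imputes remaining
  `NA`s with column medians and reports how many cells it touched.

## Windowing and dataset layouts

Two schemes cover each 60 s stimulus interval: three non-overlapping 20 s
windows, or five 20 s windows with a 10 s step.  Under the non-overlapping
scheme a trial contributes one row of 120 columns (each feature suffixed
`[W1]`--`[W3]`); under the overlapping scheme it contributes five rows of
40 columns, all carrying the trial's label.  Every window of a trial is
referenced to the same single 5 s baseline.  The arithmetic consequence,
verified exactly in the tests: 1158 trials with 166 fear trials yield
4960 non-fear and 830 fear rows under the overlapping scheme.

## Class balancing

Fear labels are rare, so the pipeline balances in two stages with
`balance_classes()`: the majority class is randomly undersampled to
`floor(n_minority / 0.2)` and the minority is then SMOTE-oversampled to
`floor(0.8 * n_majority)` -- synthetic points are uniform draws on the
segment between a minority point and one of its 5 nearest minority
neighbours.  The ratio parametrisation is fixed by the arithmetic it must
reproduce: 992/166 maps to 830/664 and 4960/830 to 4150/3320, which
uniquely pins undersampling at a 0.2 and SMOTE at a 0.8 minority:majority
target.  Class counts after balancing depend only on the input counts and
the configuration -- never on the data or the seed.

Balancing the whole dataset before splitting (the default protocol here)
leaks synthetic neighbours of test points into training and flatters every
score; `repeated_protocol(balance = balance_config())` instead applies the
same two stages inside each round's training subset, which is the
methodologically clean variant.

## Classification protocol

`repeated_protocol()` runs 10 rounds of stratified 70/30 splits.  Inside
each round, strictly on the training subset: optional balancing,
standardization (automatic for SVM and kNN -- these distance-based models
refuse visibly unscaled input unless overridden; tree models take raw
features), optional PCA (conventionally 100 components for the
120-column layout, 20 for the 40-column layout) or top-k feature
selection, then an exhaustive grid search scored by stratified 5-fold
cross-validation accuracy.  The winning configuration (first in
enumeration order on ties) is refit on the full training subset and
evaluated on the held-out 30%: confusion counts, precision, recall, F1,
accuracy, sensitivity, specificity and ROC AUC from the continuous score
ranking (flagged missing for a single-class test set; a constant score
scores 0.5).

Grids: SVM sweeps C over {0.1, 1, 10, 100, 1000, 10000} and the RBF
gamma over (1/n_features)·{1, 10, 100, 1000} -- the multiplicative
reading of the gamma ladder, confirmed by the reference values 0.083 at
120 features and 0.25 at 40 -- with balanced class weights; the gamma
base uses the feature count *after* any selection or reduction.  kNN
sweeps n_neighbors 3--9 and Minkowski p in {1, 2}; the tree-index
leaf_size is recorded as a constant because it cannot change predictions.
RF sweeps max_depth {3, 10, unbounded}, min_samples_split
{10, 30, 50, 70, 90}, max_features {sqrt, log2} and n_estimators
{100, 300, 500} under the Gini criterion; GBT is the fixed configuration
(learning rate 0.1, depth 10, 1000 trees), run through the same machinery
as a one-row grid.  Feature ranking offers Pearson correlation, L1 path
entry order, random-forest impurity, gradient-boosting gain, and RFE with
elimination step 1 using the classifier family under evaluation (linear
SVM weights or forest impurity) -- step size and ranking model are
package choices.

## Problem sizes in the shipped tests

The test suite exercises the full pipeline at sizes chosen to keep a
complete run in the low minutes while leaving no stage untested: formula
oracles on 1000 random windows, decomposition recovery on 40 noiseless
trials, the windowing arithmetic on the full 1158-trial assembly, and
effect recovery on a 200-trial cohort in which only the two headline
effect channels are active (SCR rate tripled, inter-beat variability
halved, tonic gain off) -- isolating those channels is what lets the
univariate ranking check ask specifically for `GSR_nimp`/`HR_std` at the
top.  On that cohort the balanced SVM protocol reaches a mean ROC AUC of
essentially 1.0; that number measures the recoverability of a strong
planted effect under whole-dataset balancing, and says nothing about
accuracy on real recordings.

## Known limitations

* The decomposition is tuned to the generator's kernel constants; real
  skin conductance with subject-specific response shapes or superimposed
  response bursts will degrade event recovery (per-subject kernel
  optimisation is out of scope).
* The beat detector assumes a clean pulse waveform.
* Whole-dataset balancing (the default, matching the reference protocol)
  optimistically biases every reported score; use in-fold balancing for
  honest estimates.
* The generator's independence assumptions (i.i.d. fear trials, no
  habituation) make the synthetic classification task easier than the
  real one.

## A minimal end-to-end run

```{r}
library(physiofear)

ses <- generate_session(sim_config(n_trials = 40, seed = 1))
f <- tempfile(fileext = ".csv")
write_ratings_csv(ses$ground_truth, f)
trials <- segment_trials(ses$recording, read_ratings_csv(f))

ds <- assemble_dataset(trials, window_scheme("non_overlapping"))
bal <- balance_classes(ds, config = balance_config(seed = 1))
report <- repeated_protocol(bal, "svm", rounds = 10, seed = 1)
report$mean
```
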