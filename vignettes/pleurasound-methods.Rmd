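---
title: "Methods: breath-sound detection of pneumothorax and hemothorax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-sound detection of pneumothorax and hemothorax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleurasound)
```

## The problem

Air (pneumothorax, PTX) or fluid (hemothorax, HTX) in the pleural cavity
changes chest-wall breath sounds in characteristic ways. PTX attenuates the
signal, removes high-frequency content and flattens the breath-cycle
amplitude variation; HTX damps the signal while the relative background
noise level rises, so its hallmark is a low signal-to-noise ratio. A
detector that classifies a 12 s auscultation recording by these signatures
could triage thoracic trauma where imaging and expert examination are
unavailable.

`pleurasound` implements such a detector end to end: a synthetic study
generator standing in for animal recordings that are not publicly
distributable, band-pass preprocessing and intensity conversion, a compact
acoustic feature set, a weighted k-nearest-neighbour (KNN) classifier whose
parameters are selected by a multi-objective genetic algorithm (MOGA), and
leave-one-out cross-validation (LOOCV) with permutation diagnostics.

## The synthetic study replica

The generator emulates a mechanically ventilated porcine auscultation
protocol: 4 subjects, a baseline state ("volume 0") plus PTX and HTX at
200, 400, 600, 800 and 1000 ml, each state recorded for 12 s at 20,000
samples/s by two digital stethoscopes splitting into two audio channels
each. That is 44 recordings and 4 x 11 x 4 = 176 data sources, each of
240,000 samples.

The base signal is stationary noise band-limited to 60–2000 Hz,
amplitude-modulated by a raised-cosine inhalation–exhalation envelope at
the ventilator rate (13–15 breaths/min; 15 by default, giving exactly three
cycles in 12 s, with no respiratory pause because ventilation is
controlled). Injury effects are deterministic monotone transforms of the
injected volume:

| parameter | acts on | default (per ml) | meaning |
|---|---|---|---|
| `ptx_gain_drop_per_ml` | gain | 7e-4 | log-gain drop; ~0.5x at 1000 ml |
| `ptx_tilt_per_ml` | spectrum | 8e-4 | fraction of a 300 Hz low-passed copy mixed in; 0.8 at 1000 ml |
| `ptx_envelope_drop_per_ml` | envelope depth | 7e-4 | log-drop of modulation depth |
| `htx_damping_per_ml` | gain | 9e-4 | log-gain drop; ~0.4x at 1000 ml |
| `htx_noise_per_ml` | noise | 1e-3 | added broadband noise sd in baseline-RMS units; SNR ~0 dB at 1000 ml |
| `subject_variation` | per subject | 0.15 | log-normal gain sd + small spectral tilt |
| `noise_floor` | all channels | 0.02 | sensor noise sd in baseline-RMS units (~34 dB SNR) |

No quantitative acoustic effect sizes for pleural injuries are available
to calibrate against, so these defaults are conventions chosen once to be
physiologically plausible (mild but clearly monotone changes across the
volume ladder, perceptible channel noise) rather than estimates of any real
animal. The `"strong_separation"` preset raises the effect magnitudes and
suppresses noise to create cleanly separable classes for end-to-end
verification of the optimizer.

Three structural choices matter downstream. First, the thoracic source
process is drawn once per (seed, subject) and injury effects are applied as
deterministic transforms, so summaries such as RMS and spectral centroid
are *strictly* monotone across the volume ladder rather than monotone in
expectation. Second, the breath envelope is normalised to unit RMS so that
reducing the modulation depth (a PTX signature) does not masquerade as a
gain change. Third, the two stethoscopes share the source but receive
independent sensor noise, and the two channels of one stethoscope differ by
independent low-level noise — four correlated but non-identical data
sources per recording, which is exactly the situation that motivates the
grouped cross-validation option discussed below.

What the generator does **not** emulate: heart sounds, spontaneous
breathing irregularity, chest-wall transmission physics, combined
hemopneumothorax, or structured ambient noise. Tests passing on this
replica therefore demonstrate that the pipeline recovers the *documented
signature axes* when they are present; they say nothing about effect sizes
in real recordings.

## Preprocessing

Recordings are filtered with a 4th-order Butterworth band-pass (60–2000
Hz), applied forward–backward for zero phase so breath-cycle features are
not delayed; signals are reflect-padded (three periods of the lowest
pass-band frequency) so start-up transients fall on the padding. The
single-pass response is flat to well under 1 dB across the pass-band and
more than 20 dB down an octave outside it; the two-pass application squares
the magnitude response.

Acoustic intensity (proportional to watt/m², reference constant 1, since
only relative values reach the detector) is measured in constant gaps of
0.00005 s as the mean of squared samples per gap — at the native 20 kHz
rate this is the per-sample square, giving 240,000 intensity values per
recording. The mean-of-squares convention makes the intensity scale law
exact: scaling the signal by *a* scales every intensity value by *a²*.

## Features

The detector never measures distances on the raw 240,000-point series:
point-wise distances between independent noise realisations are dominated
by phase differences carrying no injury information. Instead each data
source is reduced to 29 interpretable features spanning the documented
signature axes:

* 24 log mean-intensity values over equal time windows (level and its time
  course; sensitive to gain drop and damping),
* 3 log band-power ratios between consecutive bands bounded at 60, 250,
  500, 1000 and 2000 Hz (spectral shape; sensitive to the PTX tilt),
* the coefficient of variation and the log-scale interquartile range of
  the windowed intensity (amplitude variation; sensitive to the PTX
  envelope flattening and, through the noise floor, to HTX).

Level and shape are deliberately separated: a global gain change shifts
the 24 windowed features by exactly log(*a²*) and leaves the other five
untouched. The variation statistics are computed on the log scale
specifically to keep them gain-invariant (a raw IQR would scale with
*a²*). All logs are floored at 1e-12 so degenerate all-zero inputs yield a
finite sentinel rather than −∞. The MOGA's feature mask then performs
feature selection among the 29, so the hand-chosen set is a search space,
not a commitment.

## The KNN detector and cross-validation

Distance between feature vectors is weighted Minkowski with exponent 1 or
2 over the masked features; the majority class among the k nearest
training items wins. All tie-breaks are deterministic and order-independent:
equal distances at the k-th neighbour resolve by training-set order (stable
sort), vote ties resolve by the smaller summed neighbour distance, then by
the lexicographically first label. Features are z-scored using the training
fold's statistics only, so the held-out item never influences its own
standardisation.

LOOCV holds out each retained data source in turn — 176 iterations for the
full replica, 144 once the 200 ml states are excluded (they are acoustically
near-baseline, and a 200 ml pneumothorax is of low clinical significance).
Six differentiation tasks are built in (`build_task()`): combined injury vs
normal, the three-way contrast, PTX vs normal, the PTX volume ladder, HTX
vs normal (200 ml retained for this contrast), and HTX vs PTX.

Treating the four channels of one recording as independent datasets matches
the 176-dataset bookkeeping, but lets the sibling channels of a test item
appear in its training fold; `loocv(..., group = )` offers a stricter
leave-one-recording-out variant that holds all four channels out together.
The default remains ungrouped, matching the study design being replicated.

## The multi-objective genetic algorithm

The evolvable genome is the complete detector parameterisation: k, the
29-bit feature mask, per-feature non-negative weights, and the distance
exponent. Fitness is the LOOCV triple (sensitivity, specificity, accuracy);
accuracy is the exact-match fraction (multi-class aware), while sensitivity
and specificity come from the binary any-injury-vs-normal collapse (for
HTX-vs-PTX, HTX is the positive class). No objective weights are imposed:
candidates are compared by Pareto dominance (non-dominated sorting), with
crowding distance breaking rank ties, tournament selection on (rank,
crowding), uniform crossover, and per-gene mutation (k steps by ±2, which
preserves oddness; mask bits flip; weights jitter log-normally; the
exponent resamples). Odd k is the default search space to reduce vote ties
in binary tasks.

Elitism is implemented as a persistent archive of every non-dominated
genome found so far, deduplicated by canonical serialisation and capped at
150 members by crowding distance; up to `elitism_count` archive members are
re-injected each generation. Because the archive only ever improves, the
best archive accuracy is non-decreasing by construction — a property the
tests assert. The run stops after `n_generations` (default 30, population
40) or once the archive's set of objective vectors has been stable for
`stopping_patience` generations (default 10): on separable data the front
reaches (100, 100, 100) early and the patience rule ends the run. Fitness
is memoised by genome serialisation, so re-evaluating unchanged elites is
free. The whole run is a pure function of `(dataset, task, ga_config)`:
one seeded RNG stream drives initialisation, selection and mutation.

## Evaluation and diagnostics

Sensitivity, specificity and accuracy follow the standard confusion-count
formulas, as percentages; a metric with a zero denominator is reported as
`NA`, never 0. For volume-ladder tasks the predicted volume is the volume
attached to the predicted class (0 for normal) and agreement with the real
volume is summarised by Pearson's *r* with df = n − 2 and the two-sided
t-transform p-value; tasks whose classes pool several volumes have no
defined predicted volume and omit the correlation block.

The permutation diagnostic shuffles class labels across retained items and
recomputes LOOCV accuracy with the genome fixed, using the add-one
estimator p = (1 + #{null ≥ observed}) / (B + 1). One subtlety the tests
encode: under exchangeable labels the chance level of LOOCV with k = 1 is
not 50% but (m − 1)/(n − 1) per class of size m, because holding an item
out removes one of its own class from the candidate pool. The null-mean
check is asserted against this exact expectation.

## Numerical choices and degenerate inputs

* Log floor 1e-12 for intensities and band powers; feature standard
  deviations below 1e-12 are replaced by 1 (constant features contribute
  zero distance rather than 0/0).
* Intensity gaps must be an integer multiple of the sampling interval;
  trailing partial gaps are dropped.
* Zero effect magnitudes with a zero noise floor reproduce baseline
  recordings bit-identically at any nominal volume — the generator's
  null case.
* All randomness flows through explicitly derived seeds (a deterministic
  31-bit string hash of the master seed and the stage/subject/channel
  identity), and every seeded function restores the caller's RNG state.

## Problem sizes

The unit tests run the pipeline on a scaled-down replica (8 kHz, 1.5–3 s
recordings, 2 subjects) chosen so the whole suite exercises every code
path in seconds; the acceptance checks regenerate the full-scale design
(20 kHz, 12 s, 176 data sources of 240,000 samples) and evolve the
detector at the default population 40 × 30 generations. The effect-size
sanity check probes the volume-correlation transition in a deliberately
loud regime (noise floor 0.6, ≈4 dB SNR) where detection fails at zero
effect and improves gradedly with it.

## Known limitations

The synthetic replica is cleaner than field recordings: with the default
effect sizes the six tasks are often perfectly separable, whereas real
porcine data yielded intermediate sensitivities for the PTX contrasts.
Results on the replica validate the machinery (filters, features,
cross-validation accounting, optimizer behaviour), not clinical
performance. The detector also inherits the study design's limits: isolated
injuries only (no combined hemopneumothorax), ventilated breathing, a
single auscultation site, and four subjects whose channels are correlated —
use the grouped cross-validation mode to gauge how much that correlation
flatters the ungrouped numbers.
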