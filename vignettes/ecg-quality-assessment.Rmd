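---
title: "Grading single-lead ECG quality with fuzzy comprehensive evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading single-lead ECG quality with fuzzy comprehensive evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Mobile and wearable ECG recorders are operated by people with no training in
electrode placement, and a large fraction of what they record is too corrupted
for rhythm analysis or clinical triage. `ecgsqi` implements an automatic
quality gate for single-lead ECG segments: it computes a small set of signal
quality indices (SQIs), grades each against published criteria, and fuses the
grades into an overall verdict — Excellent (E), Barely acceptable (B) or
Unacceptable (U) — together with a follow-up recommendation (accept, denoise
and reassess, or recollect).

```{r setup}
library(ecgsqi)
```

## The indices

Six indices are computed per analysis window (9,000 samples by default, i.e.
30 s at 300 Hz):

* **qSQI** — agreement between two structurally different R-peak detectors,
  $q = 100 \cdot 2N/(N_a+N_b)$, where $N_a$, $N_b$ are the two detectors'
  beat counts and $N$ the number of matched pairs within a 150 ms window.
  Matching is solved exactly by a non-crossing dynamic program rather than a
  greedy heuristic; for points on a line with a symmetric tolerance the
  non-crossing optimum equals the unrestricted optimum, and the test suite
  checks this against an independent bipartite-matching oracle.
* **pSQI** — the fraction of 5–40 Hz spectral power that falls in the QRS
  band 5–15 Hz. Muscle (EMG) noise inflates the denominator and drives pSQI
  toward 0; a clean beat train sits near 0.5–0.8.
* **cSQI** — the coefficient of variation of the RR intervals (sample SD over
  mean). Computed and reported, and available to the heuristic rule tables,
  but not part of the fuzzy evaluation: on held-out comparisons the
  four-index set (qSQI, pSQI, kSQI, basSQI) fuses better without it.
* **sSQI, kSQI** — third and fourth standardized moments of the raw samples.
  Kurtosis is non-excess (a Gaussian scores 3, a sinusoid 1.5): clean ECG is
  spiky with kurtosis well above 5, while additive broadband noise pulls it
  toward the Gaussian regime. Skewness is reported but not graded — it is
  markedly less robust to noise than kurtosis.
* **basSQI** — one minus the fraction of 0–40 Hz power below 1 Hz; baseline
  wander pushes it down from 1.

Grades are three-level (`optimal` / `suspicious` / `unqualified`; kurtosis is
two-level) with breakpoints exactly as published: e.g. qSQI above 90 is
optimal, 60–90 suspicious (both ends closed), below 60 unqualified; kurtosis
of exactly 5 is unqualified. All breakpoints live in `sqi_config()` and can
be re-tuned.

## The two R-peak detectors

qSQI only works if the detectors fail *differently* under noise, so the two
pipelines share nothing beyond band limits:

1. **Hilbert-envelope with dynamic adaptive threshold**: 5–20 Hz zero-phase
   Butterworth band-pass, first difference, analytic-signal envelope, then a
   running threshold initialised at 0.6 times the 98th-percentile envelope of
   the first 2 s, updated to 0.3 times the mean of the last eight accepted
   peak amplitudes, with a 0.2 s refractory period and a search-back pass at
   0.4 times the threshold when a gap exceeds 1.66 times the median RR.
2. **Stationary-wavelet modulus maxima**: an à trous decomposition with the
   quadratic-spline smoothed-derivative filter pair; R peaks are the zero
   crossings between adjacent opposite-sign modulus maxima of the detail
   coefficients at the scale whose passband best covers the ~10 Hz
   QRS-dominant band (scale 3 at 300 Hz, scale 4 at 500 Hz). Two gates reject
   non-QRS extrema: an amplitude gate (the larger of 0.3 times the 95th and
   0.125 times the 99.9th percentile of the modulus — the second term keeps
   P/T-wave maxima sub-threshold when QRS lobes dominate the upper
   percentiles), and a cross-scale gate requiring the coarse-scale modulus to
   hold up against the local scale-1 modulus, which suppresses narrowband
   (50/60 Hz) interference that lives at fine scales.

Both detectors are amplitude-scale invariant and polarity insensitive by
construction, and both are verified against generator ground truth at
sensitivity at least 0.95 from 60 to 160 bpm.

One property worth knowing: when a record is swamped by stationary broadband
noise, *both* detectors emit dense refractory-limited spurious peak trains,
and two independent trains at ~4–5 peaks/s chance-match at a 150 ms tolerance
roughly 80% of the time. qSQI therefore does not collapse to 0 on pure-noise
segments; the verdict on such segments is carried by pSQI and kSQI instead.

## Fuzzy comprehensive evaluation

The four retained indices are mapped to membership triples
$r_i = (r_{iE}, r_{iB}, r_{iU})$:

* qSQI uses Cauchy-type functions: the Excellent membership is 0 up to 80,
  rises as $1/\{1+[0.3(q-80)]^{-2}\}$ on (80, 90) and continues as $q/100$ up
  to 100 — the 0.3 scale is exactly the value that makes the two branches
  meet at 0.9; the Barely-acceptable membership is a full Cauchy centred at
  75 with scale 7.5; the Unacceptable membership is 1 up to 55 and falls as a
  Cauchy with centre 55 and scale 5, so that it equals 0.5 at q = 60.
* basSQI (on the percent scale, $b = 100\,\mathrm{basSQI}$) uses the same
  shapes with centres 90/92/85, scales 0.8718/2.5/5; 0.8718 is again the
  continuity-enforcing scale at $b = 95$.
* kSQI is rectangular: $(1,0,0)$ above kurtosis 5, else $(0,0,1)$.
* pSQI uses trapezoids with breakpoints 0.15/0.25 (Unacceptable fall),
  0.25/0.35 (Excellent rise) and 0.18/0.22/0.28/0.32 (Barely-acceptable
  rise–plateau–fall).

The printed slope of the two outer pSQI trapezoids is 0.1 per unit, which
would make each function jump from 0.01 to 1 at its plateau — a
discontinuity that leaves pSQI effectively inert over its transition region.
Since continuity at branch points is the explicit design principle of the
Cauchy memberships (it is what fixes 0.3 and 0.8718), the package defaults to
`membership_mode = "continuity_corrected"`, slope 10, so the Excellent side
rises 0 to 1 across [0.25, 0.35] and the Unacceptable side falls 1 to 0
across [0.15, 0.25]. `membership_mode = "literal"` reproduces the printed
digits for comparison. Note also that these membership breakpoints
(0.15–0.35) are not the same numbers as the pSQI grading limits (0.3–0.8);
both sets are implemented as published in their respective pathways and the
package does not attempt to reconcile them.

The rows stack into a 4×3 matrix $R$, synthesised with weights
$W = (0.4, 0.4, 0.1, 0.1)$ by the weighted bounded-sum operator
$s_j = \min(1, \sum_i w_i r_{ij})$. Because the weights sum to 1 and
memberships are at most 1, the bound never truncates and the synthesis equals
the plain weighted mean — asserted as an algebraic property test. The scalar
decision score is the squared-weighted grade index

$$v = \frac{\sum_{j=1}^{3} j\, s_j^2}{\sum_{j=1}^{3} s_j^2}, \qquad
  j: \mathrm{E}=1,\ \mathrm{B}=2,\ \mathrm{U}=3,$$

thresholded at $v \le 1.50$ (E) and $v \ge 2.40$ (U). Squaring sharpens the
decision toward the dominant component relative to a plain weighted mean.

A consequence of the weight vector worth stating plainly: smooth baseline
wander alone, however heavy, can fail only kSQI and basSQI, whose combined
weight is 0.2; the decision score is then bounded near
$v \approx (0.8 + 3\cdot 0.2\cdot 0.2/0.8)/\ldots \approx 1.12$, so a
pure-drift segment is always rated E. This is a property of the published
weighting, not a bug, and it is why the synthetic "unacceptable drift" class
described below models electrode-*motion* wander (drift plus its broadband
transient component) rather than a bare slow sinusoid. A dedicated test
documents the bare-drift behaviour.

Degenerate windows (flatline, no detectable beats, zero power) make one or
more indices undefined; such windows are reported Unacceptable with `v = NA`
rather than crashing, and every undefined index grades `unqualified`.

## The heuristic alternative

`fuse_heuristic()` implements the fixed rule tables for 2–5 entered indices,
keyed on the counts of optimal/suspicious/unqualified grades (e.g. for four
indices: E requires at least three optimal and no unqualified; U requires at
least three unqualified, or two unqualified with any suspicious, or one
unqualified with three suspicious; everything else is B). The tables are
deliberately not optimised — they are fixed as published — and the test suite
proves them total and equivalent to a clause-by-clause transcription over the
full enumeration of grade tuples, and monotone under single-grade upgrades
for the four-index table.

## The synthetic generator

`generate_clean()` builds a quasi-periodic waveform from Gaussian-bump
P/Q/R/S/T components (R amplitude 1, width 10 ms; Q/S at -0.1/-0.2 with
widths 9 ms; P at 0.15 placed 0.2 RR before R; T at 0.35 placed 0.3 RR
after R with width growing with RR), with RR intervals jittered i.i.d. at a
configurable coefficient of variation and exact ground-truth R positions.
The QRS widths were chosen so that the clean template's band-power profile
matches real clean ECG against the published criteria (pSQI ~0.6–0.7,
kurtosis 8–13, basSQI ~1); they are package defaults, not per-experiment
knobs. `add_noise()` superimposes the four canonical noise classes — slow
sinusoidal baseline wander (0.05–0.5 Hz), a 50/60 Hz mains tone, EMG-like
noise band-passed to 20–40 Hz (inside the analysed 0–40 Hz band, where it
perturbs pSQI as muscle noise does), and white Gaussian noise — at
amplitudes expressed relative to the R amplitude.

`generate_dataset()` draws balanced classes with randomised heart rates
(72–110 bpm; below ~70 bpm the rhythm's 1 Hz fundamental leaks into the
basSQI numerator band and clean records start to look drifty — an edge case
of the index, not of the generator) and class mixtures:

* **E**: trace noise only (every amplitude under 0.05).
* **B**: moderate Gaussian noise (0.25–0.45) with a touch of drift — enough
  to unsettle detector agreement and kurtosis without destroying the trace.
* **U**: either EMG-dominant composite corruption (EMG 0.8–1.2 over a
  wideband + drift floor) or electrode-motion wander (drift 1.6–2.6 with
  broadband components). Both mixtures reflect how unacceptable ambulatory
  records actually fail; single-class noise at moderate amplitude tends to
  land in B, consistent with the weighting analysis above.

What the generator does *not* emulate: pathological rhythms, nonstationary
noise bursts, amplitude modulation, electrode pops, or real QRS morphology
variety. Passing tests on this generator therefore demonstrate that the
indices, memberships and fusion behave as specified under controlled
conditions — not that the published field accuracies transfer to any
particular clinical dataset.

## The evaluation harness

`cross_validate()` runs repeated stratified 10-fold cross-validation (10
repeats by default) of either fusion method against construction-time
labels, binarising E/B as acceptable and U as unacceptable (configurable).
The classifiers have no trainable parameters, so folds are evaluation
subsets; per-fold sensitivity/specificity/accuracy are averaged per repeat
and then across repeats. Records are ordered canonically by id before
folding, so results do not depend on list order. `weight_sweep()` re-scores
stored SQI vectors under candidate weight vectors without re-running the
detectors; `roc_over_v()` traces sensitivity/specificity over a grid of
decision thresholds in [1, 3].

```{r example, eval = FALSE}
ds <- generate_dataset(10, seed = 42)
cv <- cross_validate(ds, method = "fuzzy", repeats = 3, seed = 42)
glance(cv)
autoplot(roc_over_v(ds))
```

Test-suite problem sizes (30 s records at 300 Hz, 20–60 record datasets,
2–5 CV repeats) were chosen so the whole suite exercises every pathway in
well under a minute; the harness scales linearly in records and repeats.

## Numerical and design notes

* Spectra come from an averaged periodogram (Welch): 8 s Hann windows, 50%
  overlap, each window demeaned before tapering. The grid step of 0.125 Hz
  resolves the 0–1 Hz basSQI numerator band; band integrals are trapezoidal
  with interpolated band edges. Demeaning makes the band indices invariant
  to a constant offset — a DC level is an amplifier property, not baseline
  wander — and a test pins that invariance.
* RR statistics use the sample (n−1) standard deviation; the RR series and
  heart rate come from the Hilbert detector by default (configurable).
* Heart rates outside the two published pSQI bands (60–130, 130–160 bpm) use
  the nearest band's limits with a logged warning.
* WFDB support covers the PhysioNet dialect needed in practice here: formats
  16 and 212, gain/baseline conversion to physical units. CSV records are a
  single numeric column with an optional header line.
* Records containing NaN/Inf are rejected by default;
  `na_action = "interpolate"` repairs isolated gaps linearly.
* All randomness (synthesis, noise, fold assignment) flows from explicit
  integer seeds; identical seeds give bit-identical records and results.

## Known limitations

* The qSQI chance-agreement floor under dense spurious detections (above)
  means detector agreement alone cannot condemn stationary-noise segments.
* cSQI is computed but unused by the fuzzy engine; rhythm pathologies
  (e.g. atrial fibrillation) will elevate cSQI on genuinely clean signals,
  which is a quality/rhythm confound the method does not address.
* The fuzzy weighting cannot rate bare smooth drift as Unacceptable (weight
  analysis above); downstream users for whom heavy drift is disqualifying
  should gate on `grade_bassqi` directly.
* Multi-lead records are processed one lead at a time; there is no
  cross-lead fusion, no annotation-file parsing, and no streaming mode.
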