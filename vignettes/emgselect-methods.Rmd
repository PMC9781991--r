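---
title: "Methods: wrapper feature selection for surface-EMG movement classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrapper feature selection for surface-EMG movement classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emgselect)
```

## The problem and the procedure

Surface EMG measures the electrical activity of contracting muscle through
skin electrodes. A myoelectric movement classifier receives a few bipolar
channels of such activity, cuts them into short overlapping analysis
windows, summarizes each window by time-domain statistics, and predicts
which movement produced it. With 26 predictors over 4 channels the feature
space already has 104 columns, many redundant or uninformative; the
package's core is the *wrapper* search over binary column masks, scored by
the cross-validated error of the downstream classifier itself, with a
binary genetic algorithm (GA) and a binary particle swarm optimizer (BPSO)
as the two search engines.

The pipeline, in order:

1. **Band-pass filtering.** Causal fourth-order Butterworth, 10–500 Hz.
   The realized band-pass order is four (an order-2 low-pass prototype),
   and the filter is applied in a single causal pass rather than
   forward–backward: it stands in for the analog acquisition chain, whose
   phase response is also causal, and keeps the effective order the stated
   one. At 1 kHz sampling the upper cutoff sits exactly at Nyquist, which
   is not designable; it is clipped to 0.99 × fs/2 with a warning.
2. **Segmentation.** Windows of 250 ms with 190 ms overlap (60 ms step),
   converted to samples by `round(ms * fs / 1000)`. A signal of *N* usable
   samples yields ⌊(N − W)/S⌋ + 1 full windows; trailing samples are
   discarded, and no padding is ever applied.
3. **Feature extraction** into labelled matrices, in two forms: one row per
   recording (whole-signal features, the cheap surrogate on which selection
   runs) and one row per window (on which the final classifier is trained
   and evaluated). Columns are channel-major: all predictors of channel 1,
   then channel 2, and so on.
4. **ANOVA prescreen** (optional, per database): per-column one-way ANOVA
   across movement classes; predictors whose class means are
   indistinguishable are eliminated whole.
5. **Wrapper selection** by GA or BPSO, minimizing the stratified 10-fold
   cross-validated mean error of a one-vs-all SVM on the masked columns.
6. **Final classification and evaluation** on windows, with per-class
   confusion metrics, macro averages, and a leave-one-feature-out
   sensitivity analysis of the selected subset.

## Assumptions

- Class information lives in per-channel amplitude statistics and waveform
  complexity, i.e. the time domain; no spectral features are computed
  (deliberately out of scope — they are the natural extension).
- Each recording carries exactly one movement, preceded by a known rest
  period; the movement phase is located by configurable start/end trims,
  not detected.
- The whole-signal feature distribution is similar enough to the per-window
  distribution that selection on whole signals transfers to window
  classification. This is the surrogate assumption the original experiments
  relied on; the pipeline makes it explicit and configurable rather than
  implicit.

## The feature set and its numerical conventions

Every predictor is documented with its closed form at the top of
`R/features.R`. Choices that the abbreviations alone do not pin down:

- **Thresholded counters.** ZC and SSC default to threshold 0 (pure
  sign-change counts, gain-invariant, with strict inequality for SSC so a
  flat segment is not a slope change); WAMP and MYOP default to 0.02 in
  normalized amplitude units. All four are configurable via `td_options()`.
- **VAR** uses the zero-mean EMG convention Σx²/(N−1), while **STD** is the
  ordinary sample standard deviation about the mean — both are common in
  the EMG feature literature and they are deliberately not redundant.
- **MAVSLP** splits the window into 3 equal segments and reduces the
  consecutive MAV differences to their mean, so it contributes one scalar
  and the 26 × channels column grid stays rectangular.
- **AAV** is implemented as the mean absolute value of the differenced
  signal scaled by the window length (Σ|Δx|/N), distinct from AAC
  (Σ|Δx|/(N−1)).
- **FC** is the Higuchi fractal dimension with k_max = 8; **SE** is sample
  entropy with m = 2 and r = 0.2 × SD. These are the most common
  conventions behind the abbreviations "fractals" and "entropy"; other
  estimators exist, the exact original choice is not recoverable, and both
  are configurable. Both are gain-invariant, O(N·k_max) and O(N²)
  respectively, and implemented in C++ (`src/td_extra.cpp`). Degenerate
  sample entropy (no template matches) is capped at the conventional
  −log(2/((N−m−1)(N−m))) bound so the result is always finite.
- **LOG** adds 1e−12 inside the logarithm so exact zeros do not produce
  −∞.

## Prescreen aggregation

The elimination granularity is the *predictor*, not the column: a
predictor leaves across all channels at once, so eliminating p predictors
removes `channels × p` columns (6 predictors → 24 of 104 columns in the
full grid). The per-channel p-values are aggregated by their median, i.e. a
predictor is eliminated when it fails the ANOVA on at least half of its
channels. The original procedure removed whole predictors but never stated
the per-channel rule; the median is the symmetric choice that neither lets
one lucky channel rescue a dead predictor nor one noisy channel kill an
informative one. Prescreening is optional per database (the original
analysis applied it to one database and not the other).

## Classifier, fitness, and their defaults

- **One-vs-all decomposition.** One binary soft-margin SVM per class;
  prediction by maximal decision value, exact ties broken toward the
  lowest class index, so prediction is deterministic. The binary QP is
  solved by libsvm (e1071); the decomposition, standardization and
  orientation of decision values are the package's.
- **Standardization** (z-score with training-fold statistics) is on by
  default: SSI and ZC differ by orders of magnitude and kernel SVMs are
  scale-sensitive. Columns with zero variance get scale 1.
- **Hyperparameters.** C = 1; Gaussian γ defaults to
  1/(n_features × var(x)) computed on the standardized training data
  (≈ 1/n_features). The original experiments do not report C or a kernel
  width; these are the widely used library defaults, and both are
  configurable — the package treats them as inputs, not tuned constants.
- **Cross-validation.** Stratified k-fold (default k = 10) with an
  explicit seed; folds are dealt per class after a seeded shuffle, so they
  are disjoint, exhaustive and balanced within class. Every class must
  have at least k rows.

## The selectors

Both selectors minimize the same cached fitness: the CV mean error of the
masked matrix, with the fold seed fixed for the whole run so the landscape
is static, and the all-zero mask scored 1.0 (unclassifiable) without an
SVM fit.

**GA.** Population of Bernoulli(0.5) masks; roulette-wheel selection on
weights (max error − error) + 1e−6 (roulette needs non-negative weights
that favour low error; the transform is the standard minimization
adaptation), two-point crossover applied to every selected pair (crossover
rate 1.0, configurable — the "simple GA" convention), uniform per-gene
mutation (default 2 %), and generational replacement with elitism of 1.
Elitism is what makes the best-so-far history monotone non-increasing, the
behaviour the original convergence plots display; the replacement scheme
and crossover probability were unstated, and these are the plain
simple-GA conventions. Early stopping on a target error is supported but
disabled by default (the original stop threshold was never quantified).

**BPSO.** Velocities start at 0, positions Bernoulli(0.5) (symmetric and
unbiased); r₁, r₂ are drawn per dimension per update, as is r₃ in the
position rule; velocities are clamped to ±6, where the sigmoid is within
0.0025 of saturation — the standard BPSO practice that keeps bit-flip
probabilities away from hard 0/1. The global best is replaced only by a
strictly better mask, so its history is monotone by construction. The
original comparison is ambiguous about which kernel produced which average
error; the kernel is a free configuration here and the package takes no
side.

Both run logs and masks serialize to the same CSV schema (a `selector`
column distinguishes them), and `exhaustive_mask_search()` provides the
brute-force oracle used to verify both engines on small instances.

## Splits and leakage

Selection runs on a stratified 70 % of the *recordings* (whole signals);
window-level training uses a configurable fraction (25 % in the arm-style
configuration, 70 % in the leg-style one) of the *repetitions*, and all
windows of one repetition stay on one side of the split. Overlapping
windows share up to 76 % of their samples, so a window-level random split
would leak training data into validation; the repetition-level split is
stricter than the original description, which does not discuss the issue.

## The synthetic generator

No public accession exists for the original recordings, so the package
ships a generator that emulates their *structure*: the full factorial of
subjects × movements × repetitions, 4 channels, 1 or 1.5 kHz, fixed
durations with an initial rest lead. Each channel is Gaussian white noise
band-passed to 10–500 Hz, multiplied by `baseline + activation ×
trapezoid(t)`, where the trapezoid ramps over 0.25 s of the movement phase
and the activation comes from a fixed class→channel map (each non-rest
class drives a primary channel at gain 1, a secondary at 0.4, the rest at
0.1; the rest class stays at baseline 0.05 throughout). A per-subject
log-normal gain (σ = 0.1) makes cross-subject pooling non-trivial and a
per-repetition gain (σ = 0.05) adds trial-to-trial variability. Amplitudes
are unit-scaled by decision: the original recordings' units and dynamic
range are not characterized anywhere, so 0.02-level thresholds (WAMP,
MYOP) are stated in these normalized units.

What this emulates well: the factorial design, band-limited spectra,
class- and channel-dependent envelopes, rest-vs-movement contrast, and
realistic relative magnitudes of the time-domain features. What it does
not: motor-unit physiology, electrode placement and crosstalk, hardware
noise, non-stationarity within a movement, or inter-class confusability —
synthetic classes are separable by construction. Passing tests therefore
demonstrate that the machinery is correct (shapes, invariances, optima,
recovery of informative columns), not that any particular accuracy level
transfers to real EMG.

## Known discrepancies in the published arithmetic

Three places where the printed record is internally inconsistent; the
package implements the formulas and lets the configuration carry the
ambiguity:

- The stated window counts (64 windows from a 7 s / 1 kHz recording, 147
  from 8 s / 1.5 kHz) do not follow from 250/190 ms windows over the
  stated durations. The count formula is exact and property-tested; the
  effective trim is configurable, and the 64-window case corresponds to a
  4.03 s movement segment (trims of 1.0 s and 1.97 s on the 7 s
  recording). The 147-window case would need ≥ 9.01 s of signal and is
  unreachable inside an 8 s recording.
- The unsegmented reduced matrix is printed as 1120 × 80 with "four
  channels × 24 features"; 80 columns are 4 channels × 20 retained
  predictors (26 − 6), and 24 is the number of *columns* removed.
- One published macro-average (the PSO training accuracy) cannot be
  recomputed from its own per-class table; the bundled fixtures carry the
  table values, and the acceptance suite documents the exclusion rather
  than resolving it.

## Problem sizes used by the test and acceptance suites

The structural acceptance check generates the full-size synthetic database
(8 subjects × 7 movements × 20 repetitions, 4 channels at 1 kHz for 7 s)
and extracts both the 1120 × 80 whole-signal matrix and the 71 680 × 80
window matrix. Selector-vs-oracle equivalence runs on 5–6 column instances
(31–63 masks, exhaustively enumerable), statistical properties on
10⁴-draw Monte-Carlo samples with 3σ bands, and chance-level
cross-validation on 150 rows over 5 shuffled classes. These sizes make
every stochastic assertion sharp at a fixed seed while keeping the default
test run in the order of a minute or two.

## Limitations

- Time-domain features only; no spectral or time–frequency descriptors.
- No probability calibration, ROC analysis, or statistical comparison
  tests between selectors.
- The GA and BPSO are the canonical simple variants; no adaptive rates,
  constriction factors, or multi-objective formulations.
- Real-data performance claims are outside what the synthetic conditions
  can support; the package verifies arithmetic, invariances and recovery,
  and reproduces published table arithmetic exactly.
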