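# emgselect

Movement classification from multi-channel surface electromyography (EMG)
with wrapper feature selection. The package is aimed at myoelectric-control
and biomedical signal-processing work: given repeated recordings of limb
movements (e.g. foot or hand gestures) over a few bipolar EMG channels, it
builds a classifier of the movement performed in each overlapping analysis
window, and — its core purpose — searches for the small subset of
time-domain features that classifies best.

## What it implements

**Preprocessing.** Causal fourth-order Butterworth band-pass (10–500 Hz,
clipped below Nyquist when necessary) and overlapping-window segmentation
(250 ms windows, 190 ms overlap by default); a signal of *N* samples with
window *W* and step *S* yields ⌊(N − W)/S⌋ + 1 windows.

**Features.** The 26 classical time-domain predictors per window and
channel — MAV, RMS, VAR, STD, IEMG, SSI, WL, AAC, AAV, DASDV, ZC, SSC,
WAMP, MYOP, LOG, MMAV1/2, MAVSLP, kurtosis, skewness, MAD, the absolute
3rd–5th moments, Higuchi fractal dimension and sample entropy — assembled
into labelled matrices with channel-major columns (channels × predictors).

**Prescreen.** Per-column one-way ANOVA across movement classes; a
predictor whose class means are indistinguishable (median p across its
channels > α = 0.05) is eliminated whole, removing `channels` columns at a
time.

**Classifier and fitness.** One-vs-all soft-margin SVM (linear or Gaussian
kernel), features z-scored with training statistics, prediction by maximal
decision value. The selection fitness is the stratified k-fold (k = 10)
cross-validated mean misclassification error.

**Selectors.** Over binary feature masks m ∈ {0,1}^p, minimizing CV error
E(m):

- *Genetic algorithm* — roulette-wheel selection (weight
  (max E − E) + ε), two-point crossover, uniform per-gene mutation,
  elitism of 1.
- *Binary PSO* — velocity update
  v′ = w·v + c₁r₁(pbest − x) + c₂r₂(gbest − x), sigmoid transfer
  S(v) = 1/(1 + e^(−v)), bit set to 1 iff S(v) > r₃, velocities clamped to
  ±6.

**Evaluation.** Per-class one-vs-rest confusion counts with
Accuracy = (TP+TN)/(TP+TN+FP+FN), Sensitivity = TP/(TP+FN),
Specificity = TN/(TN+FP) and Efficiency = (Accuracy + Sensitivity +
Specificity)/3, their unweighted macro averages, and a
leave-one-feature-out sensitivity analysis reporting the accuracy change
Y₂ − Y₁ and the percentage change (Y₂ − Y₁)/Y₁ × 100 per removed feature.

**Synthetic data.** A seeded generator of databases with the structure of
the real experiments (subjects × movements × repetitions, 4 channels,
1–1.5 kHz, fixed rest lead): band-limited Gaussian noise amplitude-modulated
by a class- and channel-specific trapezoidal envelope, with log-normal
subject and repetition gains.

## Worked example

```r
library(emgselect)

spec <- database_spec(n_subjects = 4, movements = c("FB", "EB", "FD", "RR"),
                      n_reps = 10, n_channels = 4, fs = 1000,
                      duration = 3, rest_lead = 0.5, seed = 7)
db <- generate_database(spec)
db <- lapply(db, bandpass)                      # 10-500 Hz Butterworth

fm <- extract_features(db, trim_start = 0.5)    # whole-signal features
fm
#> Feature matrix: 160 rows x 104 columns ( 4 channels x 26 predictors ), 4 classes

ps <- anova_prescreen(fm, alpha = 0.05)
ps
#> ANOVA prescreen (alpha = 0.05 ): 5 of 26 predictors eliminated
#>  eliminated: FC, SK, ZC, MAVSLP, SSC
fm <- apply_prescreen(fm, ps)

run <- run_ga(fm, spec = svm_spec("gaussian"),
              config = ga_config(n_genes = ncol(as.matrix(fm)),
                                 pop_size = 20, mutation_rate = 0.02,
                                 max_iterations = 8, seed = 1), k = 5)
run
#> GA feature selection: 35 of 84 features kept; best CV mean error 0.0000
#> after 8 iterations (151 CV evaluations)

fm_win <- extract_features(db, fm$predictors,
                           wspec = window_spec(250, 190), trim_start = 0.5)
fm_win <- select_columns(fm_win, run$best_mask)
model <- ova_svm(fm_win, spec = svm_spec("gaussian"))
evaluate_model(model, fm_win)
#> Per-class performance (6080 observations):
#>  class   TP   TN FP FN accuracy sensitivity specificity efficiency
#>     EB 1520 4560  0  0  100.00%     100.00%     100.00%    100.00%
#>     FB 1520 4560  0  0  100.00%     100.00%     100.00%    100.00%
#>     FD 1520 4560  0  0  100.00%     100.00%     100.00%    100.00%
#>     RR 1520 4560  0  0  100.00%     100.00%     100.00%    100.00%
#> Macro averages: accuracy 100.00%, sensitivity 100.00%, specificity 100.00%, efficiency 100.00%
```

The ANOVA step eliminates the predictors that carry no class signal on
this synthetic database (which ones depends on the seed and the generator's
envelope model); the GA then halves the remaining columns at zero
cross-validated error, and the final window classifier is perfect —
expected here, because the synthetic classes are separable by construction.
On real EMG the same pipeline produces per-class efficiencies in the
80–97 % range; see the methods vignette for what the synthetic conditions
do and do not exercise.

`run_pipeline(config, out_dir)` chains all of the above from one (YAML)
configuration — see `inst/configs/` for full-size experiment configs — and
`inst/cli/emgselect.R` exposes each stage as a shell subcommand
(`synth`, `features`, `prescreen`, `select`, `train`, `evaluate`,
`sensitivity`, `report`, `pipeline`).

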