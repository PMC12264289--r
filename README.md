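# pulseco

Cardiac output (CO) estimation from the shape of a single cardiac cycle of
arterial pressure, reproduced end to end as an in silico study in R.

Noninvasive CO monitoring from applanation tonometry is attractive because
a peripheral pressure waveform is cheap to acquire, but classic pulse-wave
analysis needs physiological assumptions and calibration. The alternative
studied here is physiology-agnostic: train a compact 1D convolutional
network to map a fixed-length (150-point) single-cycle pressure waveform —
in absolute mmHg ("calibrated") or rescaled to unit range
("uncalibrated") — directly to CO, and ask whether the measurement site
(left common carotid, left superficial temporal or left radial artery),
the calibration state, or added measurement noise changes the achievable
accuracy.

The package provides every stage as tested, seeded functions:

* **Virtual cohort** (`population_config()`, `generate_population()`):
  a two-subpopulation cohort (normodynamic n = 2620, CO 5.5 ± 1.0 L/min;
  hyperdynamic n = 1198, CO 6.9 ± 1.0 L/min) with ascending-aortic cycles
  from a three-element Windkessel
  (`C dP/dt = Q − (P − P_ven)/R`, `P_ao = P_wk + Z_c Q`, half-sine
  ejection) propagated to the three tonometry sites through a tube-load
  transmission line `H(ω) = (1+Γ)e^{−(jω/c+α)L} / (1+Γe^{−2(jω/c+α)L})`.
* **Preprocessing** (`wave_matrix()`, `resample_to_fixed_length()`,
  `normalize_amplitude()`): 150-point resampling and 0–1 amplitude
  normalization.
* **Noise injection** (`inject_noise()`): Gaussian noise on every point
  plus uniform spikes (10% of signal maximum) on a random 20% of points.
* **Cohort structure** (`fit_two_component_gmm()`,
  `group_difference_tests()`): hand-implemented two-component EM on
  (CO, MAP) plus Shapiro–Wilk and Mann–Whitney tests.
* **Regressor** (`build_cnn()`, `train_model()`, `predict_co()`,
  `tune_hyperparameters()`): conv–BN–ReLU ×2 → maxpool → dropout → dense,
  written directly on BLAS matrix ops with manual backprop and Adam;
  Bayesian (GP + expected-improvement) hyperparameter search scored by
  stratified 5-fold CV.
* **Agreement statistics** (`agreement_report()`,
  `fisher_z_paired_test()`, `coefficient_of_variation()`): Pearson r,
  nRMSE (% of reference range), MAE, Bland–Altman bias and 95% limits of
  agreement, OLS slope/intercept.
* **Experiment grid** (`run_experiment()`, `export_report()`): the full
  3 sites × {calibrated, uncalibrated} × {clean, noisy} pipeline with one
  shared stratified 60/20/20 split (2290/764/764 at full size), noisy
  conditions reusing the matched clean hyperparameters. A thin CLI wrapper
  lives at `inst/cli/pulseco.R`.

## Worked example

```r
library(pulseco)

pop   <- generate_population(population_config(scale = 1500/3818, seed = 11))
X     <- wave_matrix(pop, "left_common_carotid", calibrated = FALSE)
y     <- pop$params$cardiac_output
split <- stratified_split(pop$params$group, c(0.6, 0.2, 0.2), seed = 5)

m <- build_cnn(model_hyperparameters(max_epochs = 120), seed = 7)
m <- train_model(m, X[split$train, ], y[split$train],
                 X[split$validation, ], y[split$validation], seed = 9)
agreement_report(predict_co(m, X[split$test, ]), y[split$test])
#> <agreement_report> n = 300
#>   r 0.973 | nRMSE 3.7% | MAE 0.21 | bias 0.01 [LoA -0.52, 0.54]
#>   slope 0.90, intercept 0.59 (slope p 1.1e-190)
```

That is: on a 1500-subject cohort, a CNN fed only the *shape* of the
carotid cycle (no absolute pressures, no heart rate) recovers CO on the
untouched holdout with Pearson r = 0.97, a mean absolute error of
0.21 L/min, negligible bias, and 95% limits of agreement of about
±0.5 L/min.

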