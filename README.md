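# specfuse

Feature-fused spectral classification for laser-induced breakdown
spectroscopy (LIBS).

LIBS spectra — intensity versus wavelength across element-specific
emission lines — carry a geochemical fingerprint of where an agricultural
product grew, but that fingerprint is buried under instrumental variance:
pellet-to-pellet gain and baseline differences, shot-to-shot plasma
fluctuation, detector noise. `specfuse` is a toolkit for origin
classification in this setting, built around a feature-fused 1D
convolutional network and aimed at analytical chemists and chemometricians
who want the full pipeline — simulation, preprocessing, models,
interpretability, robustness — in one reproducible package.

The core method, for a spectrum with wavelengths λ and intensities I on a
fixed grid of N channels:

1. **Leakage-safe global scaling.** From training records only,
   V<sub>min</sub> = min(min λ, min I) and V<sub>max</sub> = max(max λ,
   max I); both axes are mapped by x′ = (x − V<sub>min</sub>) /
   (V<sub>max</sub> − V<sub>min</sub> + ε). Held-out spectra reuse the
   frozen boundaries and are never clipped.
2. **Feature fusion.** S<sub>fused</sub> = λ′ + I′ (elementwise), then
   four statistical descriptors are appended: peak count N<sub>p</sub>
   (strict local maxima above 0.8·max I′), mean peak intensity
   μ<sub>p</sub>, global mean μ, and population standard deviation σ —
   giving F ∈ R<sup>N+4</sup>.
3. **Classification.** A 1D CNN (three conv blocks of 64/128/256 channels,
   kernel 3, ReLU → batch-norm → max-pool; dense 256/128 with dropout
   0.3/0.2) trained with Adam (1e-4), batch 32, cosine annealing —
   implemented from scratch in single-precision C++ — alongside tuned
   shallow baselines (random forest, weighted-Minkowski KNN, PLS-DA,
   XGBoost) with a built-in Tree-structured Parzen Estimator search.
4. **Interpretability.** 1D Grad-CAM++ (closed-form α weights
   g²/(2g² + ΣA·g³), map ReLU(Σ<sub>k</sub> w<sub>k</sub>A<sub>k</sub>))
   resolved on the wavelength axis with cross-sample mean ± sd stability
   curves, and exact/sampled Shapley attribution for the shallow models on
   the top-10 peak channels.
5. **Evaluation.** Stratified 10 % holdout + 5-fold cross-validation,
   accuracy and macro-F1, SNR-swept white-noise stress testing of
   clean-trained models, and unsupervised embedding diagnostics (PCA,
   t-SNE, UMAP with silhouette and Davies–Bouldin scores).

Because the reference coffee spectra are available only on request, the
package ships a synthetic LIBS simulator driven by ICP-MS elemental
concentrations for four origins (Kenya, Ethiopia, Colombia, Yunnan) and a
21-line Fe/Cr/Cu/Na/K library, with pellet-level and shot-level nuisance
structure. Two presets fix the study conditions: `"separable"` (mild
nuisance) and `"confounded"` (nuisance dominates unsupervised structure).

## Worked example

```r
library(specfuse)

# 4 origins x 2 pellets x 10 spectra on a reduced 1536-channel grid
spec <- preset_dataset_spec("separable", seed = 42,
                            pellets_per_origin = 2, spectra_per_pellet = 10)
spec$acquisition$n_channels <- 1536L
records <- generate_dataset(spec)

labels <- dataset_labels(records)
splits <- make_splits(labels, split_spec(seed = 42))
scaler <- fit_global_scaler(records[splits$dev])   # training records only
feats  <- featurize_records(records, scaler)        # 80 x 1540

model <- build_cnn(cnn_config(input_length = ncol(feats)), init_seed = 1)
model <- train_cnn(model, feats[splits$dev, ], labels[splits$dev],
                   train_config(epochs = 25, seed = 1))

report <- evaluate_predictions(labels[splits$holdout],
                               predict(model, feats[splits$holdout, ]))
report
```

```
accuracy 1.0000 | macro F1 1.0000 (n = 8)
row-normalized confusion matrix:
          pred
true       Colombia Ethiopia Kenya Yunnan
  Colombia        1        0     0      0
  Ethiopia        0        1     0      0
  Kenya           0        0     1      0
  Yunnan          0        0     0      1
```

Every held-out spectrum is assigned to its true origin (the separable
preset at this size is an easy problem; the confusion matrix rows are
true-origin fractions summing to 1). Robustness of the same clean-trained
model under added white noise:

```r
stress_test(list(model), records[splits$holdout], scaler,
            noise_spec(c(Inf, 40, 30, 20), seed = 1))
```

```
  snr_db mean_acc sd_acc
1    Inf        1     NA
2     40        1     NA
3     30        1     NA
4     20        1     NA
```

On this easy preset the model is noise-stable down to 20 dB (sd is NA
with a single model; pass the five fold models for mean ± sd — harder
presets show the expected degradation). Wavelength-resolved attribution
for one held-out spectrum:

```r
cam <- grad_cam(model, feats[splits$holdout[1], ],
                class_index = labels[splits$holdout[1]])
head(sort(cam$upsampled, decreasing = TRUE))
#> [1] 118.41971  92.23179  91.75162  91.57076  91.38991  91.20906
```

The largest activations sit on the discriminative emission lines; pair
with `summarize_cam()` for per-class mean ± sd curves, and
`shapley_attribution()` with `select_top_features()` for the shallow
models.

The command-line surface wraps the same functions:

```sh
Rscript inst/cli/specfuse.R simulate --seed 42 --preset separable --out out/
Rscript inst/cli/specfuse.R train    --seed 42 --out out/
Rscript inst/cli/specfuse.R stress   --seed 42 --out out/
```

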