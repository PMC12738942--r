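# grazspec

Classification of grassland **grazing intensity** — no grazing (NG), light
(LG), moderate (MG), severe (SG) — from fused UAV observations: three
visible digital-number channels (R, G, B) and four multispectral
reflectance channels (green, red, red edge, near infrared). The package is
aimed at rangeland remote-sensing analysts who have co-registered band
tables or raster stacks and want a reproducible, auditable path from raw
bands to a classified grazing-intensity map.

## What it implements

* **Spectral-index fusion.** Chromatic-coordinate normalization of the
  visible bands (`r = R/(R+G+B)`, …) and a registry of 24 indices:
  4 conventional visible (ExG, VARI, ExGR, RGBVI), 6 conventional
  multispectral (NDVI, GNDVI, SAVI, MSAVI, NDRE, EVI2) and 14
  purpose-built fusion indices (`idx1`–`idx14`, e.g.
  `idx7 = (b − RE)/(b + RE)`).
* **Separability analytics.** Per-class means/variances, one-way ANOVA
  with Tukey HSD comparisons, and the pairwise M-statistic
  `M = |x̄₁ − x̄₂| / √(s₁² + s₂²)` for all six class pairs.
* **AIFS — automatic incremental feature selection.** Random-forest
  out-of-bag permutation importance `I_j = (1/T) Σ_t ΔErr_OOB(t, j)`
  ranks the features; candidates are then accepted incrementally iff
  (1) their absolute Pearson correlation with every selected feature is
  ≤ 0.8 and (2) the stratified 5-fold cross-validated overall accuracy of
  a gate classifier strictly improves. Every decision is recorded and
  `replay_aifs()` re-derives the full trajectory as an audit.
* **SPXY partitioning and classifiers.** Kennard–Stone selection on joint
  X–Y distances (70/30 by default), then grid-searched KNN, RBF-SVM and
  random-forest models with z-score standardization; evaluation by
  overall accuracy and Cohen's kappa `κ = (p_o − p_e)/(1 − p_e)`.
* **Mapping.** Per-pixel classification of band stacks, nodata handling,
  ROI sample extraction (pixel-center rule), and 3×3 categorical mode
  filtering.
* **Synthetic study generator.** A balanced 720-sample, 4-class scenario
  (plus raster scenes) whose class-conditional band structure follows the
  documented grazing responses, so the entire pipeline is testable
  without field data.

## Worked example

```r
library(grazspec)

scenario <- synthetic_scenario(seed = 42)      # 720 samples, 180 per class
samples  <- generate_samples(scenario)
features <- build_feature_matrix(samples, indices = "all")

sel <- incremental_select(features,
                          rank_importance(features, n_trees = 500, seed = 42),
                          seed = 42)
print(sel)
#> AIFS result
#>   rho_thresh = 0.8, 5-fold CV, gate = rf
#>   selected 6 / 24 features (best CV OA = 0.8875):
#>     SAVI, idx7, idx10, idx9, idx13, NDRE
#>   decisions: accepted=6, rejected_correlation=9, rejected_no_gain=9

split <- spxy_split(features, train_fraction = 0.7)   # 504 train / 216 test
fm    <- select_features(features, sel$selected)
model <- fit_classifier(subset_rows(fm, split$train_indices),
                        model_spec("svm_rbf", seed = 42))
report <- evaluate(model, subset_rows(fm, split$test_indices))
print(report)
#> Classification report (svm_rbf)
#>   n = 216, OA = 0.9352 (93.52%), Kappa = 0.9062 (90.62%)
#>   confusion matrix (rows = reference):
#>          predicted
#> reference NG LG MG SG
#>        NG 17  1  0  0
#>        LG  1 39  0  0
#>        MG  0  0 70  5
#>        SG  0  0  7 76
```

Reading the output: AIFS kept 6 of the 24 fused indices — the rest were
either too correlated with an already-selected index (|ρ| > 0.8) or did
not improve cross-validated accuracy. The grid search settled on an RBF
kernel scale of 2 and C = 1; on the held-out SPXY test set the model
reaches 93.5% overall accuracy with κ = 0.906, and the confusion matrix
shows the residual errors concentrated between the adjacent MG/SG classes
— the hard boundary in this problem. (SPXY assigns boundary-spanning
samples to training first, so the test set is deliberately not
class-balanced.)

`run_pipeline(default_config(seed = 42))` drives the same stages end to
end from one configuration object, optionally adding the separability
report and a classified raster scene; `inst/cli/grazspec.R` is a thin
command-line wrapper around it.

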