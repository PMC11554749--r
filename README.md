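# afmicell

Label-free single-cell phenotyping from autofluorescence multispectral
images of cultured mesenchymal stromal cells (MSCs).

## The problem

MSC cultures are heterogeneous: cells in one dish differ in stemness
(STRO-1), spontaneous osteogenic differentiation (alkaline phosphatase),
replicative senescence (SA-β-gal), cell-cycle status, and in how many
population doublings they have left before growth arrest. These states
are normally read out by destructive staining. A cell's endogenous
fluorophores (NAD(P)H, flavins, lipofuscin, matrix proteins) shift with
metabolic and replicative state, so imaging the same field under many
excitation/emission combinations — 47 spectral channels here — yields a
per-pixel autofluorescence data cube that reports the same biology
without labels.

`afmicell` implements the full analysis chain for such data:

* **io**: multi-page TIFF + JSON-sidecar cubes, 16-bit label masks,
  CSV labels and reference spectra, and the canonical 47-channel
  excitation/emission table (`default_channel_table()`).
* **preprocess**: cosmic-ray removal (robust 3×3 z-test), low-rank +
  CDF 9/7 wavelet denoising, background subtraction, polynomial
  flat-field correction, and reference-fluid calibration
  (gain_k = reference_k / (measured_k − water_k)).
* **cell_features**: per-cell intensity statistics, GLCM texture,
  morphology, DNA-content and stain-positivity gating, and table
  assembly with an |r| > 0.95 correlation filter.
* **modeling**: z-scoring, MRMR (MIQ) feature selection, PCA followed
  by a regularised linear discriminant embedding, ADASYN/down-sampling,
  linear/polynomial SVM and LDA classifiers, stratified cross-validated
  ROC/AUC with Youden-point sensitivity/specificity, and a
  Kruskal–Wallis line-heterogeneity check.
* **growth_potential**: doubling labels from passage logs, per-class
  half-sample withholding, the coarse-KNN rule (among a test point's
  k = 400 nearest training points in LD space, assign the label whose
  members have the smallest mean distance), 30-repeat median aggregate
  scoring with empirical 95% prediction intervals, RMSPE/MAE, a k-sweep,
  and k-means age clustering.
* **synthetic_data**: a seeded generator (`afmi_scenario()`,
  `simulate_cells()`, `render_field()`, `null_scenario()`) that emulates
  the statistical structure of the imaging data — endmember-mixture
  spectra, a monotone aging drift with large within-class heterogeneity,
  line offsets, hypertrophic senescent morphology, flat-field,
  Poisson/read noise and cosmic rays — so every stage is testable with
  known ground truth.
* **pipeline**: `cmd_simulate()` … `cmd_report()` stage functions with
  config hashing and deterministic manifests, plus a thin CLI at
  `inst/cli/afmicell`.

## Worked example

```r
library(afmicell)

## classification benchmark: 10 of 47 channel means shifted by 1 SD
bench  <- simulate_channel_shift(n = 300, n_shifted = 10, shift_sd = 1, seed = 1)
report <- crossvalidate(bench$features, bench$labels,
                        classifier = classifier_spec("linear_svm"), seed = 1)
report
#> <evaluation_report> linear_svm (none resampling), 5 folds
#>   AUC  0.969 +/- 0.013
#>   sens 0.947 +/- 0.061   spec 0.893 +/- 0.072  (Youden)

## growth potential on the default aging scenario (~22 doubling classes)
sim    <- simulate_cells(afmi_scenario(seed = 1))
X      <- sim$features[, grep("^(ch|morph)", names(sim$features))]
dr     <- sim$cells$doublings_remaining
growth <- evaluate_doublings(X, dr, k = 400, repeats = 30, seed = 1)
growth
#> <doublings_report> k=400, 30 repeats, 22 classes
#>   RMSPE 2.077   MAE 1.745   Spearman rho 0.984
head(growth$per_class, 4)
#>   true mean_aggregate pi_lower pi_upper
#> 1    0       1.650000        1   2.1375
#> 2    1       1.566667        1   2.0000
#> 3    2       1.600000        1   2.0000
#> 4    3       3.050000        2   4.2750
```

The first block reads: a linear SVM on the z-score/MRMR/PCA/LDA
embedding separates the shifted population from the control with mean
test-fold AUC 0.97. The second: predicting each withheld cell with the
coarse KNN and aggregating per doubling class by the median gives mean
aggregate predictions within ±1.7 doublings of truth on average (RMSPE
2.08), with rank correlation 0.98 across classes; `per_class` carries
the 95% prediction interval of the 30 aggregate scores per class.

The image path works the same way from rendered fields:

```r
scn <- afmi_scenario(cells_per_class = 4, seed = 1)
fld <- render_field(sim$cells[1:4, ], sim$spectra[1:4, ], scn, seed = 1)
cal <- preprocess_cube(fld$cube, fld$mask, simulate_references(scn)$refs)
feats <- extract_cell_features(cal, fld$mask)
```

Or end-to-end from a shell:

```sh
Rscript inst/cli/afmicell all --run-dir run1 --seed 1
```

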