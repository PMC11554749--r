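---
title: "Label-free single-cell phenotyping from autofluorescence multispectral images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{afmicell methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmicell)
```

## The problem

Cultured human bone-marrow mesenchymal stromal cells (hBM-MSCs) are
heterogeneous: within one dish, cells differ in stemness (STRO-1
positivity), spontaneous osteogenic differentiation (alkaline
phosphatase), replicative senescence (SA-&beta;-gal), cell-cycle status,
and — critically for cell manufacturing — in how many population
doublings they have left before growth arrest. All of these states are
normally read out by destructive staining. Endogenous fluorophores
(NAD(P)H, flavins, lipofuscin and matrix proteins) shift in abundance
with metabolic and replicative state, so a cell's autofluorescence
spectrum is an indirect, label-free reporter of the same biology.

`afmicell` implements a complete analysis pipeline for 47-channel
autofluorescence multispectral imaging (AFMI) of single cells:
calibration and preprocessing of the spectral data cubes, per-cell
feature extraction, a classification stack for the four phenotype
endpoints, and a bespoke coarse-KNN predictor of doublings remaining.
Because the kind of imaging data this targets is rarely public, the
package ships a first-class synthetic-data generator that emulates the
statistical structure the analysis assumes; every stage is tested
against that generator's known ground truth.

## The channel table

The instrument combines 18 LED excitation lines (358--476 nm, each
&plusmn;5 nm) with five emission filters (414 &plusmn; 23, 451 &plusmn;
53, 575 &plusmn; 29.5, 594 long-pass, 675 &plusmn; 33.5 nm). Requiring
the emission band to start at least 10 nm above the excitation centre
leaves 62 physically valid pairs; the acquisition uses 47. Which 47 is
instrument configuration, not something that can be derived, so
`default_channel_table()` reduces the 62 valid pairs to 47 by a balanced
deterministic rule — repeatedly drop the highest-emission filter from
the excitation line currently holding the most channels (ties towards
the longer wavelength) — which keeps all 18 excitation lines
represented. The table is data: any real instrument table can be passed
wherever a channel table is accepted.

## Preprocessing model

Raw cubes pass through five stages in an enforced order; each stage
checks the cube's step tag, preserves shape and channel order, and keeps
pixels finite and non-negative.

1. **Cosmic-ray removal.** A pixel is a spike when it exceeds the median
   of its 3&times;3 neighbourhood (same channel, centre included) by more
   than `cosmic_ray_zscore` (default 8) robust SDs (1.4826&times;MAD of
   the same nine values). Spikes are replaced by the neighbourhood
   median. Including the centre in the nine-sample MAD stops the scale
   estimate collapsing when the centre is a moderate fluctuation; with
   the default threshold the false-alteration rate on Gaussian noise is
   below 0.1%.
2. **Denoising.** The cube is reshaped to (pixels &times; channels) and
   truncated to its top `denoise_rank` (default 8) singular components —
   cellular autofluorescence lives in the low-dimensional span of a few
   endmember spectra, so this is near-lossless for signal — followed by
   per-channel 2-D wavelet shrinkage (CDF 9/7, soft threshold at the
   universal level with the noise scale taken from the finest diagonal
   subband by the MAD rule, default 2 levels). The CDF 9/7 lifting
   transform is implemented in the package (1-D and separable 2-D,
   symmetric padding, perfect reconstruction), since no wavelet library
   is available to R here and the transform is 60 lines of lifting steps.
3. **Background subtraction.** Per channel, the median intensity over
   mask-background pixels is subtracted; negatives are clipped at zero
   and counted. The median rather than the mean makes the estimate
   robust to unmasked debris and cell skirts.
4. **Flat-field correction.** Illumination is estimated per channel by
   fitting a 2-D polynomial (default degree 2) to the median-prefiltered
   *pre-subtraction* intensities at background pixels eroded 4 px away
   from any cell (cell-adjacent pixels mix in cell signal and would bias
   the fit). The fitted surface is normalised to mean one and divided
   out. This assumes background scales with illumination, which holds
   for ambient and stray light; a measured blank can be substituted via
   configuration. A degree-0 fit normalises to a constant surface of
   one, i.e. it is a no-op after the mean-one normalisation.
5. **Calibration.** Per-channel gain is
   `calib_reference / (calib_measured - water_mean)` from
   wavelet-smoothed water-blank and calibration-fluid spectra; channels
   with non-positive denominators raise an error naming them. Gains are
   recorded on the cube and in its JSON sidecar.

On a noise-free rendered field with known flat-field, background and
instrument response, the full chain recovers the clean signal to about
0.3% relative RMS (the acceptance suite requires 2%).

## Features

Per cell: seven intensity statistics per channel (mean, median, n−1 SD,
sample skewness, excess kurtosis, 10th/90th percentiles; zero-SD cells
have skewness/kurtosis 0 by convention), five GLCM texture statistics
per channel (contrast, correlation, energy, homogeneity, entropy;
16 grey levels over the cell's own min–max, offsets (0,1), (1,0),
(1,1), (1,−1) averaged, symmetric, masked pixels only; the single-level
degenerate cell has contrast 0, correlation 0, energy 1, homogeneity 1,
entropy 0), nine morphology features (area, contour-chain perimeter,
equivalent diameter, major/minor axes from the second-moment ellipse,
eccentricity, solidity over the pixel-corner convex hull, extent,
circularity 4&pi;A/P&sup2;), and pairwise channel-mean ratios for a
configurable channel subset. The catalog is declared as data
(`feature_catalog()`) and fully determines column order, so two runs on
the same inputs produce identical CSVs, and a different catalog can be
swapped in without touching extraction logic.

Assay gating: cell-cycle phase comes from total DNA-stain intensity
(G1 mode located as the kernel-density peak; thresholds at 1.25 and 1.75
times the mode are conventions, configurable, not claims about any
particular dataset); stain positivity uses the background- and
area-normalised score with an Otsu split by default. Table assembly
drops cells with non-finite values (counted) and removes one member of
each feature pair with |r| > 0.95, keeping the higher-variance member
(ties keep the lexicographically smaller name), scanning in catalog
order for determinism.

## The classification stack

For each endpoint the pipeline is: z-score using training statistics
only; MRMR feature selection; PCA; a linear discriminant projection; an
optional resampling step; a classifier. Everything is fitted inside
each training fold — the test fold never influences scaling, selection,
embedding or resampling, and the test suite enforces this with label-copy
canary features.

* **MRMR** is the MIQ variant: relevance is the mutual information
  between the feature (10 equal-frequency bins; variables with at most
  10 distinct values are used as-is) and the class; redundancy is the
  mean MI with already-selected features; after the maximally relevant
  first pick, each step maximises relevance/(redundancy + 1e-12), with
  lexicographic tie-breaks. The greedy choice is verified against an
  exhaustive evaluation of the same criterion on small problems.
* **PCA** retains 99% of variance by default.
* **The LD embedding** solves the Fisher eigenproblem with the
  within-class scatter regularised by `+1e-6 tr(Sw) I`, projecting to
  (classes − 1) dimensions scaled so the within-class scatter is
  whitened. On two classes this equals the pooled-covariance closed form
  `w` &prop; `Sw^-1(mu2 - mu1)` (and agrees with an independent
  `MASS::lda` fit to a fraction of a degree).
* **Resampling** (training folds only): ADASYN synthesises minority
  points preferentially near the class boundary — density ratios over
  the 5 nearest neighbours, largest-remainder allocation so the counts
  balance exactly, synthetic points drawn as convex combinations of
  minority neighbours — or uniform majority down-sampling.
* **Classifiers**: linear SVM (STRO-1, senescence), LDA (ALP),
  polynomial SVM of degree 3 (cell-cycle, G1 vs cycling); cost 1,
  unweighted (balancing is the resampler's job). Performance is
  stratified 5-fold ROC AUC of the continuous decision values with a
  fixed orientation (a shuffled-label control therefore lands near 0.5
  rather than being folded above it), plus sensitivity and specificity
  at each fold's Youden-optimal threshold — the operating-point choice
  is a package convention, reported alongside the AUC rather than
  claimed to match any published one.

Line-to-line heterogeneity is quantified by Kruskal–Wallis tests of the
per-channel mean features across lines with Benjamini–Hochberg control
at 0.05, reporting the fraction of channels significant.

## Growth potential: the coarse-KNN doublings predictor

Doubling labels are `round(arrest_total - cumulative_at_imaging)` from
each line's passage log. For each of 30 repeats, half of every doubling
class (floor(n/2), freshly seeded) is withheld; the z-score / MRMR (top
100) / PCA / LDA embedding is fitted on the retained cells only and the
withheld cells are projected into it. Each withheld cell is predicted
by the coarse KNN rule: among its k = 400 nearest training points in the
full LD space, partition by label and assign the label whose members
have the smallest mean distance (ties: more members among the k, then
the smaller label). Per class and repeat, the aggregate score is the
median of the cell predictions (half-integers allowed for even counts);
per class, the report carries the mean aggregate over repeats and an
empirical 95% prediction interval (2.5/97.5 percentiles of the 30
aggregates — an assumption-free construction). RMSPE and MAE are
computed over classes on the mean aggregates. The embedding is refitted
in every repeat; this is the leakage-safe choice, and a fit-once mode
exists for speed. `sweep_k()` evaluates a k grid with shared per-repeat
splits and embeddings, so the curve isolates the effect of k;
`cluster_ages()` runs seeded k-means (10 restarts) on the first two LD
components and reports clusters ordered by decreasing mean label.

Why such a coarse neighbourhood works: per-cell heterogeneity within a
doubling class is large relative to the per-doubling drift, so a small-k
vote is dominated by noise; k = 400 averages distances over a
population-scale neighbourhood, and the median aggregate then removes
most of the residual cell-level error.

## The synthetic-data generator

`afmi_scenario()` fixes the study conditions once; its defaults are the
conditions every test and benchmark assumes.

* **Spectra.** Four smooth synthetic endmembers (NADH-like: UV
  excitation/blue emission; FAD-like: blue/green; lipofuscin-like broad
  red; collagen-like deep-UV/violet), evaluated on the 47-channel table.
  They are shaped by the known excitation/emission maxima of these
  fluorophores but claim no photophysical accuracy — their job is to
  give the data realistic low-rank structure.
* **Cells.** Abundance = base + state effects + aging drift &times;
  (28 − doublings_remaining)/28 + line offset + heterogeneity noise.
  The default heterogeneity SD equals the drift accumulated over 8
  doublings — large within-class spread, which is exactly the regime
  the coarse KNN is designed for. Five lines arrest at totals drawn
  from [20, 30] with decelerating passage increments, yielding ~22--25
  observed doubling classes with 100 cells each.
* **Assays.** Senescence probability 0.9 at &le;2 doublings remaining
  (0.05 otherwise), STRO-1 0.7 for young cells, ALP 0.15 throughout;
  cycle phases 70/15/15 G1/S/G2 with DAPI totals at 1&times;, 1.5&times;
  and 2&times; a common mode (5% CV at G1). Senescent cells are
  hypertrophic (radius &times;1.8) and shift toward lipofuscin/FAD.
* **Imaging.** Rendered fields (96 px, up to 5 cells) draw rotated
  ellipses with smooth speckle and Gaussian-softened edges, normalised
  so masked channel means equal the true signatures exactly in the
  noise-free case; then background (~5% of mean cell signal, modulated
  by the illumination ramp — the configuration under which
  background-pixel flat-field estimation is informative), a &plusmn;20%
  bilinear flat-field ramp, a smooth two-harmonic per-channel instrument
  response (smooth across the channel sequence because the calibration
  files are wavelet-smoothed downstream), Poisson photon noise at 800
  photons per intensity unit, Gaussian read noise of 0.002 (a
  shot-noise-limited EM camera; raw values then stay positive, as real
  bias-offset frames do), and cosmic-ray spikes at 1e-4 per
  pixel-channel.
* **Null scenario.** `null_scenario()` removes *every* age-linked
  channel: zero drift, zero line offsets (lines reach different classes,
  so line-specific spectra are themselves an age confound), and
  age-independent assay probabilities, while keeping the heterogeneity
  noise. Under it the doublings predictor collapses to chance and
  classifiers to AUC &asymp; 0.5.

What the generator does **not** emulate: optics (PSF, chromatic
aberration), photobleaching, cell-cell contact and clumping, segmentation
error, batch effects beyond a static line offset, and any real
photophysics. Passing tests therefore demonstrate that the pipeline's
machinery is correct and leak-free and that it recovers the kinds of
structure it assumes — not that it attains any particular accuracy on
real imaging data.

## Numerical choices and problem sizes

Degenerate inputs all have documented conventions (zero-SD moments,
single-grey-level GLCM, empty-split warnings, all-equal Otsu scores call
everything negative). All randomness flows from explicit seeds through
one deterministic seed-derivation scheme, so every CLI stage is
byte-reproducible. Distances use the squared-expansion trick; the
3&times;3 median/MAD stacks use vectorised sorting networks.

The shipped benchmarks use: n = 300 cells for the classification
benchmark (10 of 47 channels shifted by one within-class SD); the full
~2,300-cell aging population with 30 repeats for the doublings report
(about a minute of compute); 15 repeats for the null comparison; one
rendered field for preprocessing recovery; and a reduced pipeline
configuration (one rendered field, 3 growth repeats, short k grid) for
the determinism checks, since determinism is size-independent.

## Known limitations

* The 47-channel identity is a convention; with a real instrument table
  the defaults should be overridden.
* The exact published feature listings for this kind of instrument are
  not reproducible from first principles; the implemented catalog is a
  declared, swappable stand-in.
* MRMR binning (10 equal-frequency bins, MIQ quotient) is one of several
  reasonable variants; it is configurable and oracle-tested, not claimed
  to be unique.
* The morphology-only ablation inherits whatever morphology the feature
  table carries; on the generator's fast path that is a single area
  feature, so its AUC mainly reflects the hypertrophy effect.
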