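---
title: "Methods: single-cell O-PTIR heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell O-PTIR heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `optirpop`, the
assumptions of its synthetic-data generator, and the numerical and design
choices made where more than one defensible convention exists.

## The measurement model

Each cell contributes six single-point O-PTIR spectra acquired on a 3×2
grid across the cell, on a shared wavenumber grid from 950 to 1801 cm⁻¹
at 0.5 cm⁻¹ spacing (1703 points). A spectrum is an absorbance-like
intensity vector; cells additionally carry a manually segmented binary
mask from which the cross-section area (pixel count × µm/px in X and Y)
and a three-bin size class are derived: small < 6 µm², mid-size 6–12 µm²,
large > 12 µm². The interval boundaries 6 and 12 µm² belong to the mid
class, because the outer classes are defined by strict inequalities.

## Preprocessing chain

Spectra are preprocessed in a fixed order: Savitzky–Golay second
derivative, truncation to an analysis region, Euclidean vector
normalization.

* **Savitzky–Golay derivative** (`sg_window = 35` points, `sg_polyorder
  = 2`, `sg_derivorder = 2`): a local quadratic least-squares fit in a
  sliding window; the second derivative removes slowly varying baselines
  and sharpens overlapping bands. The derivative is reported with respect
  to wavenumber, i.e. the index-space coefficient scaled by 1/step²; the
  scale cancels downstream (ratios, normalization) but is fixed so the
  output is testable against an independent sliding polynomial fit. The
  17 points at each grid end come from one-sided fits and are flagged in
  the spectrum metadata; both analysis regions exclude them on the
  default grid, so no analysis depends on edge behaviour.
* **Truncation** keeps grid points in a closed interval — the
  lipid/protein fingerprint region [1350, 1780] cm⁻¹ (ester and
  carboxylic-acid carbonyls, Amide I/II, CH and C–OH deformations) or the
  cell-wall carbohydrate region [1000, 1200] cm⁻¹ — without reordering or
  interpolation.
* **Vector normalization** scales each derivative spectrum to unit
  Euclidean norm, removing intensity-scale effects (sample thickness,
  laser power); only spectral *shape* enters all downstream statistics.
  A spectrum whose derivative is numerically zero (e.g. a constant input)
  is rejected rather than normalized into noise; "numerically zero" is
  judged relative to the input norm (threshold 10⁻¹⁰ × input norm), since
  filtering a constant leaves only floating-point residue.

## Heterogeneity statistics

Chemical dissimilarity between two spectra is the Pearson distance
1 − PCC ∈ [0, 2]; it is invariant to positive affine transformations of
either spectrum, which suits normalized derivative spectra where only
shape is meaningful.

* **Intra-cell variability**: mean Pearson distance of a cell's six
  spectra to the cell centroid (their pointwise mean). It measures
  within-cell chemical structure — in oleaginous yeasts dominated by the
  contrast between nearly pure-lipid lipid bodies and the
  protein/carbohydrate-rich cytoplasm.
* **Inter-cell variability**: Pearson distance between a cell centroid
  and the population centroid. The population centroid is the mean over
  *all* spectra, not over cell centroids; the two coincide only for
  balanced designs.
* **Outliers** are flagged per statistic by the 1.5 × IQR rule.
  Quartiles use the linear-interpolation convention (R's default type 7);
  the convention matters only for boundary cases and is fixed so flags
  are reproducible.
* **Regression**: ordinary least squares of intra (response) on inter
  (predictor), one point per cell, with R² the squared Pearson
  correlation. The "without outliers" variant drops cells flagged in
  *either* statistic (the union), the most conservative reading of
  removing marked points from the scatter.
* **Cross-region correlation**: each region is preprocessed
  independently; per cell one centroid-to-population-centroid distance is
  computed per region, and the two per-cell vectors are compared by
  Spearman rank correlation. The distance metric is Pearson distance by
  default with Euclidean distance as an explicit alternative
  (`metric = "euclidean"`): the construction "distances per set, then
  rank-correlate" admits both readings, both are implemented, and the
  choice is a switch rather than a hidden assumption.

## Size-stratified chemistry

PCA (mean-centred, no scaling) runs on all individual preprocessed
spectra rather than cell centroids, so within-cell spread is visible in
the scores. Loadings are unit-norm with the sign fixed so each loading's
largest-magnitude element is positive — a deterministic convention that
makes score plots reproducible across platforms.

Chemistry proxies are ratios of intensities at the carbonyl/amide
wavenumbers — i(1748)/i(1714) for the TAG:FFA balance, i(1748)/i(1659)
for TAG content, i(1714)/i(1659) for FFA content — computed per spectrum
in two modes:

* **Broadband**: intensities read from the preprocessed
  (second-derivative, normalized) spectra at the nearest grid points. An
  offset of −0.1 is added to *both* numerator and denominator before
  division; derivative values near zero would otherwise produce unstable
  ratios, and applying the offset to both terms shifts all values away
  from zero uniformly. Derivative values are used as they are (negative
  at absorbance peaks); a peak-intense spectrum therefore has a *more
  negative* band value, and ratios remain monotone in the underlying
  band-intensity ratio.
* **Sparse**: emulating four-wavenumber acquisition, intensities are read
  from the *raw* spectra at 1659, 1714 and 1748 cm⁻¹ and
  baseline-referenced by subtracting the value at 1800 cm⁻¹ (a silent
  wavenumber with no biological absorbance); no offset. Raw spectra are
  used because a four-wavenumber instrument cannot compute a derivative;
  the mode switch in `ratio_table()` makes the choice explicit.

Wavenumber lookup is nearest-grid-point with ties broken towards the
lower wavenumber; on a 0.5 cm⁻¹ grid interpolation error is negligible
and nearest-point lookup keeps sparse and broadband modes structurally
identical.

Group comparison across size classes reports a Shapiro–Wilk normality
gate on the ratio values (the motivation for preferring a rank test over
ANOVA) followed by the Kruskal–Wallis test with the standard tie
correction and chi-square p-value on k − 1 degrees of freedom. Ratios are
compared per spectrum (n = 240 in the default design), not per cell. An
all-tied input is returned as H = 0 rather than the 0/0 the tie-corrected
formula produces.

## The synthetic-data generator

The generator exists so that every downstream stage has tested,
seed-reproducible input with known ground truth. It emulates:

* the acquisition design — `n_cells = 40`, `points_per_cell = 6`, grid
  950–1801 cm⁻¹ at 0.5 cm⁻¹;
* **band chemistry**: spectra are linear mixtures of five component
  spectra (TAG, FFA, protein, carbohydrate, phosphate), each a sum of
  pseudo-Voigt bands (η = 0.5, FWHM 16–28 cm⁻¹ for carbonyl/amide and
  deformation bands, 35–40 cm⁻¹ for the broad carbohydrate envelope) at
  the field's assignment positions: 1748/1463/1377 (TAG), 1714/1463/1413
  (FFA), 1659/1547 (protein), 1200–1000 envelope (carbohydrate), 1245
  (phosphate). Only peak positions are constrained by the literature;
  shapes and widths are generator choices. No band sits in the silent
  window 1790–1810 cm⁻¹, so the 1800 cm⁻¹ baseline reference behaves as
  on real data;
* **size-dependent composition**: areas are lognormal (`meanlog = 2.09`,
  `sdlog = 0.35` on µm², placing roughly 20/67/13 % of mass in the
  small/mid/large bins); compositions are Dirichlet draws (concentration
  150) around size-class means — small cells protein-dominant (protein
  0.45), mid-size cells FFA-rich (FFA 0.30 > TAG 0.15), large cells
  TAG-rich (TAG 0.40 > FFA 0.12). These means encode the qualitative
  size-chemistry pattern the pipeline is designed to detect; the numbers
  are declared defaults, not measured fractions;
* **intra-cell heterogeneity**: each point spectrum is a two-endmember
  mixture m · (lipid body) + (1 − m) · (cytoplasm), where the lipid-body
  endmember is 95 % lipid in the cell's own TAG:FFA proportions and the
  cytoplasm endmember is chosen so the mixture at the cell's mean m
  reproduces the cell composition. Per-point m is Beta-distributed around
  a per-cell mean (`point_kappa = 12`; the per-cell means are themselves
  Beta around 1/3 with `mean_kappa = 8`). Lipid bodies contain nearly
  pure lipid while cytoplasm is a complex mixture, so a two-endmember
  model is the simplest generator with realistic within-cell structure.
  Setting a κ to `Inf` removes that variance source exactly, which the
  test suite uses to isolate causes;
* **nuisance**: per-spectrum quadratic baseline drift (coefficients
  uniform in ±0.03/±0.02/±0.01 on the grid rescaled to [−1, 1]) and
  additive Gaussian noise (σ = 0.005, about 1–2 % of a typical peak);
* **masks**: per cell, a pixel-exact disk at 0.1 µm/px whose area matches
  the sampled area, so the geometry stage runs on the same inputs it
  would see from manual segmentation.

All draws flow from a single master seed (config field `seed`) in a
documented order inside one seeded block, so identical configs give
byte-identical datasets; `inject_outlier_cells()` and the pipeline use
separately derived seeds so adding a stage never perturbs earlier draws.

What the generator does **not** emulate: photothermal physics (thermal
expansion differences between lipids and polysaccharides enter real
O-PTIR intensities), instrument-specific baseline structure, detector
nonlinearity, scattering artefacts, cell-to-cell focus variation, and the
C–H stretch region above 1801 cm⁻¹. Passing tests therefore demonstrate
that the *statistical machinery* behaves as constructed — they do not
validate the spectroscopy itself against instrument data.

## Problem sizes and numerical tolerances

The test suite runs everything at the design scale (40 × 6) where a
single dataset is enough, and scales repetition counts to keep the suite
fast: the Savitzky–Golay oracle comparison uses 100 random spectra of
length 101 (window 35, every interior point checked against an
independent sliding `lm` fit, relative tolerance 10⁻⁹); the
Kruskal–Wallis null calibration uses 10,000 three-group Gaussian datasets
of 15 values per group; the seeded-power check uses 200 full populations;
the paired mixing-variance comparison uses 100 seed pairs at 12 cells
each (the property is population-size independent); outlier recovery uses
60 injected populations. PCA reconstruction is checked to 10⁻⁸, vector
norms to 10⁻¹², grid uniformity to a relative 10⁻⁶ on the spacing.

## Known limitations

* The band library is deliberately minimal (12 bands, 5 components);
  real yeast spectra contain many more overlapping modes, so absolute
  ratio values are not comparable between synthetic and measured data —
  only their orderings and test decisions are.
* Compositions and endmembers are linear in absorbance; O-PTIR signal
  saturation and thermal effects are not modelled.
* The Kruskal–Wallis p-value uses the chi-square approximation, standard
  at the group sizes of this design but inaccurate for groups of fewer
  than ~5 spectra.
* Masks are assumed solid (holes count as background) and one cell per
  mask file, matching manual single-cell segmentation practice.
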