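# optirpop

Single-cell analysis of phenotypic heterogeneity in oleaginous yeast
populations from optical photothermal infrared (O-PTIR) microspectroscopy.

Microbial lipid producers such as *Rhodotorula* yeasts accumulate
triacylglycerols (TAGs) and free fatty acids (FFAs) unevenly across a
population: cell-to-cell differences in chemistry ("population
heterogeneity") and within-cell differences between lipid bodies and
cytoplasm ("cellular heterogeneity") both matter for bioprocess
monitoring. O-PTIR measures sub-micron infrared absorbance spectra of
individual cells, so a handful of single-point spectra per cell is enough
to place every cell in chemical space. This package implements the full
analysis for such data, for spectroscopists and bioprocess scientists:

* **Forward simulator** — synthetic single-cell O-PTIR spectra (40 cells ×
  6 point spectra on a 3×2 grid, 1801–950 cm⁻¹ at 0.5 cm⁻¹) with matching
  segmentation masks, size-dependent composition, lipid-body/cytoplasm
  domain mixing, baseline drift and noise, so the whole pipeline is
  testable without instrument data.
* **Preprocessing** — Savitzky–Golay second derivative (polynomial order
  2, window 35), truncation to the lipid/protein fingerprint region
  (1780–1350 cm⁻¹) or carbohydrate region (1200–1000 cm⁻¹), and vector
  normalization.
* **Heterogeneity statistics** — Pearson distance (1 − PCC). Intra-cell
  variability is the mean 1 − PCC of a cell's six spectra to the cell
  centroid; inter-cell variability is the 1 − PCC between a cell centroid
  and the population centroid (mean of all 240 spectra). Outliers are
  flagged by the 1.5 × IQR rule; intra is regressed on inter (with and
  without outliers), and the two spectral regions are compared by a
  Spearman correlation of per-cell distances.
* **Size-stratified chemistry** — cell cross-section areas from
  segmentation masks (pixel count × µm/px in X and Y), three size classes
  (small < 6 µm², mid 6–12 µm², large > 12 µm²), PCA of the preprocessed
  spectra, and band-ratio proxies from the carbonyl/amide intensities:
  i(1748)/i(1714) for the TAG:FFA balance, i(1748)/i(1659) for TAG
  content, i(1714)/i(1659) for FFA content, compared across size classes
  with a Shapiro–Wilk normality gate and the rank-based Kruskal–Wallis
  test.
* **Sparse acquisition simulation** — the same chemistry from intensities
  at only four wavenumbers (1659, 1714, 1748 cm⁻¹, baseline-referenced
  against the silent region at 1800 cm⁻¹), emulating fast sparse-wavenumber
  O-PTIR imaging, plus a concordance report against the broadband analysis.

## Worked example

```r
library(optirpop)

run <- run_pipeline(synthetic_config(seed = 1), outdir = "results/run1")

run$summary$counts$cells                  # 40
run$summary$counts$spectra                # 240
unlist(run$summary$counts$per_size_class) # small 4, mid 33, large 3

# heterogeneity in the fingerprint region (1 - PCC)
run$summary$variability$fingerprint$median_intra   # 0.0133
run$summary$variability$fingerprint$median_inter   # 0.0137
run$summary$regressions$fingerprint$with_outliers$r_squared  # 0.014

# size-dependent TAG:FFA chemistry, sparse four-wavenumber mode
g <- run$summary$group_tests$sparse
g$kruskal_h                    # 87.7
g$kruskal_p                    # 8.9e-20
unlist(g$medians)              # small 0.78, mid 0.52, large 3.52

compare_modes(run)$rho         # 0.994
```

Reading the output: intra- and inter-cell variability sit in the same
range (medians ≈ 0.013), i.e. a typical cell differs from the population
average about as much as its own measurement points differ from each
other, and the regression R² ≈ 0.01 shows the two are essentially
uncorrelated. The TAG:FFA ratio medians separate the size classes —
large cells well above 1 (TAG-dominated), mid-size cells below 1
(FFA-rich) — and the Kruskal–Wallis test rejects equality across classes
(p ≪ 0.001). The sparse four-wavenumber simulation ranks cells almost
identically to the broadband analysis (Spearman ρ = 0.99) and reaches the
same significance decision.

Measured data can be analysed the same way from a long-format CSV
(`cell_id,point_id,wavenumber_cm1,intensity`) via
`run_pipeline(synthetic = NULL, spectra_path = "spectra.csv")`, with masks
read by `read_mask()` (8-bit PNG plus a JSON sidecar carrying µm-per-pixel
resolution).

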