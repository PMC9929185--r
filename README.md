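# SynapseColoc

Quantification of two-channel receptor colocalization at immunological
synapses, for microscopists and immunologists asking whether two membrane
receptors — typically a GFP-tagged chimeric antigen receptor (CAR) and a
far-red-labeled probe such as the T cell receptor (TCR) or the transferrin
receptor (TfR) — occupy the same contact zone when a T cell engages its
target.

The package implements two complementary measurement pipelines and a
ground-truth synthetic scene generator to validate them:

* **2D TIRF analysis** — contact ROI from pixels above threshold in at
  least one channel; contact size = pixel count × pixel area
  (160 × 160 nm²); colocalization as the Pearson correlation coefficient

  r = Σᵢ(xᵢ − x̄)(yᵢ − ȳ) / √( Σᵢ(xᵢ − x̄)² · Σᵢ(yᵢ − ȳ)² )

  over the gated pixels, with x and y the per-pixel green and red
  intensities.
* **3D stack analysis** — 7×7×7 box mean filtering; Otsu-based
  segmentation of a synaptic ROI (green channel) and extrasynaptic
  membrane ROI (red channel); relative intensities
  RI = mean(region)/mean(whole membrane); per-z-slice Pearson correlation
  over ROI voxels passing a histogram-intersection intensity gate,
  averaged per cell.
* **Group statistics** — Wilcoxon–Mann–Whitney, Kruskal–Wallis with
  Dunn's tie-corrected post-hoc test (Bonferroni-adjusted), and the
  plate-assay formulas viability (%) = (OD_exp − OD_Tcell)/(OD_tumor −
  OD_medium) × 100, cytotoxicity (%) = 100 − viability.
* **Synthetic scenes** — membrane Poisson point processes on a
  truncated-sphere cell with a flat synaptic contact, a tunable
  colocalization fraction ρ mixing a shared molecular pattern into the red
  channel, Gaussian PSF (120 nm lateral / 350 nm axial FWHM), Poisson shot
  noise, camera background and read noise; deterministic under a seed.

The methods vignette (`vignettes/synapse-colocalization.Rmd`) documents the
model, every tunable parameter and all numerical choices.

## Worked example

```r
library(SynapseColoc)

# three probe conditions: identical-target (CAR/CAR, rho = 0.9),
# synapse-excluded (CAR/TCR), uniform control (CAR/TfR)
cells <- generateCohort(synapseConditions("stack3d"), 10, seed = 1)
df <- measurementsToDataFrame(lapply(cells, analyzeStackCell))
summarizeGroups(df, statistic = "pcc")
#>   condition  n nExcluded     median       mean          sd
#> 1   CAR_CAR 10         0 0.91166004 0.90975979 0.005754996
#> 2   CAR_TCR 10         0 0.09094330 0.09528304 0.023490748
#> 3   CAR_TFR 10         0 0.07971741 0.08549735 0.021980450

res <- compareMany(split(df$pcc, df$condition))
res$omnibusP
#> [1] 4.688832e-05
```

Read: the identical-target probe scores a per-cell mean synaptic PCC of
about 0.91 while both the synapse-excluded and the uniform probe sit near
0.09 — the red probe colocalizes with the reference receptor only when it
*is* the reference receptor, and the omnibus Kruskal–Wallis test confirms
the group difference. `runPipeline(pipelineConfig("stack3d"))` performs the
same simulation–analysis–summary loop as one reproducible run directory
with per-cell CSV, summary CSV and a statistics report.

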