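---
title: "Quantifying receptor colocalization at immunological synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor colocalization at immunological synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynapseColoc)
```

## The question and the measurement

When an engineered T cell carries both a chimeric antigen receptor (CAR) and
its endogenous T cell receptor (TCR), do the two receptors gather in the
same contact zone — the immunological synapse — when one of them engages its
antigen? The measurement that answers this is two-channel fluorescence
colocalization: a green reference channel (a GFP-tagged CAR) marks the
synapse, and a red probe channel carries either the same receptor
(an anti-CAR label: the positive control), the TCR (the biological
question), or the transferrin receptor TfR (a membrane protein with no
synaptic role: the negative control).

`SynapseColoc` implements the two quantification pipelines this design
needs, plus a synthetic scene generator with known ground truth that stands
in for raw microscopy data:

* **2D TIRF path** (`analyzeTirfCell()`): cells on a coated coverslip,
  imaged only at the glass-proximal membrane. Pixels above a threshold in
  *at least one* channel form the contact ROI; the contact size is the pixel
  count times the pixel area (160 × 160 nm²), and colocalization is the
  Pearson correlation coefficient (PCC)
  \[ r = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
  {\sqrt{\sum_i (x_i-\bar x)^2 \sum_i (y_i-\bar y)^2}} \]
  over the gated pixels, where \(x\) and \(y\) are the per-pixel green and
  red intensities.
* **3D stack path** (`analyzeStackCell()`): live conjugates with a target
  cell, imaged as z-stacks (0.23 µm steps). Both channels are smoothed with
  a 7×7×7 box mean (radius 3 voxels per axis, ≈ 0.30 × 0.30 × 0.68 µm),
  thresholded and reduced to connected components to obtain a *synaptic* ROI
  (from the green channel) and an *extrasynaptic* membrane ROI (from the
  red channel, synaptic voxels removed); their union is the whole-cell
  membrane. Mean intensities per region are divided by the whole-cell mean
  to give relative intensities (RI > 1 = accumulation, < 1 = exclusion),
  and the PCC is computed per z-slice over ROI voxels passing an
  either-channel intensity gate, then averaged over slices per cell.
* **Group statistics** (`compareTwo()`, `compareMany()`): two-sided
  Wilcoxon–Mann–Whitney for two groups; Kruskal–Wallis plus Dunn's post-hoc
  z tests (tie-corrected, Bonferroni-adjusted by default) for three or
  more. `cytotoxicityFromOD()` implements the plate-assay arithmetic
  viability (%) = (OD_exp − OD_Tcell)/(OD_tumor − OD_medium) × 100 and
  cytotoxicity (%) = 100 − viability.

## The synthetic scene model

No raw images are distributed with the analysis this package reimplements,
so validation runs on simulated scenes whose ground truth is known exactly
(`sceneTruth()`, `generateTirfScene()`, `generateStackScene()`).

**Membrane geometry.** A 3D cell is a sphere (radius 3.2 µm by default)
truncated at the contact plane with its target: the flat circular face is
the synaptic interface, the remaining sphere the extrasynaptic membrane.
The truncation angle (`capAngle`, default 1.1 rad) sets the contact size.
We deliberately model the contact as *flat* rather than as a curved
spherical cap: a T cell pressed against a target forms a planar interface,
and a curved cap would be tangent to the imaging planes near its pole,
which imprints a strong shared intensity envelope on both channels within
each z-slice — per-slice correlations would then be dominated by geometry
rather than by molecular colocalization. A 2D TIRF scene is simply the
contact disc (radius 4 µm) in a uniform membrane background.

**Receptors.** Each channel is a spatial Poisson point process on the
membrane. The extrasynaptic density is `baselineDensity` (20 molecules/µm²
for stacks — of the order of 10⁴ receptors over a lymphocyte surface — and
100/µm² for TIRF, whose evanescent excitation integrates the membrane
together with the proximal receptor pool into one dense footprint).
Synaptic density is `enrichmentGreen` (default 3) or `enrichmentRed` times
the baseline.

**Colocalization knob.** The red channel is the mixture
\(\rho\,w\,S + (1-\rho)\,R\): a fraction `colocFraction` (ρ) of the red
pattern is copied from the green molecular pattern \(S\) (rescaled by
\(w = \text{enrichmentRed}/\text{enrichmentGreen}\) inside the synapse so
the red net enrichment stays as configured), the rest is an independent
process \(R\). ρ = 0 gives independent channels, ρ = 1 a perfect spatial
copy; the measured PCC is monotone in ρ, which is what the recovery tests
exploit.

**Optics and noise.** Channels are convolved with a Gaussian PSF whose
sigmas derive from the stated optical resolution via FWHM = 2.355 σ
(120 nm lateral, 350 nm axial). Voxel sampling is 100 nm lateral / 0.23 µm
axial (160 nm pixels in TIRF). Detection applies Poisson shot noise on the
expected photon counts plus camera background and Gaussian read noise, and
quantizes to non-negative integer counts (16-bit camera units). Stacks
default to background 2 / read noise 1 (deconvolution-processed confocal
data is nearly background-free); TIRF frames to background 10 / read noise
3 (raw EMCCD frames). In TIRF, membrane outside the contact disc is
attenuated by `tirfContrast` (default 0.15), the evanescent-field decay for
membrane farther from the glass.

**Cohorts.** `generateCohort()` derives one child seed per cell from the
master seed with a fixed counter scheme and applies mild biological jitter
(log-normal, 8% SD) to cell radius and enrichment factors. The jitter
sequence depends only on the cell index, so changing the master seed
changes the noise realization but not the per-cell biology. Parameter
recovery sweeps (e.g. recovering the colocalization fraction or the
enrichment factor) disable the jitter (`jitterSd = 0`): recovering a known
parameter requires holding it fixed, while the probe-condition cohorts keep
the jitter to emulate real cell-to-cell variability.

**What the generator does not emulate.** Receptor microclustering and
diffusion, membrane ruffling and microvilli, chromatic shift, detector
pixel cross-talk, photobleaching, axial attenuation, and any live-cell
dynamics (scenes are static snapshots). Passing recovery tests on these
scenes therefore shows that the *measurement chain* is correct and
unbiased under a known generative model — not that real images meet that
model's assumptions.

## Numerical and design choices

* **Volume Otsu, two levels.** Stack segmentation needs a threshold on the
  pooled voxel histogram of a smoothed 3D stack. That histogram has three
  populations — background, smoothing halo, bright membrane — and the two
  candidate 2-class splits score nearly identically, so a single Otsu
  threshold flips unpredictably between them. `segmentRoi3D()` therefore
  fits a three-class (two-threshold) Otsu; the synaptic anchor uses the
  upper threshold, the extrasynaptic anchor the lower one.
* **Bounded synaptic z-window.** The synaptic and extrasynaptic membrane
  form one connected surface, so after smoothing the bright contact always
  merges with the membrane walls into a single connected component —
  "largest component" alone cannot isolate the contact. The synaptic
  anchor is therefore restricted to a z-window around the contact plane
  (located as the peak of the raw green per-slice intensity profile, a
  4–5× peak in these scenes) spanning 1 slice below to 2 slices above —
  the axial PSF reach of the interface. This is the automated counterpart
  of verifying each synaptic ROI against the visible extent of the contact
  region, which the original workflow did manually. `contactZWindow =
  NULL` disables it.
* **Halo margin of the extrasynaptic ROI.** Intensity genuinely bleeds
  about one PSF width beyond the membrane; beyond that, foreground voxels
  are pure smoothing halo. The extrasynaptic anchor keeps foreground
  voxels within the optical-resolution FWHM (in voxel units: 1 lateral,
  2 axial at default calibration) of the bright membrane core. Without
  this margin the synaptic and extrasynaptic ROIs dilute their mean
  intensities by very different amounts and relative intensities acquire a
  coverage bias (a uniform probe would read RI ≈ 1.3 in the synapse).
* **Intensities are measured on the original stack.** Smoothing exists to
  generate ROIs; relative intensities and correlations are quantified on
  the unfiltered voxel values.
* **Histogram-intersection gate.** The gating threshold is the crossing of
  the intensity histograms of cell-containing (whole-cell ROI) and
  cell-free voxels (everything farther than one filter radius outside it),
  on a common 256-bin grid. The crossing search starts at the background
  mode and runs upward until the cell density first reaches the background
  density; it is not capped at the cell-sample mode because a whole-cell
  ROI contains many unlabeled voxels, putting its mode at the background
  level. If the histograms never cross, the midpoint of the two modes is
  used; identical distributions raise a no-threshold condition. The gate
  is computed per stack by default (`gatePerSlice = TRUE` recomputes it
  per slice; neither variant is asserted to be the original authors'
  choice, which is unstated).
* **Per-slice eligibility.** A slice enters the per-cell PCC average only
  if at least `minPixels` (default 20) ROI voxels pass the either-channel
  gate — correlations on fewer pixels are numerically meaningless — and
  slices are skipped, never zero-filled. Zero-variance slices are skipped
  likewise. An undefined correlation is reported as `NA` plus a QC flag,
  never silently as 0, because 0 would fake "no colocalization".
* **TIRF thresholds.** The original analysis used an analyst-chosen
  ("user-defined") threshold. The reproducible default is Otsu per channel
  (`thresholdSpec("otsu")`), overridable by an explicit value; thresholds
  can be set per cell or shared across a dataset — both are supported.
* **Unstimulated controls** are analyzed as single 2D slices through the
  same gated correlation path (`analyzeControlSlice()`), mirroring how
  unengaged, mobile cells are imaged with a single fast slice.
* **Statistics.** Sample SD (n − 1) for all "± SD" summaries; Dunn's
  post-hoc multiplicity adjustment is Bonferroni by default (the most
  conservative common choice) and is recorded in the output metadata.
  Degenerate all-tied comparisons return p = 1 with a classed warning.
  Viability clamping to [0, 100] is flagged, never silent.
* **Pixel conventions.** Arrays are indexed (row = y, column = x[, slice =
  z]); masks are plain logical arrays; saturated 16-bit values are
  included in all statistics (no saturation filter), a documented
  limitation.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run entirely on synthetic
scenes: default-size stacks are 96 × 96 × 60 voxels and TIRF frames
128 × 128 pixels; recovery cohorts use 10 cells per condition (3D) and 16
per condition (TIRF), with smaller 64 × 64 × 40 stacks for property sweeps
where only orderings are asserted. These sizes make the whole suite run in
minutes on a single core while keeping every assertion at the default
imaging geometry.

## A worked example

```{r example, eval = FALSE}
library(SynapseColoc)

# simulate the three probe conditions and analyze each cell
cells <- generateCohort(synapseConditions("stack3d"), 10, seed = 1)
measurements <- lapply(cells, analyzeStackCell)
df <- measurementsToDataFrame(measurements)

summarizeGroups(df, statistic = "pcc")
compareMany(split(df$pcc, df$condition))

# or as one reproducible run directory
res <- runPipeline(pipelineConfig("stack3d", nCells = 10, seed = 1))
res$summary
```

## Known limitations

* The generative model is a judgment about realism, not a fit to data: no
  raw images accompany the analysis being reimplemented, so generator
  defaults (densities, photon yields, noise levels) are physically
  plausible choices, documented above and held fixed.
* Relative intensities retain a residual ROI-coverage dependence of order
  10–15% even with the halo margin; enrichment factors recovered from RI
  ratios are accurate to roughly that level, not better.
* The per-slice PCC of ROIs containing almost no labeled pixels depends on
  the gate quality; with a gate close to the background level, the
  either-channel rule can admit noise voxels whose selection induces a
  negative correlation bias. The bounded z-window keeps such slices out of
  the synaptic ROI at default settings.
* No reader for proprietary microscope formats is included; scenes enter
  as two-channel multi-page TIFFs with plain-text sidecars.
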