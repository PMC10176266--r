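---
title: "Methods: per-cell immunofluorescence quantification in trophoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell immunofluorescence quantification in trophoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophoquant)
```

## Scope and model

`trophoquant` quantifies per-cell marker expression in multichannel
immunofluorescence fields of differentiating human trophoblast stem cells
(hTSCs). The measurement model is deliberately simple and auditable: cells
are identified by their DAPI-stained nuclei; marker signal is attributed to
cells by proximity; all intensities are expressed as fold-changes over the
nonspecific baseline defined by isotype-control staining. The package makes
no attempt at learning-based segmentation, spectral unmixing, or 3-D
reconstruction.

All pixel coordinates in the package are 1-based `(row, col)` with pixel
centers at integer coordinates; distances are Euclidean in pixel units and
converted to micrometres through the acquisition scale `um_per_px`.

## Cell detection

The blue (DAPI) channel is binarized either by Otsu's method (default) or at
a fixed global threshold; the threshold actually used is recorded in the run
manifest. The mask is then cleaned: enclosed holes filled, components below
`min_area_px` removed, and — optionally — touching nuclei split by a
watershed on the distance transform. Components are 8-connected and labeled
in raster-scan order of their first pixel, which makes labeling fully
deterministic.

Defaults and rationale:

* `min_area_px = 30` at the default scale of 0.62 μm/px corresponds to a
  disk of radius ≈ 3.4 μm, a conservative lower bound for a nucleus; smaller
  components are noise or debris.
* Watershed splitting is off by default because the generator's default
  layout guarantees non-touching nuclei; it is exercised (and verified
  against ground truth) through the generator's `touching` mode, which
  places nucleus pairs at 1.5× radius spacing.
* The original analysis calibrated its mask-processing steps on two images
  with known cell number and extrapolated. That manual step is not
  reproducible, so this package replaces it with explicit configuration
  (threshold method, minimum area, watershed switch) whose defaults are
  validated on synthetic fields with known counts. This favors
  reproducibility over fidelity to an undocumented procedure.

## Per-cell marker assignment

Two modes are provided.

**Nearest-stain mode** (default for surface markers such as HLA-G and
Notch1). The stain channel is binarized and cleaned with the same operator
family as DAPI; each component's mean is computed over the *original*
intensities. A cell receives the mean of the component containing the stain
pixel nearest its nucleus centroid. If that nearest stain pixel is farther
away than the nearest DAPI pixel of a *different* nucleus, the stain more
plausibly belongs to the neighbor, and the cell instead receives the
isotype-control average (fallback). Reading "nearest blue stain" as the
nearest *other* nucleus is a deliberate interpretation: a cell's own nucleus
is at distance ≈ 0 from its centroid, so the literal reading (any blue
pixel) makes fallback nearly certain for every cell and degenerates the
rule into a constant assignment. The literal variant is retained as
`fallback_rule = "any_blue"` for sensitivity analysis, and the degenerate
behavior is asserted in the test suite.

Numerical conventions: distances are measured from the nucleus centroid
(the only point the detection stage guarantees) to the nearest mask pixel;
an exact tie `d_stain == d_other` resolves to *no* fallback; among
equidistant stain pixels the smallest `(row, col)` wins. These tie rules
make the operation bit-reproducible and are enforced by an exhaustive
per-pixel oracle over 1000 random fields.

**Nuclear mode** (HIF1α/HIF2α). The cell's value is the mean of the channel
over the cell's own nucleus pixel set. No distance rule applies.

**Isotype reference.** Per-cell values from 1–3 isotype-control fields,
processed in the same mode, are pooled (weighted by cell count) and
averaged. Pooling rather than averaging per-field means was chosen because a
single "average isotype control expression intensity" is the natural
estimator and pooling is its simplest consistent form; the per-field
alternative remains available. On stain-free isotype images the nearest-stain
mode has no components to assign, so the per-cell nonspecific baseline is
measured as the nuclear-region mean of the stain channel. Normalized
intensity is `raw / reference`; fallback cells therefore normalize to
exactly 1, which the suite asserts as an identity.

## Spatial classification and quartiles

A cell is a *single* cell iff no other centroid lies within the neighbor
radius (default 50 μm), inclusively at the boundary — the boundary handling
is a declared convention, since "within a radius" does not specify it.
Classification is per field and verified against an O(n²) brute force.

For quartile stratification, cells negative for *both* markers are excluded
first. "Negative" defaults to fallback-assigned (equivalently, normalized
intensity exactly 1); an explicit threshold on normalized intensity is
available because negativity is not otherwise numerically defined. The
included cells are sorted ascending by the primary marker with ties broken
by `cell_id` (stable, deterministic), and the bottom and top groups each
take exactly `⌊n/4⌋` cells. Equal group sizes are a construction property —
consistent with equal reported sizes for both extracted quartile groups in
this kind of analysis — rather than percentile interpolation.

## Fusion index

`FI = (N − S)/T` where `N` is the number of nuclei inside syncytia, `S` the
number of syncytia (each holding at least two nuclei), and `T` the total
nuclei counted. The reference input path is a manual counts table
(condition, replicate, N, S, T), since fusion counting is typically done by
eye; the automated path assigns each nucleus to the membrane-bounded region
containing its centroid (boundary hits go to the nearest region and are
logged) and is validated against generated membrane fields with known
fusion indices. Summaries report mean ± SD per condition (fusion indices are
conventionally reported with SD; qPCR fold changes with SE).

## Statistics

* **Mann-Whitney U, large-sample form.** U from midranks; null variance with
  the standard tie correction (ties are frequent in normalized data because
  fallback cells all sit at exactly 1); two-sided p from the normal
  approximation, no continuity correction by default (a flag enables it).
  The package also ships a complete-enumeration oracle (guarded to
  n₁ + n₂ ≤ 20) used in tests. The enumeration quantifies the approximation
  error at small n: at n₁ = n₂ = 8 the worst-case deviation from the
  inclusive exact two-sided p is ≈ 0.046 and is concentrated where
  |U − μ| ≤ 1 (exact p ≈ 1), because the point mass P(U = μ) ≈ 0.042 at that
  size exceeds any continuous approximation's resolution; in the rejection
  region the approximation is far more accurate, and at n = 500 per group
  the empirical type-I rate at 0.05 sits within [0.04, 0.06].
* **Variance-gated t test.** A two-sided F test for equality of variances at
  α = 0.05 selects pooled Student or Welch; the decision is recorded in the
  result. Degenerate zero-variance inputs are flagged.
* **ΔΔCT.** Per sample, `ΔCt = Ct − geomean(Ct_GAPDH, Ct_ACTB)`, taking the
  geometric mean over the Ct values themselves — a literal reading of the
  normalization description, documented as such (not over linearized 2^−Ct
  quantities). `ΔΔCt` averages replicate ΔCt per condition minus the
  reference condition; `log2FC = −ΔΔCt`, SE across replicates, and a
  per-condition t test on replicate ΔCt values against the reference.
  Significance at ΔCt level is standard practice and is the package's
  choice. No multiple-testing correction is applied by default (raw p at
  0.05 with `*`/`**`/`***` markers at 0.05/0.005/0.0005); a
  Benjamini-Hochberg adjustment can be applied by the caller via
  `p.adjust`.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
optics. Nuclei are rendered as filled disks (radius 4–6 px by default) at
positions satisfying, by construction: full containment in the image,
non-overlap (center separation > 2× max radius), and the spatial-class
definition (singles have no neighbor within the colony radius, default
50 μm; colony members have at least one). Marker signal is a disk blob of
the cell's true intensity, drawn from a two-population mixture that is
anti-correlated across the two channels (high-green/low-red versus
low-green/high-red, emulating HLA-G/Notch1 heterogeneity at day 6).
Background and Gaussian noise are added and clipped to [0, 255]; the default
scale is 8-bit at 0.62 μm/px — both are declared assumptions, since bit
depth and magnification are acquisition choices, and both are configurable.
Intensities are kept floating point by default (`quantize = FALSE`) so that
recovery tests are exact identities rather than approximate ones.

Membrane fields partition the image into a rectangular grid of closed
regions and place nuclei so that the requested fusion index is met to within
its attainable granularity 1/T; the syncytium-size composition uses as few,
roughly equal syncytia as the target allows.

Ct tables encode fold changes as `Ct = base − log2FC + noise` with constant
housekeeping Cts, so the ΔΔCT pipeline recovers the truth exactly at zero
noise.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: point-spread blur, chromatic aberration,
channel bleed-through, uneven illumination, out-of-focus nuclei, apoptotic
fragments, and genuinely overlapping nuclei beyond the pairwise touching
mode. Results on real images depend on segmentation quality in ways the
synthetic fields cannot probe.

## Problem sizes and reproducibility

The shipped verification uses synthetic fields of 512×512 px with up to 200
nuclei, 1000 random 48×48 fields for the nearest-stain oracle, 500-cell
spatial brute-force checks, 10,000 Monte-Carlo replicates for test levels,
and 1000 replicates for noisy fold-change recovery — sizes chosen so the
whole suite completes in a few minutes on a laptop while keeping Monte-Carlo
standard errors well inside the asserted tolerances. Every stochastic step
is seeded; runs with equal seeds are bit-identical, which the suite asserts
for the generator, the pipeline CSV outputs, and the fixture writer.

## Known limitations

* The nearest-stain rule attributes one component mean per cell; it cannot
  express partial ownership when a single stain component spans several
  cells, and it inherits any segmentation errors.
* Otsu thresholding on a stain channel with two well-separated positive
  populations can place the threshold between the populations rather than
  between background and signal; for exact-recovery analyses a fixed global
  stain threshold is the appropriate configuration.
* The fusion-index automation assumes membrane boundaries form closed
  regions; broken membranes merge regions and bias N upward. The manual
  counts path is the reference.
* The large-sample Mann-Whitney p is an approximation; at group sizes below
  ~20 the exact enumeration should be preferred (it is included).
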