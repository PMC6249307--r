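---
title: "Methods: quantitative MSI drug-distribution mapping with msipk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative MSI drug-distribution mapping with msipk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

msipk re-implements, as a tested pipeline, an integrated pharmacokinetic /
pharmacodynamic mapping analysis for intracranial tumor models: quantitative
3D MALDI MSI of drug distribution, t-SNE-based registration of MSI sections
to MR volumes, ROI segmentation with colocalization statistics, and
correlation-based integration of phosphoproteomic and transcriptomic
response. This vignette describes the models and procedures, the parameters
that matter, what the synthetic phantoms do and do not emulate, and the
numerical choices behind the implementation.

## 1. MSI data model and ion images

A dataset is a set of centroided peak lists on a raster grid (default
geometry: 100 µm pixels in-plane, 160 µm between serial sections). An ion
image for a target mass `m0` with tolerance `tol` is the per-pixel sum of
centroid intensities with `|m - m0| <= tol`; the interval is closed at both
edges and guarded by a 1e-9 Da epsilon against floating-point representation
of the edges. Windows are absolute ±Da (default ±0.001, matching
FT-ICR-class resolving power); a ppm-window option exists but is off by
default. Multiple peaks in a window are summed, not maximized, which keeps
extraction linear in the underlying spectra (a property the test suite
checks directly). Off-tissue pixels are explicit `NA`s and are excluded from
every statistic.

Mass accuracy is reported as signed ppm error,
`(measured − reference)/reference × 1e6`. Reference masses are an explicit
input because published ∆ppm values do not state whether theoretical or
library masses were used.

The imzML-dialect writer/reader (processed mode, float64 external arrays)
exists because no installed R package parses imzML; it follows the standard
layout (XML with external byte offsets into an `.ibd` sidecar, 1-based pixel
coordinates) so files interoperate at the structural level. In memory the
package uses R's native 1-based matrix indexing.

## 2. Tissue-mimetic calibration

Intensity is modeled as linear in concentration, `I = a·c + b`, fitted by
ordinary least squares on the spiked-homogenate series (default design: the
seven levels 50 000 … 500 ng g⁻¹). A `1/Y²` weighting option mirrors the
weighting used by reference LC–MS/MS assays; unweighted is the default since
no weighting is stated for MSI curves. r² is computed from the (weighted)
residuals directly rather than via `summary.lm`, because a noiseless series
is a legitimate input that `summary.lm` warns about. Concentration maps
invert the line per pixel; negative back-calculations are clipped to zero
and counted, out-of-range values are counted but retained. Fitting requires
three or more levels; the generator will happily simulate a single level for
bookkeeping and arithmetic checks.

## 3. Segmentation and regional statistics

Pixels are vectorized by binning their spectra on a fixed 0.005 Da grid and
L2-normalizing each pixel, making clusters intensity-scale-free. Binning is
*linear* (each centroid shares intensity between the two nearest bin
centers): the analyte masses can sit exactly on hard-bin boundaries, where
ppm jitter flips pixels between bins and injects purely artifactual
variance. Bisecting k-means then repeatedly splits the cluster with the
largest within-cluster sum of squares using 2-means (10 seeded restarts)
until `k` clusters remain; the total within-cluster SSE is non-increasing in
`k`. The tumor cluster is identified as the one with the highest mean
biomarker-channel intensity (m/z 503.949 by default).

The core/edge split erodes the tumor mask with a square structuring element
(`depth_px`, default 2 px = 200 µm at 100 µm pixels; the geometric
definition of "edge" is not standardized, so the depth is exposed).
Regional statistics (mean, median, sd, IQR, pixel count) run over present
pixels only, and quadrant masks split an ROI about its centroid into
R1/R2/L1/L2 for dissection-style relative-intensity summaries (percent of
the maximum region).

## 4. t-SNE color embedding and registration

The registration guide image is built by embedding each tissue pixel's
binned spectrum into 3D with exact t-SNE (perplexity 30, 500 iterations by
default — the upstream settings are unpublished, so these are package
defaults) and min–max scaling the axes into the L\*, a\*, b\* channels.
Exact (O(n²)) t-SNE is appropriate at section scale (hundreds to a few
thousand tissue pixels) and is deterministic for a fixed seed.

Transforms map fixed-frame (MR) coordinates to moving-frame (MSI)
coordinates, the resampling convention, so warping evaluates
`moving(T(x))` on the fixed grid. The chain is an affine transform followed
by an additive cubic B-spline displacement field on the fixed frame.

*Affine stage.* Nelder-Mead over six pose parameters (rotation, two log
scales, shear, translation about the fixed-image center) on a 3-level
resolution pyramid, seeded by centroid alignment and a coarse rotation
multi-start (±30° in 5° steps) because the similarity landscape has
rotational local minima. Similarity is Mattes-style mutual information with
a partial-volume (soft-binned, 32-bin) joint histogram — soft binning keeps
the landscape smooth enough for a simplex optimizer — or mean squares on
z-scored intensities for same-modality problems. Similarity is evaluated
over the overlap region only, with a hard floor on the overlap fraction so
shrinking the overlap cannot pay; a final similarity floor turns grossly
mismatched inputs into a classed failure with the optimizer trace attached.

*B-spline stage.* Control points on an 8 px grid (one cell margin beyond
the image); displacement is the tensor-product cubic B-spline of the
control displacements. The data term is mean squares with an analytic
gradient (chain rule through bilinear interpolation of the moving image),
regularized by a first-difference smoothness penalty on the control grid —
a plain ridge is the wrong prior here because it pulls featureless regions
toward zero displacement instead of letting them inherit their neighbors'
motion. Optimization is L-BFGS-B under a coarse-to-fine blur-continuation
schedule (box radii 3/1/0 and 4/2/1/0 as two candidates; the candidate with
the lower final raw-image mean squares is kept — a deterministic model
selection). If the fitted field improves the data term by less than 5%
relative to the affine-only alignment, the identity field is returned: with
purely affine truth there is no evidence for a non-rigid component, and
refinement must not degrade the alignment by chasing noise. Cross-modality
pairs can be histogram-matched before the mean-squares refinement.

Registration quality is scored only against synthetic ground truth, as mean
target registration error (TRE) over identifiable landmarks — structure
boundaries (tissue, tumor, ventricle outlines) and vessel pixels. Interior
pixels of homogeneous regions are not landmarks: no intensity-driven method
can recover their displacement, and landmark-based TRE is the standard
definition. On the default phantoms the affine stage recovers a planted
10°/1.1×/(5, −3) px pose to ~0.1 px; the B-spline stage recovers an added
3 px sinusoidal warp to 1.2–1.6 px from the affine initialization.
Cross-modality alignment (drug image or t-SNE image vs. MR anatomy)
carries an irreducible content bias of roughly 1–2 px because the two
contrasts genuinely disagree about where structure is.

## 5. Colocalization

Pearson r between co-registered channels over jointly present pixels
(pairwise-complete deletion), optionally within an ROI; a 3D volume is
correlated over all sections' pixels concatenated, which the tests verify
against a flattening oracle. Raw r is canonical; a clip-at-zero view mirrors
the 0–1 display convention in which inverse distributions count as no
colocalization. Constant channels within a region make the correlation
undefined — an error from `pearson_pair()`, and a skipped-with-warning row
in `correlation_table()` (a noise-free phantom legitimately produces
constant heme inside the vessel-free core). No smoothing is applied before
correlation.

## 6. Multi-omic integration

TMT normalization is two-step: divide each sample by its crude-analysis
median (loading correction), then express every feature as the ratio to the
same run's normalization channel; a zero/missing normalization value flags
the feature missing in that run. Technical replicates of the same tumor are
collapsed by geometric mean (undefined at zero, which is an error, not a
silent drop). Transcripts get `log2((v + 0.001)/(v_ref + 0.001))` against a
designated reference tumor; base 2 is the package's fold-change convention
(the original base is unstated) and is recorded in the output attributes.

Feature-by-feature Pearson correlation across the shared samples yields the
matrix whose row vectors are clustered: Euclidean distance with average
(UPGMA) or McQuitty (WPGMA) linkage via `stats::hclust`, plus exact optimal
leaf ordering (dynamic programming over all orderings consistent with the
tree, minimizing the summed adjacent-leaf distance). The exact DP is cubic
to quartic in leaf count and implemented in pure R, so it is capped at 40
leaves; above that the native order is kept with a message. Tests verify
the merge heights against an exhaustive agglomeration oracle for both
linkages and that the optimal order never worsens adjacent-leaf similarity.

Group comparisons use the pooled-variance unpaired two-tailed t-test
(`df = n₁ + n₂ − 2`, matching the published df values for 3-vs-3 and 2-vs-2
designs), with `p = 2·S(|t|)` from the central t survival function. Zero
pooled variance with equal means gives `t = 0, p = 1`; with unequal means
the statistic degenerates to infinity and is flagged. IF-style
quantification replaces manual nuclear-channel ROIs with Otsu thresholding
plus largest connected component (a manual mask can be supplied for
parity). Interaction-network tables are filtered at confidence strictly
greater than 0.9 with text-mining evidence excluded.

## 7. What the phantoms emulate — and what they do not

The MSI phantom plants, per section: a brain-shaped tissue ellipse, an
elliptical tumor whose radius varies along z, a core/edge partition by
erosion, a ventricle, a sparse branching vessel map (~5–10% of tissue, half
the walks seeded at the tumor edge, emulating peritumoral vasculature), and
multi-scale lognormal-textured intensity fields. The planted structure is
exact by construction: region means are rescaled after texturing so that at
zero noise the core/edge mean ratio equals `core_edge_ratio` (default 2.0)
and the metabolite/drug intensity ratio over the tumor equals
`metabolite_fraction` (default 0.1) to machine precision. The edge drug
field co-varies with the same binary-vessel-plus-halo signal that drives
the heme channel, so drug–heme correlation concentrates in the edge; the
core's texture is vessel-independent. The metabolite adds a moderate
ventricle hotspot (2× the mean tissue metabolite level, a CSF-accumulation
stand-in). Spectra carry the four analyte channels plus two endogenous
background peaks, uniform ppm jitter on centroid positions (±0.5 ppm
default) and multiplicative lognormal noise (CV 0.15 default, mean 1).

The MR phantom renders an anatomical image from the masks, with a
contrast-enhancing region drawn strictly inside the tumor, in a frame
displaced by a known affine (default 10°, 1.1×, (5, −3) px) plus an
optional smooth sinusoidal warp whose amplitude and period are parameters;
the analytic deformation is stored so TRE is computable exactly.

The omics generator mirrors a two-run TMT design: one tumor per condition
per run, with the vehicle tumor shared by both runs as normalization
channel and technical replicate (matrix shape `n_phospho × 8` for four
conditions). A dose-responsive module decreases linearly from 1 to 0.25
across conditions; transcripts carry suppressed and induced blocks
(anti-correlated after the log-ratio transform) plus unstructured genes and
a sprinkling of exact zeros. The phosphopeptide count defaults to 210; the
companion count of 212 that appears in some descriptions is equally valid —
the count is a parameter, not a constant.

What passing these tests does *not* show about real data: phantoms have no
isotope envelopes, no FT-ICR lineshapes or resolution-dependent peak
shapes, no matrix/ionization suppression gradients, no section-to-section
thickness variation, no histology, and their deformations are smooth and
known. Real registration accuracy, in particular, cannot be certified by
phantom TRE; the pipeline still emits overlay images for visual assessment.

## 8. Problem sizes, determinism, degenerate inputs

Default validation sizes are chosen so the whole suite runs in well under a
minute on one core: 40–64 px grids with 1–2 sections (1 000–2 600 tissue
pixels), 7-level calibration series, 10⁴-pixel planted-correlation fields,
7-leaf clustering fixtures with 30–36-leaf module-recovery cases, and
210 × 8 omics matrices. Every stochastic step is seeded; equal seeds give
bit-identical phantoms, embeddings and pipeline outputs (the run manifest
records per-stage output hashes to make this checkable). Degenerate inputs
are first-class: all-identical spectra produce a constant color image with
a warning, empty ROIs and empty calibration series are classed errors,
zero-TIC pixels become missing with a warning, constant features are
excluded from correlation matrices with a warning, and a stage failure in
the pipeline halts with the stage name attached.

## 9. Known limitations

- The exact optimal-leaf-ordering DP is pure R and capped at 40 leaves.
- The B-spline stage's data term is mean squares; cross-modality refinement
  relies on prior histogram matching rather than a gradient-based MI.
- Dose-monotonicity of the planted phospho module is asserted on
  per-condition means: the generator gives two tumors per condition
  identical planted effects, so their within-condition ordering is a coin
  flip by design.
- 2D registration per section, as in the workflow being modeled; no 3D
  deformable registration.
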