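# msipk

Quantitative MALDI mass spectrometry imaging (MSI), multimodal registration
and multi-omic integration for mapping drug penetration in intracranial
tumor models.

## The problem

Drug delivery into brain tumors is limited by the blood–brain barrier, and
its disruption is spatially heterogeneous: the invasive tumor edge typically
receives far less drug than the contrast-enhancing core. Characterizing this
heterogeneity requires stitching together several quantitative analyses:

- **Ion imaging and 3D reconstruction.** MALDI MSI acquires a centroided
  mass spectrum at every raster position (e.g. 100 µm pixels, serial coronal
  sections every 160 µm). An *ion image* for an analyte is the per-pixel sum
  of centroid intensities within a narrow window, `|m/z − m₀| ≤ Δ` (±0.001 Da
  here), e.g. erlotinib at m/z 394.176, its M13/M14 metabolite at 380.160,
  heme (a vasculature surrogate) at 616.177, and a tumor biomarker at
  503.949.
- **Tissue-mimetic calibration.** Spiked homogenate standards (seven levels:
  50 000, 10 000, 7 500, 5 000, 2 500, 1 000, 500 ng g⁻¹) give a linear map
  `I = a·c + b` from intensity to absolute concentration; inverting it per
  pixel turns ion images into ng g⁻¹ maps.
- **Segmentation and regional statistics.** Tissue pixels are clustered by
  their binned, L2-normalized spectra with *bisecting k-means* (repeatedly
  2-means-splitting the cluster with largest within-cluster scatter); the
  tumor cluster is split into core and invading edge by square-element
  erosion, and per-region means/medians/IQRs summarize the concentration
  maps.
- **t-SNE based multimodal registration.** Each pixel's spectrum is embedded
  into 3D with t-SNE and the axes feed the L\*, a\*, b\* channels of a color
  image, turning molecular similarity into color similarity. That image is
  aligned to an MR slice by an affine transform (Mattes mutual information,
  multi-resolution Nelder-Mead) followed by a cubic B-spline free-form
  refinement; every m/z image can then be warped into the MR frame.
- **Colocalization.** Pearson correlation between co-registered ion images
  (2D or whole 3D volumes), per region: drug vs. metabolite, drug vs. heme
  in core vs. edge.
- **Multi-omic response integration.** TMT phosphoproteomic matrices are
  normalized by per-sample crude medians, expressed as ratios to each run's
  normalization channel, and technical replicates are averaged
  geometrically; FPKM transcript matrices get a 0.001 pseudocount, a
  reference-tumor ratio and a log2 transform. Feature-by-feature Pearson
  correlation matrices are clustered hierarchically (Euclidean distance,
  average/UPGMA or McQuitty/WPGMA linkage) with exact optimal leaf ordering,
  and interaction-network edge tables are filtered at confidence > 0.9
  excluding text-mining evidence. Group comparisons use the unpaired
  two-tailed pooled-variance t-test, `df = n₁ + n₂ − 2`.

Every stage is validated on seeded synthetic phantoms with full ground
truth: a multi-section brain phantom with a ~2× core/edge drug gradient, a
metabolite channel at ~1/10 of the parent drug, a sparse vessel map coupled
to the edge drug field, an MR phantom displaced by a known affine + smooth
warp, a 7-level calibration series, and omics matrices with planted
dose-responsive and anti-correlated modules.

## Worked example

```r
library(msipk)

cfg <- phantom_config(grid_shape = c(48, 48), n_sections = 2,
                      noise_cv = 0.15, seed = 7)
ph    <- generate_msi_phantom(cfg)
drug  <- extract_ion_image(ph$dataset[[1]], 394.176, 0.001)
model <- fit_calibration(generate_calibration_series(slope = 2, noise_cv = 0))
map   <- apply_calibration(drug, model)

seg <- segment_bisecting_kmeans(ph$dataset[[1]], k = 2, seed = 7)
ce  <- split_core_edge(seg$masks$tumor, depth_px = 3)
dplyr::bind_rows(roi_statistics(map, ce$core), roi_statistics(map, ce$edge))
#> # A tibble: 2 × 7
#>   label  mean median    sd   iqr n_pixels units
#>   <chr> <dbl>  <dbl> <dbl> <dbl>    <int> <chr>
#> 1 core  2789.  2771.  467.  574.       66 ng/g
#> 2 edge  1404.  1712.  844. 1571.      167 ng/g
```

The recovered core/edge concentration ratio is 1.99 — the phantom plants a
2-fold gradient, mirroring the roughly two-fold drop in drug concentration
at the invasive edge seen in tissue. Colocalization shows the same spatial
story: drug–heme correlation is concentrated at the vessel-limited edge.

```r
vols <- lapply(c(drug = 394.176, heme = 616.177), function(mz)
  stack_volume(lapply(ph$dataset, extract_ion_image, target_mz = mz), 160))
correlation_table(vols, regions = list(core = ph$truth$core_mask,
                                       edge = ph$truth$edge_mask))
#> # A tibble: 3 × 6
#>   channel_a channel_b region       n_pixels  r_raw r_clipped
#> 1 drug      heme      whole_tissue     2552 0.432     0.432
#> 2 drug      heme      core              132 0.0857    0.0857
#> 3 drug      heme      edge              328 0.862     0.862

t_pvalue(4.213, 4)   # two-tailed p for a printed t/df pair -> 0.0136
```

`run_pipeline(pipeline_config(...))` chains all stages (simulation, ion
images, calibration, segmentation, registration, colocalization, omics
integration) and writes per-stage outputs plus a manifest with seeds and
output hashes; `inst/cli/msipk.R` is a thin command-line wrapper with
`simulate` / `quantify` / `register` / `run-all` style subcommands.

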