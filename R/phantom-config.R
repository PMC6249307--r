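#' Phantom configuration
#'
#' Bundles the parameters of the synthetic multi-section brain phantom used to
#' validate the imaging pipeline. Defaults mirror the acquisition geometry of
#' the study the package models: 100 um raster pixels, coronal sections every
#' 160 um, channels for the parent drug (m/z 394.176), its M13/M14 metabolite
#' (380.160), heme as a vasculature surrogate (616.177) and a tumor biomarker
#' (503.949), a ~2-fold core-to-edge drug gradient and a metabolite at ~1/10
#' of the parent intensity.
#'
#' @param grid_shape integer(2), pixels as (rows, cols).
#' @param n_sections number of serial sections (>= 1).
#' @param pixel_size in-plane pixel size, um.
#' @param z_spacing distance between sections, um.
#' @param channels data frame with columns `name` and `mz` (Da). The defaults
#'   are the four channels above; a `drug` and `biomarker` channel must be
#'   present (quantification and tumor identification depend on them).
#' @param core_edge_ratio mean core / mean edge drug concentration planted in
#'   the tumor (>= 1).
#' @param metabolite_fraction metabolite intensity as a fraction of the parent
#'   drug intensity, in (0, 1].
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   pixel noise (0 disables noise).
#' @param mz_jitter_ppm half-width of the uniform ppm jitter applied to every
#'   centroid position.
#' @param core_conc planted drug concentration in the tumor core, ng/g.
#' @param brain_conc planted concentration in normal brain, ng/g.
#' @param cal_slope,cal_intercept linear map from concentration (ng/g) to
#'   drug-channel intensity used when rendering spectra.
#' @param core_depth_px erosion depth (px) separating planted core from edge.
#' @param seed integer seed; equal seeds give bit-identical phantoms.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @export
#' @examples
#' cfg <- phantom_config(grid_shape = c(48, 48), n_sections = 3, noise_cv = 0)
#' cfg$core_edge_ratio
phantom_config <- function(grid_shape = c(64, 64),
                           n_sections = 8,
                           pixel_size = 100,
                           z_spacing = 160,
                           channels = default_channels(),
                           core_edge_ratio = 2.0,
                           metabolite_fraction = 0.1,
                           noise_cv = 0.15,
                           mz_jitter_ppm = 0.5,
                           core_conc = 2800,
                           brain_conc = 600,
                           cal_slope = 2,
                           cal_intercept = 0,
                           core_depth_px = 3,
                           seed = 1L) {
  assert_that(is.numeric(grid_shape) && length(grid_shape) == 2 &&
                all(grid_shape >= 8) && all(grid_shape == round(grid_shape)),
              "`grid_shape` must be two positive integers (>= 8 px)",
              "msipk_config_error")
  assert_that(is_scalar_number(n_sections) && n_sections >= 1 &&
                n_sections == round(n_sections),
              "`n_sections` must be a positive integer", "msipk_config_error")
  assert_that(is_scalar_number(pixel_size) && pixel_size > 0,
              "`pixel_size` must be > 0", "msipk_config_error")
  assert_that(is_scalar_number(z_spacing) && z_spacing > 0,
              "`z_spacing` must be > 0", "msipk_config_error")
  assert_that(is.data.frame(channels) &&
                all(c("name", "mz") %in% names(channels)) &&
                nrow(channels) >= 1 && all(channels$mz > 0),
              "`channels` must be a data frame with columns name, mz (> 0)",
              "msipk_config_error")
  assert_that(all(c("drug", "biomarker") %in% channels$name),
              "`channels` must include a 'drug' and a 'biomarker' channel",
              "msipk_config_error")
  assert_that(is_scalar_number(core_edge_ratio) && core_edge_ratio >= 1,
              "`core_edge_ratio` must be >= 1", "msipk_config_error")
  assert_that(is_scalar_number(metabolite_fraction) &&
                metabolite_fraction > 0 && metabolite_fraction <= 1,
              "`metabolite_fraction` must be in (0, 1]", "msipk_config_error")
  assert_that(is_scalar_number(noise_cv) && noise_cv >= 0,
              "`noise_cv` must be >= 0", "msipk_config_error")
  assert_that(is_scalar_number(mz_jitter_ppm) && mz_jitter_ppm >= 0,
              "`mz_jitter_ppm` must be >= 0", "msipk_config_error")
  assert_that(is_scalar_number(cal_slope) && cal_slope > 0,
              "`cal_slope` must be > 0", "msipk_config_error")
  assert_that(is_scalar_number(core_conc) && core_conc > 0 &&
                is_scalar_number(brain_conc) && brain_conc > 0,
              "planted concentrations must be > 0", "msipk_config_error")
  assert_that(is_scalar_number(core_depth_px) && core_depth_px >= 1,
              "`core_depth_px` must be >= 1", "msipk_config_error")

  structure(list(
    grid_shape = as.integer(grid_shape),
    n_sections = as.integer(n_sections),
    pixel_size = pixel_size,
    z_spacing = z_spacing,
    channels = tibble::as_tibble(channels),
    core_edge_ratio = core_edge_ratio,
    metabolite_fraction = metabolite_fraction,
    noise_cv = noise_cv,
    mz_jitter_ppm = mz_jitter_ppm,
    core_conc = core_conc,
    brain_conc = brain_conc,
    cal_slope = cal_slope,
    cal_intercept = cal_intercept,
    core_depth_px = as.integer(core_depth_px),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Default phantom channel table
#'
#' The four m/z channels imaged in the study: erlotinib (parent drug), its
#' M13/M14 metabolite, heme (vasculature surrogate) and a tumor biomarker.
#'
#' @return A tibble with columns `name` and `mz` (Da).
#' @export
default_channels <- function() {
  tibble::tibble(
    name = c("drug", "metabolite", "heme", "biomarker"),
    mz = c(394.176, 380.160, 616.177, 503.949)
  )
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  grid: %d x %d px, %d sections (%g um px, %g um z)\n",
              x$grid_shape[1], x$grid_shape[2], x$n_sections,
              x$pixel_size, x$z_spacing))
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s=%.3f", x$channels$name, x$channels$mz),
                    collapse = ", ")))
  cat(sprintf("  core/edge ratio %.2f, metabolite fraction %.2f, noise CV %.2f, seed %d\n",
              x$core_edge_ratio, x$metabolite_fraction, x$noise_cv, x$seed))
  invisible(x)
}
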