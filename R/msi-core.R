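#' MSI dataset constructor
#'
#' An `msi_dataset` holds centroided per-pixel mass spectra on a fixed 2D
#' raster grid, with physical pixel size and the section's z-index. Only
#' tissue pixels carry spectra; all other grid positions are missing.
#'
#' @param spectra list of per-pixel spectra, each `list(mz=, intensity=)` with
#'   `mz` strictly increasing and intensities >= 0.
#' @param coords integer matrix (n_pixels x 2) of 1-based (row, col) grid
#'   positions, one row per spectrum.
#' @param grid_shape integer(2): (rows, cols) of the raster.
#' @param pixel_size in-plane pixel size, um (> 0).
#' @param z_spacing section spacing, um (> 0).
#' @param section_index integer z-index of this section.
#' @param metadata list; `polarity` and `mz_range` are used by downstream
#'   operations.
#' @return An `msi_dataset` object.
#' @export
new_msi_dataset <- function(spectra, coords, grid_shape, pixel_size,
                            z_spacing = NA_real_, section_index = 1L,
                            metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  dimnames(coords) <- list(NULL, c("row", "col"))
  assert_that(length(spectra) == nrow(coords),
              "`spectra` and `coords` must have matching length",
              "msipk_format_error")
  assert_that(is_scalar_number(pixel_size) && pixel_size > 0,
              "`pixel_size` must be > 0")
  assert_that(all(coords[, 1] >= 1) && all(coords[, 2] >= 1) &&
                all(coords[, 1] <= grid_shape[1]) &&
                all(coords[, 2] <= grid_shape[2]),
              "pixel coordinates must lie on the grid", "msipk_format_error")
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    validate_spectrum(s, sprintf("pixel %d (row %d, col %d)",
                                 i, coords[i, 1], coords[i, 2]))
  }
  structure(list(
    spectra = spectra,
    coords = coords,
    grid_shape = as.integer(grid_shape),
    pixel_size = pixel_size,
    z_spacing = z_spacing,
    section_index = as.integer(section_index),
    metadata = metadata
  ), class = "msi_dataset")
}

validate_spectrum <- function(s, where) {
  assert_that(is.list(s) && all(c("mz", "intensity") %in% names(s)),
              sprintf("spectrum at %s must have mz and intensity", where),
              "msipk_format_error")
  assert_that(length(s$mz) == length(s$intensity),
              sprintf("mz/intensity length mismatch at %s", where),
              "msipk_format_error")
  if (length(s$mz) > 1) {
    assert_that(all(diff(s$mz) > 0),
                sprintf("mz must be strictly increasing at %s", where),
                "msipk_format_error")
  }
  assert_that(all(s$intensity >= 0),
              sprintf("negative intensity at %s", where),
              "msipk_format_error")
  invisible(TRUE)
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> section %d: %d x %d grid, %d tissue pixels, %g um px\n",
              x$section_index, x$grid_shape[1], x$grid_shape[2],
              length(x$spectra), x$pixel_size))
  invisible(x)
}

#' Ion image constructor
#'
#' A scalar intensity grid for one m/z window. Off-tissue pixels are `NA` and
#' are excluded from every downstream statistic.
#'
#' @param values numeric matrix, `NA` where no spectrum exists.
#' @param target_mz window center, Da.
#' @param tolerance window half-width, Da (> 0).
#' @param pixel_size um.
#' @param section_index section z-index the image came from.
#' @return An `ion_image` object.
#' @export
new_ion_image <- function(values, target_mz, tolerance, pixel_size,
                          section_index = 1L) {
  assert_that(is.matrix(values), "`values` must be a matrix")
  assert_that(all(values >= 0, na.rm = TRUE),
              "ion-image values must be >= 0 where present")
  assert_that(is_scalar_number(tolerance) && tolerance > 0,
              "`tolerance` must be > 0")
  structure(list(values = values, target_mz = target_mz,
                 tolerance = tolerance, pixel_size = pixel_size,
                 section_index = as.integer(section_index)),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> m/z %.4f +/- %.4g Da, %d x %d px (%d present)\n",
              x$target_mz, x$tolerance, nrow(x$values), ncol(x$values),
              sum(!is.na(x$values))))
  invisible(x)
}

#' Extract an ion image from an MSI dataset
#'
#' For each tissue pixel, sums the intensities of all centroids whose m/z lies
#' within the closed window `target_mz` +/- `tolerance` (the study used
#' +/- 0.001 Da windows). Pixels without a spectrum are missing (`NA`).
#' Extraction is linear in the underlying spectra and the window is inclusive
#' at both edges.
#'
#' @param dataset an [msi_dataset][new_msi_dataset].
#' @param target_mz window center, Da.
#' @param tolerance half-width, Da (> 0; default 0.001).
#' @param ppm if `TRUE`, `tolerance` is interpreted in ppm of `target_mz`
#'   instead of Da (off by default).
#' @return An [ion_image][new_ion_image].
#' @export
#' @examples
#' ph <- generate_msi_phantom(phantom_config(grid_shape = c(24, 24),
#'                                           n_sections = 1, noise_cv = 0))
#' img <- extract_ion_image(ph$dataset[[1]], 394.176)
#' range(img$values, na.rm = TRUE)
extract_ion_image <- function(dataset, target_mz, tolerance = 0.001,
                              ppm = FALSE) {
  assert_that(inherits(dataset, "msi_dataset"), "`dataset` must be an msi_dataset")
  assert_that(is_scalar_number(tolerance) && tolerance > 0,
              "`tolerance` must be > 0")
  tol_da <- if (ppm) target_mz * tolerance * 1e-6 else tolerance
  rng <- dataset$metadata$mz_range
  if (!is.null(rng) &&
      (target_mz + tol_da < rng[1] || target_mz - tol_da > rng[2])) {
    warning(sprintf("window %.4f +/- %.4g Da lies outside the dataset m/z range [%g, %g]; returning a zero image",
                    target_mz, tol_da, rng[1], rng[2]),
            call. = FALSE)
  }
  vals <- matrix(NA_real_, dataset$grid_shape[1], dataset$grid_shape[2])
  # guard the closed interval against floating-point representation of the
  # window edges (1e-9 Da is far below any centroid spacing)
  eps <- 1e-9
  lo <- target_mz - tol_da - eps; hi <- target_mz + tol_da + eps
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    j1 <- findInterval(lo, s$mz, left.open = TRUE) + 1L
    j2 <- findInterval(hi, s$mz)
    v <- if (j2 >= j1) sum(s$intensity[j1:j2]) else 0
    vals[dataset$coords[i, 1], dataset$coords[i, 2]] <- v
  }
  new_ion_image(vals, target_mz, tol_da, dataset$pixel_size,
                dataset$section_index)
}

#' Signed ppm mass error
#'
#' `(measured - reference) / reference * 1e6`. The reference mass is an
#' explicit input (theoretical or library value, e.g. the erlotinib
#' \[M+H\]+ at 394.1761 Da).
#'
#' @param measured_mz measured m/z, Da.
#' @param reference_mz reference m/z, Da (> 0).
#' @return Signed mass error in ppm (vectorized).
#' @export
#' @examples
#' ppm_error(394.1760, 394.1761)  # about -0.25 ppm
ppm_error <- function(measured_mz, reference_mz) {
  assert_that(all(reference_mz > 0), "`reference_mz` must be > 0")
  (measured_mz - reference_mz) / reference_mz * 1e6
}

#' Stack ion images into a 3D ion volume
#'
#' Orders sections by their `section_index` and stacks them at `z_spacing`
#' intervals (the study acquired sections every 160 um). The physical z
#' coordinate of the section with sorted position k (1-based) is
#' `(k - 1) * z_spacing`.
#'
#' @param images list of [ion_image][new_ion_image]s with identical grid shape.
#' @param z_spacing um between sections (> 0).
#' @return An `ion_volume`: list with `images` (sorted), `z_spacing`,
#'   and `z_um` (physical z of each section).
#' @export
stack_volume <- function(images, z_spacing) {
  assert_that(is.list(images) && length(images) >= 1,
              "`images` must be a non-empty list of ion images")
  assert_that(all(vapply(images, inherits, logical(1), "ion_image")),
              "all elements must be ion_image objects")
  assert_that(is_scalar_number(z_spacing) && z_spacing > 0,
              "`z_spacing` must be > 0")
  shp <- dim(images[[1]]$values)
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]$values), shp)) {
      abort_msipk(sprintf("section %d has grid %d x %d, expected %d x %d",
                          i, nrow(images[[i]]$values), ncol(images[[i]]$values),
                          shp[1], shp[2]),
                  "msipk_shape_error")
    }
  }
  idx <- vapply(images, function(im) im$section_index, integer(1))
  images <- images[order(idx)]
  structure(list(images = images, z_spacing = z_spacing,
                 z_um = (seq_along(images) - 1) * z_spacing),
            class = "ion_volume")
}

#' @export
print.ion_volume <- function(x, ...) {
  cat(sprintf("<ion_volume> %d sections at %g um spacing, grid %d x %d\n",
              length(x$images), x$z_spacing,
              nrow(x$images[[1]]$values), ncol(x$images[[1]]$values)))
  invisible(x)
}

#' Total-ion-current normalization
#'
#' Divides each pixel's intensities by that pixel's total ion current (TIC).
#' The study applied no spectral normalization, so this is an optional
#' preprocessing step, off by default everywhere in the pipeline. For an
#' `msi_dataset` the spectra themselves are rescaled; for an `ion_image` a
#' matching TIC image must be supplied.
#'
#' @param x an `msi_dataset` or `ion_image`.
#' @param tic for an `ion_image`: a matrix of per-pixel TIC values.
#' @return Object of the same class, TIC-normalized. Zero-TIC tissue pixels
#'   are marked missing with a warning.
#' @export
tic_normalize <- function(x, tic = NULL) {
  UseMethod("tic_normalize")
}

#' @export
tic_normalize.msi_dataset <- function(x, tic = NULL) {
  dropped <- 0L
  for (i in seq_along(x$spectra)) {
    tt <- sum(x$spectra[[i]]$intensity)
    if (tt <= 0) {
      x$spectra[[i]]$intensity <- rep(NA_real_, length(x$spectra[[i]]$intensity))
      dropped <- dropped + 1L
    } else {
      x$spectra[[i]]$intensity <- x$spectra[[i]]$intensity / tt
    }
  }
  if (dropped > 0) {
    warning(sprintf("%d zero-TIC tissue pixel(s) marked missing", dropped),
            call. = FALSE)
  }
  x$metadata$tic_normalized <- TRUE
  x
}

#' @export
tic_normalize.ion_image <- function(x, tic = NULL) {
  assert_that(is.matrix(tic) && identical(dim(tic), dim(x$values)),
              "`tic` must be a matrix matching the image grid")
  zero <- !is.na(x$values) & (is.na(tic) | tic <= 0)
  out <- x$values / ifelse(tic > 0, tic, NA_real_)
  if (any(zero)) {
    out[zero] <- NA_real_
    warning(sprintf("%d zero-TIC tissue pixel(s) marked missing", sum(zero)),
            call. = FALSE)
  }
  x$values <- out
  x
}

#' Per-pixel total ion current image
#'
#' @param dataset an `msi_dataset`.
#' @return An [ion_image][new_ion_image]-shaped matrix of TIC values
#'   (`NA` off tissue).
#' @export
tic_image <- function(dataset) {
  assert_that(inherits(dataset, "msi_dataset"), "`dataset` must be an msi_dataset")
  vals <- matrix(NA_real_, dataset$grid_shape[1], dataset$grid_shape[2])
  for (i in seq_along(dataset$spectra)) {
    vals[dataset$coords[i, 1], dataset$coords[i, 2]] <-
      sum(dataset$spectra[[i]]$intensity)
  }
  vals
}
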