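#' Generate an MR-like phantom volume from MSI phantom truth
#'
#' Renders an anatomical T1-contrast-like volume from the phantom's masks:
#' tissue, ventricle, tumor, and a contrast-enhancing region drawn *smaller*
#' than the tumor (the drug's high-intensity area extends beyond contrast
#' enhancement, as observed in the study). The MR frame is displaced from the
#' MSI frame by a known affine pose plus an optional smooth sinusoidal
#' non-rigid warp; the exact deformation is recorded so registration error
#' against ground truth is computable analytically.
#'
#' @param truth a `phantom_truth` from [generate_msi_phantom()].
#' @param config the matching [phantom_config()].
#' @param rotation_deg,scale,shear,translation affine pose of the MR frame
#'   relative to the MSI frame (defaults: 10 degrees, 1.1 scale,
#'   (5, -3) px shift).
#' @param warp_amplitude amplitude (px) of the smooth sinusoidal non-rigid
#'   component (0 = pure affine).
#' @param warp_period spatial period (px) of the sinusoidal warp.
#' @param enhancing_erosion_px erosion depth making the contrast-enhancing
#'   region a strict subset of the tumor (0 = identical to tumor).
#' @return An `mri_phantom`: list with `volume` (rows x cols x sections
#'   array), `enhancing_msi` / `enhancing_mr` (per-section masks in each
#'   frame), `deformation` (the truth map from MR/fixed coordinates to
#'   MSI/moving coordinates: a [transform_chain()]-compatible list with the
#'   affine, warp parameters and a point-mapping function), and geometry.
#' @export
generate_mri_phantom <- function(truth, config,
                                 rotation_deg = 10, scale = 1.1, shear = 0,
                                 translation = c(5, -3),
                                 warp_amplitude = 0, warp_period = 24,
                                 enhancing_erosion_px = 2) {
  assert_that(inherits(truth, "phantom_truth"),
              "`truth` must come from generate_msi_phantom()")
  K <- length(truth$tissue_mask)
  nr <- nrow(truth$tissue_mask[[1]]); nc <- ncol(truth$tissue_mask[[1]])
  center <- c((nr + 1) / 2, (nc + 1) / 2)

  aff <- make_affine(rotation_deg = rotation_deg, scale = scale,
                     shear = shear, translation = translation,
                     center = center)
  warp_fun <- function(points) {
    points <- rbind2cols(points)
    if (warp_amplitude == 0) return(matrix(0, nrow(points), 2))
    cbind(warp_amplitude * sin(2 * pi * points[, 2] / warp_period),
          warp_amplitude * cos(2 * pi * points[, 1] / warp_period))
  }
  map <- function(points) {
    points <- rbind2cols(points)
    transform_points(aff, points) + warp_fun(points)
  }

  grid_pts <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  src <- map(grid_pts)

  volume <- array(0, dim = c(nr, nc, K))
  enhancing_msi <- enhancing_mr <- vector("list", K)
  for (k in seq_len(K)) {
    tumor <- truth$tumor_mask[[k]]
    enh <- if (enhancing_erosion_px > 0) {
      erode_square(tumor, enhancing_erosion_px)
    } else tumor
    anatomy <- matrix(0, nr, nc)
    anatomy[truth$tissue_mask[[k]]] <- 400
    anatomy[truth$ventricle_mask[[k]]] <- 900
    anatomy[tumor] <- 650
    anatomy[enh] <- 1000
    anatomy <- box_blur(anatomy, 1)

    slice <- bilinear_sample(anatomy, src[, 1], src[, 2], fill = 0)
    volume[, , k] <- matrix(slice, nr, nc)

    enh_mr <- nearest_sample(enh, src[, 1], src[, 2], fill = FALSE)
    enhancing_msi[[k]] <- enh
    enhancing_mr[[k]] <- matrix(as.logical(enh_mr), nr, nc)
  }

  structure(list(
    volume = volume,
    enhancing_msi = enhancing_msi,
    enhancing_mr = enhancing_mr,
    deformation = list(affine = aff,
                       warp = list(amplitude = warp_amplitude,
                                   period = warp_period),
                       map = map),
    pixel_size = config$pixel_size,
    z_spacing = config$z_spacing
  ), class = "mri_phantom")
}

#' @export
print.mri_phantom <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<mri_phantom> %d x %d x %d volume, %g um px, %g um z\n",
              d[1], d[2], d[3], x$pixel_size, x$z_spacing))
  invisible(x)
}

#' Write / read an MR-like volume as NIfTI
#'
#' Thin wrappers around RNifti carrying the phantom's voxel geometry
#' (pixel size in mm along x/y, z-spacing along z).
#'
#' @param volume 3D numeric array (or an `mri_phantom`, whose `$volume` is
#'   used).
#' @param path output `.nii` / `.nii.gz` path.
#' @param pixel_size,z_spacing voxel geometry in um (used when `volume` is a
#'   bare array).
#' @return `write_mri_nifti`: invisibly, `path`. `read_mri_nifti`: a list
#'   with `volume` (array) and the voxel geometry in um.
#' @export
write_mri_nifti <- function(volume, path, pixel_size = 100, z_spacing = 160) {
  if (inherits(volume, "mri_phantom")) {
    pixel_size <- volume$pixel_size
    z_spacing <- volume$z_spacing
    volume <- volume$volume
  }
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- c(pixel_size / 1000, pixel_size / 1000,
                           z_spacing / 1000)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mri_nifti
#' @export
read_mri_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(volume = array(as.numeric(img), dim(img)),
       pixel_size = pd[1] * 1000,
       z_spacing = if (length(pd) >= 3) pd[3] * 1000 else NA_real_)
}
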