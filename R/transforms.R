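# Spatial transforms. Convention: a transform maps *fixed*-frame pixel
# coordinates (row, col) to *moving*-frame coordinates, the resampling
# direction, so warping evaluates moving(T(x)) on the fixed grid.

#' Affine 2D transform
#'
#' @param matrix 2x2 linear part (must be invertible).
#' @param translation length-2 (row, col) translation, px.
#' @param center length-2 rotation/scaling center, px (defaults to origin).
#' @return An `affine_transform` object.
#' @export
affine_transform <- function(matrix = diag(2), translation = c(0, 0),
                             center = c(0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  assert_that(abs(det(matrix)) > 1e-12, "affine matrix must be invertible")
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "affine_transform")
}

#' Build an affine transform from pose parameters
#'
#' @param rotation_deg rotation angle, degrees (counter-clockwise in
#'   (row, col) space).
#' @param scale isotropic or length-2 (row, col) scale factor(s).
#' @param shear shear coefficient (col added to row).
#' @param translation length-2 (row, col) shift, px.
#' @param center length-2 center of rotation/scaling, px.
#' @return An [affine_transform()].
#' @export
make_affine <- function(rotation_deg = 0, scale = 1, shear = 0,
                        translation = c(0, 0), center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  if (length(scale) == 1) scale <- c(scale, scale)
  S <- diag(scale)
  Sh <- matrix(c(1, 0, shear, 1), 2, 2)
  affine_transform(R %*% Sh %*% S, translation, center)
}

#' Map points through a transform
#'
#' @param transform an `affine_transform`, `bspline_transform`, or
#'   `transform_chain`.
#' @param points n x 2 matrix of (row, col) coordinates in the fixed frame.
#' @return n x 2 matrix of coordinates in the moving frame.
#' @export
transform_points <- function(transform, points) {
  UseMethod("transform_points")
}

#' @export
transform_points.affine_transform <- function(transform, points) {
  points <- rbind2cols(points)
  centered <- sweep(points, 2, transform$center)
  out <- centered %*% t(transform$matrix)
  sweep(out, 2, transform$center + transform$translation, "+")
}

rbind2cols <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  assert_that(ncol(points) == 2, "`points` must be an n x 2 matrix")
  points
}

#' Invert an affine transform
#' @param transform an [affine_transform()].
#' @return The inverse `affine_transform`.
#' @export
invert_affine <- function(transform) {
  Ainv <- solve(transform$matrix)
  # y = A(x - c) + c + t  =>  x = Ainv(y - c - t) + c
  affine_transform(Ainv, translation = -Ainv %*% transform$translation,
                   center = transform$center + transform$translation)
}

#' Cubic B-spline free-form deformation
#'
#' A displacement field parameterized by control-point displacements on a
#' regular grid with `spacing` px between control points; the grid extends
#' one cell beyond the image on every side. The displacement at a point is
#' the tensor-product cubic B-spline interpolation of the control
#' displacements and is *added* to the point's coordinates.
#'
#' @param spacing control-point spacing, px (> 1).
#' @param disp_r,disp_c matrices (n_ctrl_r x n_ctrl_c) of row/col control
#'   displacements, px.
#' @param image_shape integer(2) shape of the fixed image the grid covers.
#' @return A `bspline_transform` object.
#' @export
bspline_transform <- function(spacing, disp_r, disp_c, image_shape) {
  assert_that(is_scalar_number(spacing) && spacing > 1,
              "`spacing` must be > 1 px")
  need <- bspline_grid_size(image_shape, spacing)
  assert_that(identical(dim(disp_r), need) && identical(dim(disp_c), need),
              sprintf("control grids must be %d x %d for this image/spacing",
                      need[1], need[2]))
  structure(list(spacing = spacing, disp_r = disp_r, disp_c = disp_c,
                 image_shape = as.integer(image_shape)),
            class = "bspline_transform")
}

bspline_grid_size <- function(image_shape, spacing) {
  c(as.integer(floor((image_shape[1] - 1) / spacing)) + 4L,
    as.integer(floor((image_shape[2] - 1) / spacing)) + 4L)
}

# Basis weight matrix: rows = points, cols = control indices along one axis.
bspline_weights_1d <- function(x, spacing, n_ctrl) {
  t <- (x - 1) / spacing
  i <- floor(t)
  u <- t - i
  B <- cbind((1 - u)^3 / 6,
             (3 * u^3 - 6 * u^2 + 4) / 6,
             (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
             u^3 / 6)
  W <- matrix(0, length(x), n_ctrl)
  for (l in 0:3) {
    idx <- i + 1L + l  # control 1 sits one cell before the image origin
    ok <- idx >= 1 & idx <= n_ctrl
    W[cbind(which(ok), idx[ok])] <- W[cbind(which(ok), idx[ok])] + B[ok, l + 1]
  }
  W
}

bspline_displacement <- function(transform, points) {
  points <- rbind2cols(points)
  Wr <- bspline_weights_1d(points[, 1], transform$spacing,
                           nrow(transform$disp_r))
  Wc <- bspline_weights_1d(points[, 2], transform$spacing,
                           ncol(transform$disp_r))
  dr <- rowSums((Wr %*% transform$disp_r) * Wc)
  dc <- rowSums((Wr %*% transform$disp_c) * Wc)
  cbind(dr, dc)
}

#' @export
transform_points.bspline_transform <- function(transform, points) {
  points <- rbind2cols(points)
  points + bspline_displacement(transform, points)
}

#' Chain of transforms (affine then B-spline refinement)
#'
#' Applied in listed order: the affine maps fixed coordinates toward the
#' moving frame and the B-spline displacement (defined on the fixed frame)
#' is added to the result.
#'
#' @param affine an [affine_transform()].
#' @param bspline optionally a [bspline_transform()].
#' @return A `transform_chain` object.
#' @export
transform_chain <- function(affine, bspline = NULL) {
  assert_that(inherits(affine, "affine_transform"),
              "`affine` must be an affine_transform")
  if (!is.null(bspline)) {
    assert_that(inherits(bspline, "bspline_transform"),
                "`bspline` must be a bspline_transform")
  }
  structure(list(affine = affine, bspline = bspline),
            class = "transform_chain")
}

#' @export
transform_points.transform_chain <- function(transform, points) {
  points <- rbind2cols(points)
  out <- transform_points(transform$affine, points)
  if (!is.null(transform$bspline)) {
    out <- out + bspline_displacement(transform$bspline, points)
  }
  out
}

#' Serialize a transform (chain) to JSON
#'
#' @param transform an affine, B-spline or chain transform.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_transform_json <- function(transform, path) {
  to_list <- function(tr) {
    if (inherits(tr, "affine_transform")) {
      list(type = "affine", matrix = tr$matrix,
           translation = tr$translation, center = tr$center)
    } else if (inherits(tr, "bspline_transform")) {
      list(type = "bspline", spacing = tr$spacing,
           disp_r = tr$disp_r, disp_c = tr$disp_c,
           image_shape = tr$image_shape)
    } else if (inherits(tr, "transform_chain")) {
      list(type = "chain", affine = to_list(tr$affine),
           bspline = if (is.null(tr$bspline)) NULL else to_list(tr$bspline))
    } else {
      abort_msipk("unknown transform type", "msipk_invalid_argument")
    }
  }
  jsonlite::write_json(to_list(transform), path, digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
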