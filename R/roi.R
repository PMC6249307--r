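#' ROI mask
#'
#' A labeled boolean pixel grid used for regional statistics. Standard labels
#' follow the study's regions (`normal_brain`, `tumor`, `core`, `edge`,
#' `T1Gd_enhancing`, `quadrant_R1/R2/L1/L2`, `flank`) but any label is
#' accepted.
#'
#' @param label character label.
#' @param pixels logical matrix; must contain at least one `TRUE` pixel.
#' @return An `roi_mask` object.
#' @export
new_roi_mask <- function(label, pixels) {
  assert_that(is.character(label) && length(label) == 1,
              "`label` must be a single string")
  assert_that(is.matrix(pixels) && is.logical(pixels),
              "`pixels` must be a logical matrix")
  assert_that(any(pixels), sprintf("ROI '%s' is empty", label),
              "msipk_empty_roi")
  structure(list(label = label, pixels = pixels), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d px on %d x %d grid\n", x$label,
              sum(x$pixels), nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "roi_mask")) mask$pixels else {
    assert_that(is.matrix(mask) && is.logical(mask),
                "`mask` must be an roi_mask or logical matrix")
    mask
  }
}

#' Split a tumor ROI into core and invading edge
#'
#' The core is the tumor eroded by `depth_px` with a square structuring
#' element; the edge is the remainder, so core and edge partition the tumor
#' exactly. The study quantified a ~2-fold drug drop from core to edge; it
#' does not define the split geometrically, so the erosion depth is an
#' explicit parameter (default 2 px = 200 um at 100 um pixels).
#'
#' @param tumor an [new_roi_mask()] (or logical matrix) marking the tumor.
#' @param depth_px erosion depth in pixels (>= 1).
#' @return List with `core` and `edge` [new_roi_mask()]s.
#' @export
split_core_edge <- function(tumor, depth_px = 2) {
  assert_that(is_scalar_number(depth_px) && depth_px >= 1 &&
                depth_px == round(depth_px),
              "`depth_px` must be a positive integer")
  m <- as_mask_matrix(tumor)
  core <- erode_square(m, depth_px)
  if (!any(core)) {
    abort_msipk(sprintf(
      "erosion by %d px empties the core; use a smaller depth_px", depth_px),
      "msipk_empty_roi")
  }
  list(core = new_roi_mask("core", core),
       edge = new_roi_mask("edge", m & !core))
}

#' Regional statistics over an ROI
#'
#' Computes mean, median, sd, IQR and pixel count over the present
#' (non-missing) pixels inside the mask, the summary underlying the study's
#' per-region concentration tables and ROI boxplots.
#'
#' @param map a `concentration_map`, `ion_image`, or numeric matrix.
#' @param mask an [new_roi_mask()] or logical matrix.
#' @return A one-row tibble: `label`, `mean`, `median`, `sd`, `iqr`,
#'   `n_pixels`, `units`.
#' @export
roi_statistics <- function(map, mask) {
  vals <- if (inherits(map, c("concentration_map", "ion_image"))) {
    map$values
  } else {
    assert_that(is.matrix(map), "`map` must be a map, image or matrix")
    map
  }
  m <- as_mask_matrix(mask)
  assert_that(identical(dim(vals), dim(m)),
              "mask and map must share the same grid", "msipk_shape_error")
  v <- vals[m]
  v <- v[!is.na(v)]
  if (length(v) < 1) {
    abort_msipk("mask overlaps no present pixels", "msipk_empty_roi")
  }
  tibble::tibble(
    label = if (inherits(mask, "roi_mask")) mask$label else "roi",
    mean = mean(v),
    median = stats::median(v),
    sd = if (length(v) > 1) stats::sd(v) else 0,
    iqr = stats::IQR(v),
    n_pixels = length(v),
    units = if (inherits(map, "concentration_map")) "ng/g" else "intensity"
  )
}

#' Tissue-to-plasma concentration ratio
#'
#' @param tissue_conc tissue concentration, ng/g.
#' @param plasma_conc plasma concentration, ng/mL (> 0).
#' @return Dimensionless ratio(s) tissue/plasma.
#' @export
#' @examples
#' tissue_to_plasma_ratio(54, 100)  # 0.54
tissue_to_plasma_ratio <- function(tissue_conc, plasma_conc) {
  assert_that(all(plasma_conc > 0), "`plasma_conc` must be > 0")
  tissue_conc / plasma_conc
}

#' Quadrant ROI masks for dissection-style regional analysis
#'
#' Splits an ROI into four quadrants about its centroid, labeled by brain
#' side (R/L, right = higher column index) and row block (1 = upper), the
#' layout used for laser-capture quadrant dissection.
#'
#' @param mask an [new_roi_mask()] or logical matrix.
#' @return Named list of four `roi_mask`s: `quadrant_R1`, `quadrant_R2`,
#'   `quadrant_L1`, `quadrant_L2` (quadrants that would be empty are
#'   dropped).
#' @export
quadrant_masks <- function(mask) {
  m <- as_mask_matrix(mask)
  idx <- which(m, arr.ind = TRUE)
  r0 <- mean(idx[, 1]); c0 <- mean(idx[, 2])
  rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  defs <- list(
    quadrant_R1 = m & rows <= r0 & cols > c0,
    quadrant_R2 = m & rows > r0 & cols > c0,
    quadrant_L1 = m & rows <= r0 & cols <= c0,
    quadrant_L2 = m & rows > r0 & cols <= c0
  )
  defs <- defs[vapply(defs, any, logical(1))]
  purrr::imap(defs, function(px, nm) new_roi_mask(nm, px))
}

#' Relative ROI intensity as percent of the maximum region
#'
#' Expresses each region's mean as a percentage of the largest region mean,
#' the convention used for per-quadrant relative drug intensity (e.g. 100%
#' in the best-perfused quadrant down to ~61% in the least).
#'
#' @param stats a tibble with columns `label` and `mean` (e.g. rows from
#'   [roi_statistics()]).
#' @return The input with an added `relative_pct` column.
#' @export
#' @examples
#' relative_quadrant_intensity(tibble::tibble(
#'   label = c("R1", "L1", "R2", "L2"), mean = c(10, 7.5, 6.45, 6.109)))
relative_quadrant_intensity <- function(stats) {
  assert_that(is.data.frame(stats) && all(c("label", "mean") %in% names(stats)),
              "`stats` must have columns label and mean")
  assert_that(nrow(stats) >= 1, "need at least one ROI")
  assert_that(all(stats$mean >= 0), "ROI means must be >= 0")
  mx <- max(stats$mean)
  if (mx <= 0) abort_msipk("all ROI means are zero", "msipk_invalid_argument")
  dplyr::mutate(tibble::as_tibble(stats),
                relative_pct = .data$mean / mx * 100)
}

#' Write ROI masks as PNG + JSON label map
#'
#' Each mask becomes a 0/255 grayscale PNG; a JSON sidecar maps labels to
#' files.
#'
#' @param masks named list of [new_roi_mask()]s.
#' @param dir output directory (created if needed).
#' @return Invisibly, the JSON sidecar path.
#' @export
write_roi_masks <- function(masks, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_msipk("the png package is required to write mask images",
                "msipk_missing_dependency")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (m in masks) {
    f <- file.path(dir, paste0(m$label, ".png"))
    png::writePNG(m$pixels * 1, f)
    entries[[m$label]] <- basename(f)
  }
  side <- file.path(dir, "roi_labels.json")
  jsonlite::write_json(entries, side, auto_unbox = TRUE)
  invisible(side)
}
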