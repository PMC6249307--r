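# Pearson colocalization between ion images / volumes.

flatten_channel <- function(x) {
  if (inherits(x, c("ion_image", "concentration_map"))) {
    as.vector(x$values)
  } else if (inherits(x, "ion_volume")) {
    unlist(lapply(x$images, function(im) as.vector(im$values)))
  } else if (is.matrix(x)) {
    as.vector(x)
  } else {
    abort_msipk("unsupported channel type for colocalization",
                "msipk_invalid_argument")
  }
}

flatten_mask <- function(mask, n) {
  if (is.null(mask)) return(rep(TRUE, n))
  if (inherits(mask, "roi_mask")) return(rep_len(as.vector(mask$pixels), n))
  if (is.list(mask)) {
    return(unlist(lapply(mask, function(m) as.vector(as_mask_matrix(m)))))
  }
  rep_len(as.vector(as_mask_matrix(mask)), n)
}

#' Pearson colocalization of two ion images or volumes
#'
#' Sample Pearson correlation over jointly present pixels (pairwise-complete:
#' missing pixels in either channel are dropped), optionally restricted to an
#' ROI. For a 3D volume the correlation runs over all sections' pixels
#' concatenated. The raw coefficient is canonical; `clip_zero = TRUE` gives
#' the 0-1 display convention in which inverse distributions count as no
#' colocalization.
#'
#' @param a,b `ion_image`s, `ion_volume`s, `concentration_map`s or matrices
#'   of equal total size.
#' @param mask optional [new_roi_mask()] (or logical matrix); for volumes, a
#'   list of per-section masks is recycled/concatenated.
#' @param clip_zero if `TRUE`, return `max(r, 0)`.
#' @return Pearson r. Attribute `n_pixels` carries the sample size.
#' @export
#' @examples
#' m <- matrix(runif(64), 8, 8)
#' pearson_pair(m, m)  # 1
pearson_pair <- function(a, b, mask = NULL, clip_zero = FALSE) {
  va <- flatten_channel(a)
  vb <- flatten_channel(b)
  assert_that(length(va) == length(vb),
              "channels must have the same total pixel count",
              "msipk_shape_error")
  keep <- flatten_mask(mask, length(va)) & !is.na(va) & !is.na(vb)
  n <- sum(keep)
  if (n < 3) {
    abort_msipk(sprintf("only %d jointly present pixels (need >= 3)", n),
                "msipk_empty_roi")
  }
  x <- va[keep]; y <- vb[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_msipk("constant channel within the region: correlation undefined",
                "msipk_undefined_correlation")
  }
  r <- stats::cor(x, y)
  if (clip_zero) r <- max(r, 0)
  structure(r, n_pixels = n)
}

#' Pairwise correlation table across channels and regions
#'
#' Pearson r for every unordered channel pair in every region, plus
#' whole-tissue rows — the per-region drug/heme availability analysis. All
#' channels must be co-registered on the same grid. Regions with fewer than
#' 3 jointly present pixels are skipped with a warning.
#'
#' @param channels named list of co-registered `ion_volume`s / `ion_image`s
#'   / matrices.
#' @param regions named list of ROI masks (per-channel-shape matrices, or
#'   lists of per-section masks for volumes). Whole-tissue rows are always
#'   included under region `"whole_tissue"`.
#' @return A `correlation_report` tibble: `channel_a`, `channel_b`,
#'   `region`, `n_pixels`, `r_raw`, `r_clipped`.
#' @export
correlation_table <- function(channels, regions = list()) {
  assert_that(is.list(channels) && length(channels) >= 2 &&
                !is.null(names(channels)),
              "`channels` must be a named list of >= 2 channels")
  if (length(regions)) {
    assert_that(!is.null(names(regions)), "`regions` must be named")
  }
  nms <- names(channels)
  region_list <- c(list(whole_tissue = NULL), regions)
  rows <- list()
  for (reg in names(region_list)) {
    for (i in seq_along(nms)) {
      for (j in seq_along(nms)) {
        if (j <= i) next
        skip <- function(e) {
          warning(sprintf("region '%s' skipped for %s/%s: %s", reg,
                          nms[i], nms[j], conditionMessage(e)),
                  call. = FALSE)
          NULL
        }
        r <- tryCatch(
          pearson_pair(channels[[i]], channels[[j]],
                       mask = region_list[[reg]]),
          msipk_empty_roi = skip,
          msipk_undefined_correlation = skip)
        if (is.null(r)) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          channel_a = nms[i], channel_b = nms[j], region = reg,
          n_pixels = attr(r, "n_pixels"),
          r_raw = as.numeric(r), r_clipped = max(as.numeric(r), 0))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("correlation_report", class(out))
  out
}

#' Write a correlation report as TSV
#' @param report a [correlation_table()] result.
#' @param path TSV path.
#' @return Invisibly, `path`.
#' @export
write_correlation_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
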