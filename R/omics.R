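# TMT normalization, replicate averaging, log-ratio transforms, feature
# correlation, t statistics, IF ROI quantification, network edge filtering.

#' Normalize a TMT reporter-intensity matrix
#'
#' Two-step normalization mirroring the study's workflow: each sample's
#' values are divided by its crude-analysis median protein quantification
#' (loading correction), then every feature is expressed as the ratio to the
#' same run's normalization channel. Features whose normalization-channel
#' value is zero or missing are flagged missing (`NA`) in that run.
#'
#' @param matrix a TMT [new_omics_matrix()]; sample annotations must include
#'   `run` and `is_normalization_channel`.
#' @param crude_medians per-sample crude medians (> 0), in column order;
#'   defaults to the `crude_median` sample annotation.
#' @return The normalized `omics_matrix` (normalization channels become 1).
#'   Attribute `n_flagged` counts feature-run pairs dropped for a bad
#'   normalization value.
#' @export
tmt_normalize <- function(matrix, crude_medians = NULL) {
  assert_that(inherits(matrix, "omics_matrix") && matrix$type == "tmt",
              "`matrix` must be a TMT omics_matrix")
  smp <- matrix$samples
  assert_that(all(c("run", "is_normalization_channel") %in% names(smp)),
              "sample annotations must include run and is_normalization_channel")
  if (is.null(crude_medians)) {
    assert_that("crude_median" %in% names(smp),
                "supply `crude_medians` or a crude_median annotation")
    crude_medians <- smp$crude_median
  }
  assert_that(length(crude_medians) == ncol(matrix$values),
              "one crude median per sample required")
  assert_that(all(crude_medians > 0), "crude medians must be > 0")

  v <- sweep(matrix$values, 2, crude_medians, "/")
  n_flagged <- 0L
  for (r in unique(smp$run)) {
    cols <- which(smp$run == r)
    norm_col <- cols[smp$is_normalization_channel[cols]]
    ref <- v[, norm_col]
    bad <- is.na(ref) | ref <= 0
    n_flagged <- n_flagged + sum(bad)
    ref[bad] <- NA_real_
    v[, cols] <- v[, cols, drop = FALSE] / ref
  }
  out <- new_omics_matrix(v, smp, type = "tmt")
  attr(out, "n_flagged") <- n_flagged
  out
}

#' Collapse technical replicates by geometric mean
#'
#' Replicate measurements of the same physical tumor (grouped by the
#' `tumor_id` annotation) are averaged geometrically, the study's rule for
#' repeated spectrometric measurements. Values must be positive; a zero in a
#' replicate group is an error because its geometric mean is undefined.
#'
#' @param matrix an [new_omics_matrix()] with a `tumor_id` sample
#'   annotation.
#' @return An `omics_matrix` with one column per tumor; `run` annotations
#'   are dropped, other annotations keep their first value per group.
#' @export
geometric_mean_replicates <- function(matrix) {
  assert_that(inherits(matrix, "omics_matrix"), "`matrix` must be an omics_matrix")
  smp <- matrix$samples
  assert_that("tumor_id" %in% names(smp),
              "sample annotations must include tumor_id")
  groups <- split(seq_len(ncol(matrix$values)), smp$tumor_id)
  groups <- groups[unique(smp$tumor_id)]  # keep first-appearance order
  for (g in names(groups)) {
    vals <- matrix$values[, groups[[g]], drop = FALSE]
    if (any(vals <= 0, na.rm = TRUE)) {
      abort_msipk(sprintf(
        "replicate group '%s' contains non-positive values; geometric mean undefined", g),
        "msipk_invalid_argument")
    }
  }
  v <- vapply(groups, function(cols) {
    exp(rowMeans(log(matrix$values[, cols, drop = FALSE]), na.rm = TRUE))
  }, numeric(nrow(matrix$values)))
  keep <- c("condition", "dose", "is_normalization_channel")
  new_smp <- tibble::tibble(sample_id = names(groups))
  for (col in intersect(keep, names(smp))) {
    new_smp[[col]] <- vapply(groups, function(cols) smp[[col]][cols[1]],
                             smp[[col]][1])
  }
  new_smp$tumor_id <- new_smp$sample_id
  new_omics_matrix(v, new_smp, type = matrix$type)
}

#' Log-ratio transform against a reference sample
#'
#' `value' = log((v + pseudocount) / (v_ref + pseudocount))`, base 2 by
#' default (fold-change convention; the log base used in the original
#' analysis is not stated, and the choice is recorded in the output). A
#' pseudocount of 0.001 FPKM and normalization to a designated control tumor
#' follow the study's transcript preprocessing; the reference sample's
#' column becomes all zeros.
#'
#' @param matrix an [new_omics_matrix()].
#' @param reference_sample sample id of the reference column.
#' @param pseudocount added to every value (> 0; default 0.001).
#' @param base logarithm base (default 2).
#' @return The transformed `omics_matrix` (type unchanged is no longer
#'   meaningful, so values may be negative; FPKM non-negativity is not
#'   re-enforced). Attributes `log_base`, `pseudocount`, `reference_sample`
#'   record the transform.
#' @export
log_ratio_transform <- function(matrix, reference_sample,
                                pseudocount = 0.001, base = 2) {
  assert_that(inherits(matrix, "omics_matrix"), "`matrix` must be an omics_matrix")
  assert_that(is_scalar_number(pseudocount) && pseudocount > 0,
              "`pseudocount` must be > 0")
  cols <- colnames(matrix$values)
  if (!reference_sample %in% cols) {
    abort_msipk(sprintf("reference sample '%s' not found", reference_sample),
                "msipk_invalid_argument")
  }
  ref <- matrix$values[, reference_sample] + pseudocount
  v <- log(sweep(matrix$values + pseudocount, 1, ref, "/"), base = base)
  out <- matrix
  out$values <- v
  out$type <- matrix$type
  class(out) <- class(matrix)
  attr(out, "log_base") <- base
  attr(out, "pseudocount") <- pseudocount
  attr(out, "reference_sample") <- reference_sample
  out
}

#' Feature-by-feature Pearson correlation across samples
#'
#' Correlates every feature (phosphopeptide and transcript) with every other
#' across the shared tumor samples, producing the matrix whose row vectors
#' are subsequently clustered. Constant features have undefined correlations
#' and are excluded with a warning.
#'
#' @param phospho an [new_omics_matrix()] (post-normalization).
#' @param transcripts optionally a second `omics_matrix` sharing the sample
#'   set (matched by `sample_id`); pass `NULL` to correlate one matrix with
#'   itself.
#' @return A `correlation_matrix`: `r` (feature x feature Pearson matrix),
#'   `classes` (feature class, `"phospho"` or `"transcript"`), `samples`
#'   (the shared sample ids used).
#' @export
feature_correlation_matrix <- function(phospho, transcripts = NULL) {
  assert_that(inherits(phospho, "omics_matrix"), "`phospho` must be an omics_matrix")
  if (is.null(transcripts)) {
    shared <- colnames(phospho$values)
    combined <- phospho$values
    classes <- rep("phospho", nrow(combined))
  } else {
    assert_that(inherits(transcripts, "omics_matrix"),
                "`transcripts` must be an omics_matrix")
    shared <- intersect(colnames(phospho$values), colnames(transcripts$values))
    assert_that(length(shared) >= 3,
                "matrices must share at least 3 samples")
    combined <- rbind(phospho$values[, shared, drop = FALSE],
                      transcripts$values[, shared, drop = FALSE])
    classes <- c(rep("phospho", nrow(phospho$values)),
                 rep("transcript", nrow(transcripts$values)))
  }
  assert_that(ncol(combined) >= 3, "need at least 3 samples")
  sds <- apply(combined, 1, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning(sprintf("%d constant feature(s) excluded: %s", sum(const),
                    paste(utils::head(rownames(combined)[const], 5),
                          collapse = ", ")), call. = FALSE)
    combined <- combined[!const, , drop = FALSE]
    classes <- classes[!const]
  }
  r <- stats::cor(t(combined))
  structure(list(r = r, classes = classes, samples = shared),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d features (%s) across %d samples\n",
              nrow(x$r),
              paste(sprintf("%d %s", table(x$classes),
                            names(table(x$classes))), collapse = ", "),
              length(x$samples)))
  invisible(x)
}

#' Two-tailed p-value from a t statistic
#'
#' `p = 2 * S(|t|)` with `S` the survival function of the central
#' t-distribution with `df` degrees of freedom — the closed form behind the
#' study's printed t/df/p triplets.
#'
#' @param t t statistic (vectorized).
#' @param df degrees of freedom (>= 1).
#' @return Two-tailed p-value(s) in (0, 1].
#' @export
#' @examples
#' t_pvalue(1.183, 2)   # 0.358
#' t_pvalue(4.213, 4)   # 0.0136
t_pvalue <- function(t, df) {
  assert_that(all(df >= 1), "`df` must be >= 1")
  2 * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Unpaired two-tailed pooled-variance t-test
#'
#' Classic two-sample t with pooled variance and `df = n_a + n_b - 2` (the
#' study's printed df values match this convention: df 4 for 3-vs-3 flank
#' groups, df 2 for 2-vs-2 brain groups). With zero pooled variance the
#' statistic degenerates: equal means give `t = 0, p = 1`; unequal means
#' give an infinite statistic, reported with `p = 0` and `degenerate =
#' TRUE`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`, `degenerate`.
#' @export
unpaired_t_test <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  assert_that(na >= 2 && nb >= 2, "each group needs at least 2 values")
  ma <- mean(group_a); mb <- mean(group_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / df
  if (sp2 == 0) {
    if (ma == mb) {
      tt <- 0; p <- 1; degen <- FALSE
    } else {
      tt <- sign(ma - mb) * Inf; p <- 0; degen <- TRUE
    }
  } else {
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- t_pvalue(tt, df)
    degen <- FALSE
  }
  tibble::tibble(t = tt, df = df, p = p, mean_a = ma, mean_b = mb,
                 n_a = na, n_b = nb, degenerate = degen)
}

#' Quantify marker intensity over a nuclear-channel ROI
#'
#' Automatic stand-in for manual tumor ROIs drawn on nuclear (Hoechst)
#' images: the high-cellularity region is segmented by Otsu thresholding of
#' the nuclear channel, reduced to its largest connected component, and the
#' mean marker intensity inside that ROI is returned. A manual mask can be
#' supplied instead for parity with hand-drawn ROIs.
#'
#' @param nuclear_image numeric matrix (nuclear stain).
#' @param marker_image numeric matrix, same shape (marker stain).
#' @param mask optional [new_roi_mask()] / logical matrix overriding the
#'   automatic segmentation.
#' @return An `if_roi_result`: `mean_intensity`, `roi`
#'   ([new_roi_mask()]), `threshold` (`NA` when a manual mask is used).
#' @export
if_roi_quantify <- function(nuclear_image, marker_image, mask = NULL) {
  assert_that(is.matrix(nuclear_image) && is.matrix(marker_image) &&
                identical(dim(nuclear_image), dim(marker_image)),
              "images must be matrices of the same shape", "msipk_shape_error")
  if (is.null(mask)) {
    rng <- range(nuclear_image, na.rm = TRUE)
    if (diff(rng) == 0) {
      abort_msipk("nuclear image is constant; cannot segment an ROI",
                  "msipk_empty_roi")
    }
    scaled <- (nuclear_image - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(scaled))
    bin <- scaled > thr
    if (!any(bin)) abort_msipk("empty ROI after thresholding", "msipk_empty_roi")
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    lab <- as.matrix(EBImage::imageData(lab))
    sizes <- table(lab[lab > 0])
    keep <- as.integer(names(sizes)[which.max(sizes)])
    roi_px <- lab == keep
    thr_out <- thr * diff(rng) + rng[1]
  } else {
    roi_px <- as_mask_matrix(mask)
    assert_that(identical(dim(roi_px), dim(marker_image)),
                "mask must match the image shape", "msipk_shape_error")
    if (!any(roi_px)) abort_msipk("manual ROI is empty", "msipk_empty_roi")
    thr_out <- NA_real_
  }
  structure(list(
    mean_intensity = mean(marker_image[roi_px], na.rm = TRUE),
    roi = new_roi_mask("tumor", roi_px),
    threshold = thr_out
  ), class = "if_roi_result")
}

#' @export
print.if_roi_result <- function(x, ...) {
  cat(sprintf("<if_roi_result> mean marker intensity %.4g over %d px ROI\n",
              x$mean_intensity, sum(x$roi$pixels)))
  invisible(x)
}

#' Filter a network edge table by confidence and evidence channel
#'
#' Keeps edges with confidence strictly greater than the threshold (the
#' study required a score *over* 0.9) whose evidence channel is not
#' excluded (text mining was excluded there).
#'
#' @param table data frame with columns `node_a`, `node_b`, `confidence`
#'   (in \[0, 1\]) and `channel`.
#' @param threshold strict lower bound on confidence (default 0.9).
#' @param exclude evidence channels to drop (default `"textmining"`).
#' @return The filtered tibble (possibly empty).
#' @export
#' @examples
#' edges <- tibble::tibble(node_a = c("A", "B"), node_b = c("B", "C"),
#'                         confidence = c(0.91, 0.89),
#'                         channel = c("experimental", "experimental"))
#' filter_network_edges(edges)  # keeps only the 0.91 edge
filter_network_edges <- function(table, threshold = 0.9,
                                 exclude = "textmining") {
  assert_that(is.data.frame(table) &&
                all(c("node_a", "node_b", "confidence", "channel") %in%
                      names(table)),
              "`table` needs columns node_a, node_b, confidence, channel")
  assert_that(all(table$confidence >= 0 & table$confidence <= 1),
              "confidence scores must be in [0, 1]")
  assert_that(!any(table$node_a == table$node_b),
              "self-loops are not allowed in the edge table")
  dplyr::filter(tibble::as_tibble(table),
                .data$confidence > threshold,
                !(.data$channel %in% exclude))
}

#' Read / write a network edge table (TSV)
#'
#' TSV columns `node_a`, `node_b`, `score`, `channel`; `score` maps to the
#' in-memory `confidence` column.
#'
#' @param path TSV path.
#' @param table tibble as in [filter_network_edges()].
#' @return `read_network_tsv`: a tibble; `write_network_tsv`: invisibly
#'   `path`.
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(all(c("node_a", "node_b", "score", "channel") %in% names(df)),
              "TSV must have columns node_a, node_b, score, channel",
              "msipk_format_error")
  tibble::tibble(node_a = df$node_a, node_b = df$node_b,
                 confidence = df$score, channel = df$channel)
}

#' @rdname read_network_tsv
#' @export
write_network_tsv <- function(table, path) {
  utils::write.table(
    data.frame(node_a = table$node_a, node_b = table$node_b,
               score = table$confidence, channel = table$channel),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
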