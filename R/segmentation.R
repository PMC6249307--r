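# Spectral vectorization and bisecting k-means tissue segmentation.

# Vectorize tissue pixels onto a fixed-width m/z bin axis (only occupied bins
# are materialized) and L2-normalize each pixel so clustering is
# intensity-scale-free. Intensities are shared linearly between the two
# nearest bin centers, so a centroid jittering across a bin boundary moves
# weight smoothly instead of flipping bins.
bin_spectra <- function(dataset, bin_width = 0.005, normalize = TRUE) {
  rng <- dataset$metadata$mz_range %||%
    range(unlist(lapply(dataset$spectra, `[[`, "mz")))
  n_px <- length(dataset$spectra)

  per_px <- lapply(dataset$spectra, function(s) {
    t <- (s$mz - rng[1]) / bin_width - 0.5
    k0 <- floor(t)
    frac <- t - k0
    b <- c(k0 + 1L, k0 + 2L)
    w <- c(s$intensity * (1 - frac), s$intensity * frac)
    keep <- b >= 1 & w > 0
    tapply(w[keep], b[keep], sum)
  })
  bins <- sort(unique(unlist(lapply(per_px, function(v) as.integer(names(v))))))
  X <- matrix(0, n_px, length(bins),
              dimnames = list(NULL, sprintf("mz_%.4f",
                                            rng[1] + (bins - 0.5) * bin_width)))
  bin_pos <- match(seq_len(max(bins)), bins)
  for (i in seq_len(n_px)) {
    v <- per_px[[i]]
    X[i, bin_pos[as.integer(names(v))]] <- v
  }
  if (normalize) {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    X <- X / nrm
  }
  attr(X, "bin_centers") <- rng[1] + (bins - 0.5) * bin_width
  X
}

#' Bisecting k-means segmentation of an MSI dataset
#'
#' Clusters tissue pixels by their binned, L2-normalized spectra using
#' divisive bisecting k-means: starting from one cluster, the cluster with
#' the largest within-cluster sum of squares is repeatedly split by 2-means
#' (10 seeded restarts) until `k` clusters remain — the approach the study
#' used to define tumor ROIs from MSI data. The tumor cluster is identified
#' as the one with the highest mean intensity in the biomarker channel
#' (m/z 503.949 by default).
#'
#' @param dataset an [msi_dataset][new_msi_dataset].
#' @param k number of clusters (>= 2, <= number of tissue pixels).
#' @param seed integer seed for the 2-means restarts.
#' @param bin_width spectral bin width, Da.
#' @param biomarker_mz,biomarker_tol m/z window identifying the tumor
#'   cluster.
#' @param nstart restarts per 2-means split.
#' @return A `segmentation_result`: `labels` (integer matrix, `NA` off
#'   tissue), `masks` (list of [new_roi_mask()]; the tumor cluster is
#'   labeled `"tumor"`, the rest `"cluster_<i>"`), `tumor_cluster`,
#'   `wss_trace` (total within-cluster SSE after each bisection) and
#'   `biomarker_means` per cluster.
#' @export
segment_bisecting_kmeans <- function(dataset, k = 2, seed = 1L,
                                     bin_width = 0.005,
                                     biomarker_mz = 503.949,
                                     biomarker_tol = 0.001,
                                     nstart = 10) {
  assert_that(inherits(dataset, "msi_dataset"), "`dataset` must be an msi_dataset")
  assert_that(is_scalar_number(k) && k >= 2 && k == round(k),
              "`k` must be an integer >= 2")
  n_px <- length(dataset$spectra)
  assert_that(k <= n_px,
              sprintf("k = %d exceeds the %d tissue pixels", k, n_px))

  X <- bin_spectra(dataset, bin_width = bin_width)
  labels <- rep(1L, n_px)
  wss_of <- function(idx) {
    if (length(idx) < 2) return(0)
    sub <- X[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  wss_trace <- numeric(0)

  with_seed(seed, {
    next_label <- 2L
    while (max(labels) < k) {
      per <- vapply(split(seq_len(n_px), labels), wss_of, numeric(1))
      for (cand in names(sort(per, decreasing = TRUE))) {
        idx <- which(labels == as.integer(cand))
        sub <- X[idx, , drop = FALSE]
        if (length(idx) < 2 || nrow(unique(sub)) < 2) next
        km <- suppressWarnings(stats::kmeans(sub, centers = 2,
                                             nstart = nstart))
        labels[idx[km$cluster == 2]] <- next_label
        next_label <- next_label + 1L
        break
      }
      total <- sum(vapply(split(seq_len(n_px), labels), wss_of, numeric(1)))
      wss_trace <- c(wss_trace, total)
      if (length(unique(labels)) == max(labels) &&
          max(labels) < k && all(per == 0)) break
    }
  })

  lab_img <- matrix(NA_integer_, dataset$grid_shape[1], dataset$grid_shape[2])
  lab_img[dataset$coords] <- labels

  bio <- extract_ion_image(dataset, biomarker_mz, biomarker_tol)
  bio_px <- bio$values[dataset$coords]
  means <- tapply(bio_px, labels, mean, na.rm = TRUE)
  tumor_cluster <- as.integer(names(means)[which.max(means)])

  masks <- list()
  for (cl in sort(unique(labels))) {
    nm <- if (cl == tumor_cluster) "tumor" else sprintf("cluster_%d", cl)
    masks[[nm]] <- new_roi_mask(nm, !is.na(lab_img) & lab_img == cl)
  }

  structure(list(
    labels = lab_img,
    masks = masks,
    tumor_cluster = tumor_cluster,
    wss_trace = wss_trace,
    biomarker_means = tibble::tibble(cluster = as.integer(names(means)),
                                     biomarker_mean = as.numeric(means))
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  k <- length(x$masks)
  cat(sprintf("<segmentation_result> %d clusters; tumor = cluster %d\n",
              k, x$tumor_cluster))
  for (nm in names(x$masks)) {
    cat(sprintf("  %s: %d px\n", nm, sum(x$masks[[nm]]$pixels)))
  }
  invisible(x)
}
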