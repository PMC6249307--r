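# Shared fixtures, built once per test run. Small grids keep the suite fast;
# objects are memoized in the helper environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_phantom <- function() {
  fixture("small_phantom", function() {
    generate_msi_phantom(phantom_config(grid_shape = c(40, 40),
                                        n_sections = 2, noise_cv = 0,
                                        seed = 11L))
  })
}

noisy_phantom <- function() {
  fixture("noisy_phantom", function() {
    generate_msi_phantom(phantom_config(grid_shape = c(48, 48),
                                        n_sections = 2, noise_cv = 0.15,
                                        seed = 7L))
  })
}

# hand-built 2x2 dataset with known peak lists
tiny_dataset <- function() {
  spectra <- list(
    list(mz = c(394.1755, 394.1762, 616.1770), intensity = c(40, 60, 10)),
    list(mz = c(394.1760, 503.9490), intensity = c(100, 5)),
    list(mz = c(380.1600, 550.3000), intensity = c(20, 30)),
    list(mz = c(394.1800, 616.1771), intensity = c(7, 3))
  )
  coords <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  new_msi_dataset(spectra, coords, grid_shape = c(2, 2), pixel_size = 100,
                  z_spacing = 160, section_index = 1L,
                  metadata = list(polarity = "positive",
                                  mz_range = c(380, 620)))
}

# masks of identical shape for ROI tests
square_mask <- function(n, r1, r2, c1, c2, label = "roi") {
  m <- matrix(FALSE, n, n)
  m[r1:r2, c1:c2] <- TRUE
  new_roi_mask(label, m)
}

# exhaustive agglomerative clustering oracle (UPGMA / WPGMA) over a small
# distance matrix; independent of stats::hclust
agglomerate_oracle <- function(D, linkage = c("average", "mcquitty")) {
  linkage <- match.arg(linkage)
  n <- nrow(D)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d <- D
  heights <- numeric(0)
  while (length(active) > 1) {
    m <- length(active)
    best <- c(1, 2); bd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (d[i, j] < bd) { bd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bd)
    newd <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      newd[k] <- if (linkage == "average") {
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
      } else {
        (d[i, k] + d[j, k]) / 2
      }
    }
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- matrix(0, m - 1, m - 1)
    if (length(keep)) {
      d2[seq_along(keep), seq_along(keep)] <- d[keep, keep]
      d2[length(keep) + 1, seq_along(keep)] <- newd[keep]
      d2[seq_along(keep), length(keep) + 1] <- newd[keep]
    }
    d <- d2
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
  }
  sort(heights)
}

# adjusted Rand index (chance-corrected partition agreement)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# mean silhouette width of a labeling on a distance matrix
silhouette_mean <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
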