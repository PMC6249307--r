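# Calibration fitting/inversion, segmentation, core/edge split, ROI stats.

test_that("calibration fit recovers an exact line and accepts the 7-level grid", {
  series <- calibration_series(mimetic_levels(), 2 * mimetic_levels() + 5)
  expect_silent(m <- fit_calibration(series))
  expect_equal(m$slope, 2, tolerance = 1e-9)
  expect_equal(m$intercept, 5, tolerance = 1e-6)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_equal(m$valid_range, c(500, 50000))
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "slope"], 2, tolerance = 1e-9)
  expect_equal(glance(m)$n, 7)
})

test_that("noisy generator series refits slope within 5% of truth", {
  m <- fit_calibration(generate_calibration_series(slope = 2, intercept = 0,
                                                   noise_cv = 0.05, seed = 1L))
  expect_lt(abs(m$slope - 2) / 2, 0.05)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(calibration_series(c(1, 1, 2), c(1, 2, 3)))
  expect_error(fit_calibration(calibration_series(c(1, 2, 3), c(1, 2, 3))[1:2, ]))
  same_x <- data.frame(nominal_conc = c(5, 5, 5), mean_intensity = 1:3)
  expect_error(fit_calibration(same_x), class = "msipk_fit_error")
})

test_that("calibration inversion is exact and clips negatives with a count", {
  m <- fit_calibration(calibration_series(mimetic_levels(),
                                          2 * mimetic_levels() + 5))
  img <- new_ion_image(matrix(c(2 * 500 + 5, 5, 1, NA), 2, 2),
                       394.176, 0.001, 100)
  map <- apply_calibration(img, m)
  expect_equal(map$values[1, 1], 500, tolerance = 1e-9)
  expect_equal(map$values[2, 1], 0)          # intensity == intercept
  expect_equal(map$values[1, 2], 0)          # negative back-calc clipped
  expect_equal(map$n_clipped, 1)
  expect_true(is.na(map$values[2, 2]))
  bad <- m; bad$slope <- -1
  expect_error(apply_calibration(img, bad), class = "msipk_fit_error")
})

test_that("calibration round trip recovers the phantom truth at zero noise", {
  ph <- small_phantom()
  cfg <- ph$truth$config
  m <- fit_calibration(generate_calibration_series(
    slope = cfg$cal_slope, intercept = cfg$cal_intercept, noise_cv = 0))
  map <- apply_calibration(extract_ion_image(ph$dataset[[1]], 394.176), m)
  tis <- ph$truth$tissue_mask[[1]]
  expect_lt(max(abs(map$values[tis] - ph$truth$true_concentration[[1]][tis])),
            1e-6)
})

test_that("bisecting k-means separates two synthetic spectral populations perfectly", {
  # two blocks of pixels with disjoint peaks
  spectra <- c(
    replicate(20, list(mz = c(400.0, 500.0), intensity = c(100, 5) *
                         stats::runif(1, 0.8, 1.2)), simplify = FALSE),
    replicate(20, list(mz = c(450.0, 503.949), intensity = c(90, 80) *
                         stats::runif(1, 0.8, 1.2)), simplify = FALSE)
  )
  coords <- cbind(rep(1:8, 5), rep(1:5, each = 8))
  ds <- new_msi_dataset(spectra, coords, c(8, 5), 100,
                        metadata = list(mz_range = c(380, 620)))
  seg <- segment_bisecting_kmeans(ds, k = 2, seed = 1)
  truth <- rep(1:2, each = 20)
  labs <- seg$labels[coords]
  expect_equal(ari(labs, truth), 1)
  expect_equal(seg$tumor_cluster, labs[21])  # biomarker population
})

test_that("phantom segmentation recovers the tumor mask with ARI >= 0.9", {
  ph <- noisy_phantom()
  ds <- ph$dataset[[1]]
  seg <- segment_bisecting_kmeans(ds, k = 2, seed = 1)
  truth <- ph$truth$tumor_mask[[1]][ds$coords]
  est <- seg$masks$tumor$pixels[ds$coords]
  expect_gte(ari(est, truth), 0.9)
  # the tumor cluster has the higher biomarker mean by construction
  bm <- seg$biomarker_means
  expect_equal(bm$cluster[which.max(bm$biomarker_mean)], seg$tumor_cluster)
})

test_that("bisecting k-means WSS is non-increasing in k and labels partition", {
  ph <- noisy_phantom()
  ds <- ph$dataset[[1]]
  seg <- segment_bisecting_kmeans(ds, k = 4, seed = 2)
  expect_true(all(diff(seg$wss_trace) <= 1e-8))
  labs <- seg$labels[ds$coords]
  expect_false(anyNA(labs))
  expect_equal(sum(lengths(lapply(seg$masks, function(m) which(m$pixels)))),
               length(ds$spectra))
  expect_error(segment_bisecting_kmeans(ds, k = length(ds$spectra) + 1))
})

test_that("core/edge split matches the erosion oracle and partitions the tumor", {
  tumor <- square_mask(13, 3, 11, 3, 11, "tumor")  # 9 x 9 square
  ce <- split_core_edge(tumor, depth_px = 2)
  expect_equal(sum(ce$core$pixels), 25)  # 5 x 5
  expect_equal(sum(ce$edge$pixels), 81 - 25)
  expect_identical(ce$core$pixels | ce$edge$pixels, tumor$pixels)
  expect_false(any(ce$core$pixels & ce$edge$pixels))
  expect_error(split_core_edge(tumor, depth_px = 5), class = "msipk_empty_roi")
  # partition holds for every feasible depth
  for (d in 1:3) {
    ce_d <- split_core_edge(tumor, depth_px = d)
    expect_identical(ce_d$core$pixels | ce_d$edge$pixels, tumor$pixels)
  }
})

test_that("noisy phantom core/edge concentration ratio stays near the planted 2x", {
  ph <- noisy_phantom()
  cfg <- ph$truth$config
  m <- fit_calibration(generate_calibration_series(
    slope = cfg$cal_slope, intercept = cfg$cal_intercept, noise_cv = 0))
  map <- apply_calibration(extract_ion_image(ph$dataset[[1]], 394.176), m)
  ce <- split_core_edge(new_roi_mask("tumor", ph$truth$tumor_mask[[1]]),
                        depth_px = cfg$core_depth_px)
  ratio <- roi_statistics(map, ce$core)$mean / roi_statistics(map, ce$edge)$mean
  expect_equal(ratio, 2.0, tolerance = 0.15 / 2)
})

test_that("ROI statistics equal a brute-force loop and handle fixtures", {
  uniform <- matrix(2787.1, 10, 10)
  mask <- square_mask(10, 2, 6, 3, 8, "core")
  st <- roi_statistics(uniform, mask)
  expect_equal(st$mean, 2787.1)
  expect_equal(st$sd, 0)
  one_px <- square_mask(10, 4, 4, 4, 4, "px")
  st1 <- roi_statistics(uniform, one_px)
  expect_equal(st1$n_pixels, 1)
  expect_equal(st1$sd, 0)
  set.seed(42)
  rnd <- matrix(rexp(100), 10, 10)
  rnd[1, 1] <- NA
  big <- square_mask(10, 1, 9, 1, 9, "tumor")
  st2 <- roi_statistics(rnd, big)
  vals <- c()
  for (r in 1:9) for (c in 1:9) {
    if (!is.na(rnd[r, c])) vals <- c(vals, rnd[r, c])
  }
  expect_equal(st2$mean, mean(vals))
  expect_equal(st2$median, median(vals))
  expect_equal(st2$iqr, IQR(vals))
  expect_equal(st2$n_pixels, length(vals))
  empty_overlap <- matrix(NA_real_, 10, 10)
  expect_error(roi_statistics(empty_overlap, big), class = "msipk_empty_roi")
})

test_that("tissue-to-plasma ratio is plain division with a guarded domain", {
  expect_equal(tissue_to_plasma_ratio(54, 100), 0.54)
  expect_equal(tissue_to_plasma_ratio(7, 7), 1)
  expect_equal(tissue_to_plasma_ratio(0, 100), 0)
  expect_error(tissue_to_plasma_ratio(5, 0))
})

test_that("relative quadrant intensity reproduces the percent-of-max pattern", {
  st <- tibble::tibble(label = c("R1", "L1", "R2", "L2"),
                       mean = c(10, 7.5, 6.45, 6.109))
  out <- relative_quadrant_intensity(st)
  expect_equal(out$relative_pct, c(100, 75, 64.5, 61.09))
  eq <- relative_quadrant_intensity(tibble::tibble(label = c("a", "b"),
                                                   mean = c(3, 3)))
  expect_equal(eq$relative_pct, c(100, 100))
  single <- relative_quadrant_intensity(tibble::tibble(label = "a", mean = 5))
  expect_equal(single$relative_pct, 100)
  expect_error(relative_quadrant_intensity(tibble::tibble(label = "a", mean = 0)))
})

test_that("quadrant masks partition the ROI by centroid and brain side", {
  mask <- square_mask(12, 3, 10, 3, 10, "tumor")
  q <- quadrant_masks(mask)
  expect_setequal(names(q), c("quadrant_R1", "quadrant_R2",
                              "quadrant_L1", "quadrant_L2"))
  total <- Reduce(`|`, lapply(q, function(m) m$pixels))
  expect_identical(total, mask$pixels)
  expect_equal(sum(vapply(q, function(m) sum(m$pixels), numeric(1))),
               sum(mask$pixels))
})
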