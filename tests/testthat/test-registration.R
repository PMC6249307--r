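# t-SNE color embedding and affine + B-spline registration on phantoms with
# analytically known deformations.

# resample an image through a point map (independent bilinear oracle)
resample_through <- function(img, map_fun, shape = dim(img)) {
  grid <- cbind(rep(seq_len(shape[1]), shape[2]),
                rep(seq_len(shape[2]), each = shape[1]))
  src <- map_fun(grid)
  vals <- vapply(seq_len(nrow(src)), function(i) {
    r <- src[i, 1]; c <- src[i, 2]
    r0 <- floor(r); c0 <- floor(c)
    if (r0 < 1 || c0 < 1 || r0 + 1 > nrow(img) || c0 + 1 > ncol(img)) return(0)
    fr <- r - r0; fc <- c - c0
    img[r0, c0] * (1 - fr) * (1 - fc) + img[r0 + 1, c0] * fr * (1 - fc) +
      img[r0, c0 + 1] * (1 - fr) * fc + img[r0 + 1, c0 + 1] * fr * fc
  }, numeric(1))
  matrix(vals, shape[1], shape[2])
}

boundary_of <- function(m) {
  n <- nrow(m); p <- ncol(m)
  inner <- m
  inner[2:(n - 1), 2:(p - 1)] <- m[2:(n - 1), 2:(p - 1)] &
    m[1:(n - 2), 2:(p - 1)] & m[3:n, 2:(p - 1)] &
    m[2:(n - 1), 1:(p - 2)] & m[2:(n - 1), 3:p]
  m & !inner
}

landmark_points <- function(truth, k = 1) {
  which(boundary_of(truth$tissue_mask[[k]]) |
          boundary_of(truth$tumor_mask[[k]]) |
          boundary_of(truth$ventricle_mask[[k]]) |
          truth$vessel_mask[[k]], arr.ind = TRUE)
}

test_that("identical spectra embed to a constant color image with a warning", {
  spectra <- replicate(9, list(mz = c(400, 500), intensity = c(10, 5)),
                       simplify = FALSE)
  coords <- cbind(rep(1:3, 3), rep(1:3, each = 3))
  ds <- new_msi_dataset(spectra, coords, c(3, 3), 100,
                        metadata = list(mz_range = c(380, 620)))
  expect_warning(emb <- embed_tsne_lab(ds), "identical")
  for (ch in 1:3) {
    vals <- emb$rgb_image[, , ch]
    expect_equal(length(unique(vals[!is.na(vals)])), 1)
  }
})

test_that("two spectral populations separate in the embedding", {
  set.seed(3)
  spectra <- c(
    replicate(30, list(mz = c(400, 500), intensity = c(100, 10) *
                         runif(1, 0.9, 1.1)), simplify = FALSE),
    replicate(30, list(mz = c(450, 550), intensity = c(80, 60) *
                         runif(1, 0.9, 1.1)), simplify = FALSE)
  )
  coords <- cbind(rep(1:10, 6), rep(1:6, each = 10))
  ds <- new_msi_dataset(spectra, coords, c(10, 6), 100,
                        metadata = list(mz_range = c(380, 620)))
  emb <- embed_tsne_lab(ds, perplexity = 10, iterations = 300, seed = 1)
  labels <- rep(1:2, each = 30)
  expect_gt(silhouette_mean(dist(emb$embedding), labels), 0.5)
  # the same separation shows as distinct colors (Lab distance)
  D <- as.matrix(dist(emb$lab))
  intra <- mean(D[1:30, 1:30])
  inter <- mean(D[1:30, 31:60])
  expect_gt(inter, intra)
  # determinism for a fixed seed
  emb2 <- embed_tsne_lab(ds, perplexity = 10, iterations = 300, seed = 1)
  expect_identical(emb$embedding, emb2$embedding)
})

test_that("tumor pixels form a distinct color region in the phantom embedding", {
  ph <- noisy_phantom()
  ds <- ph$dataset[[1]]
  # subsample pixels for speed: embed a strided subset as its own dataset
  keep <- seq(1, length(ds$spectra), by = 4)
  sub <- new_msi_dataset(ds$spectra[keep], ds$coords[keep, ], ds$grid_shape,
                         ds$pixel_size, ds$z_spacing, ds$section_index,
                         ds$metadata)
  emb <- embed_tsne_lab(sub, perplexity = 20, iterations = 300, seed = 1)
  truth <- ph$truth$tumor_mask[[1]][sub$coords]
  D <- as.matrix(dist(emb$lab))
  intra <- mean(D[truth, truth])
  inter <- mean(D[truth, !truth])
  expect_gt(inter, intra)
})

test_that("affine registration of an image with itself recovers the identity", {
  ph <- noisy_phantom()
  img <- extract_ion_image(ph$dataset[[1]], 394.176)
  est <- register_affine(img, img, metric = "mse")
  expect_lt(max(abs(est$translation)), 0.1)
  ang <- atan2(est$matrix[2, 1], est$matrix[1, 1]) * 180 / pi
  expect_lt(abs(ang), 0.1)
  expect_lt(abs(det(est$matrix) - 1), 0.01)
})

test_that("a known 10-degree / 1.1-scale / (5,-3) px displacement is recovered under 1 px TRE", {
  cfg <- phantom_config(grid_shape = c(64, 64), n_sections = 1,
                        noise_cv = 0.15, seed = 2L)
  ph <- generate_msi_phantom(cfg)
  mri <- generate_mri_phantom(ph$truth, cfg, rotation_deg = 10, scale = 1.1,
                              translation = c(5, -3))
  mov <- extract_ion_image(ph$dataset[[1]], 394.176)
  movm <- mov$values; movm[is.na(movm)] <- 0
  fixed <- resample_through(movm, mri$deformation$map)
  pts <- which(ph$truth$tissue_mask[[1]], arr.ind = TRUE)
  pts <- pts[seq(1, nrow(pts), by = 13), , drop = FALSE]
  for (met in c("mse", "mattes")) {
    est <- register_affine(mov, fixed, metric = met)
    expect_lt(target_registration_error(est, mri$deformation$map, pts), 1)
    expect_true(length(attr(est, "optimizer_trace")) >= 1)
  }
})

test_that("cross-modality MR alignment approaches the known pose", {
  cfg <- phantom_config(grid_shape = c(64, 64), n_sections = 1,
                        noise_cv = 0.15, seed = 2L)
  ph <- generate_msi_phantom(cfg)
  mri <- generate_mri_phantom(ph$truth, cfg)
  mov <- extract_ion_image(ph$dataset[[1]], 394.176)
  est <- register_affine(mov, mri$volume[, , 1], metric = "mattes")
  pts <- which(ph$truth$tissue_mask[[1]], arr.ind = TRUE)
  pts <- pts[seq(1, nrow(pts), by = 13), , drop = FALSE]
  # drug distribution and MR anatomy are different contrasts, so alignment
  # carries a content bias; it must still land within ~2 px of the pose
  expect_lt(target_registration_error(est, mri$deformation$map, pts), 2)
})

test_that("grossly mismatched images fail with a registration error", {
  a <- matrix(0, 32, 32); a[4:8, 4:8] <- 1
  set.seed(9)
  b <- matrix(runif(32 * 32), 32, 32)
  expect_error(register_affine(a, b, metric = "mse"),
               class = "msipk_registration_error")
})

test_that("B-spline refinement stays near zero when the truth is purely affine", {
  cfg <- phantom_config(grid_shape = c(48, 48), n_sections = 1,
                        noise_cv = 0.15, seed = 4L)
  ph <- generate_msi_phantom(cfg)
  mri <- generate_mri_phantom(ph$truth, cfg)
  mov <- extract_ion_image(ph$dataset[[1]], 394.176)
  movm <- mov$values; movm[is.na(movm)] <- 0
  fixed <- resample_through(movm, mri$deformation$map)
  aff <- register_affine(mov, fixed, metric = "mse")
  bsp <- register_bspline(mov, fixed, aff)
  expect_lt(max(abs(c(bsp$disp_r, bsp$disp_c))), 0.5)
  pts <- which(ph$truth$tissue_mask[[1]], arr.ind = TRUE)
  pts <- pts[seq(1, nrow(pts), by = 13), , drop = FALSE]
  tre_aff <- target_registration_error(aff, mri$deformation$map, pts)
  tre_chain <- target_registration_error(transform_chain(aff, bsp),
                                         mri$deformation$map, pts)
  expect_lte(tre_chain, tre_aff + 1e-9)  # refinement does not degrade
  expect_lt(tre_aff, 1)
})

test_that("a 3 px sinusoidal warp is recovered below 2 px TRE with a decreasing loss", {
  cfg <- phantom_config(grid_shape = c(64, 64), n_sections = 1,
                        noise_cv = 0.15, seed = 2L)
  ph <- generate_msi_phantom(cfg)
  mri <- generate_mri_phantom(ph$truth, cfg, warp_amplitude = 3)
  mov <- extract_ion_image(ph$dataset[[1]], 394.176)
  movm <- mov$values; movm[is.na(movm)] <- 0
  fixed <- resample_through(movm, mri$deformation$map)
  bsp <- register_bspline(mov, fixed, mri$deformation$affine)
  chain <- transform_chain(mri$deformation$affine, bsp)
  landmarks <- landmark_points(ph$truth)
  expect_lt(target_registration_error(chain, mri$deformation$map, landmarks), 2)
  # within the final optimization level the loss decreases
  trace <- attr(bsp, "optimizer_trace")
  fin <- trace[[length(trace)]]
  expect_lt(fin[length(fin)], fin[1])
})

test_that("apply_transform warps scalars bilinearly and masks nearest-neighbor", {
  img <- new_ion_image(matrix(runif(400), 20, 20), 394.176, 0.001, 100)
  ident <- transform_chain(affine_transform())
  out <- apply_transform(ident, img)
  expect_equal(out$values, img$values)
  # binary disk rotated 90 degrees about the center keeps its pixel count
  disk <- matrix(FALSE, 21, 21)
  for (r in 1:21) for (c in 1:21) {
    if ((r - 11)^2 + (c - 11)^2 <= 36) disk[r, c] <- TRUE
  }
  rot <- make_affine(rotation_deg = 90, center = c(11, 11))
  warped <- apply_transform(rot, new_roi_mask("disk", disk))
  expect_true(is.logical(warped$pixels))
  expect_lt(abs(sum(warped$pixels) - sum(disk)) / sum(disk), 0.02)
  # missing pixels propagate
  img$values[5, 5] <- NA
  out2 <- apply_transform(ident, img)
  expect_true(is.na(out2$values[5, 5]))
})

test_that("registered drug distribution recovers the planted MR enhancing overlap", {
  cfg <- phantom_config(grid_shape = c(48, 48), n_sections = 1,
                        noise_cv = 0.15, seed = 6L)
  ph <- generate_msi_phantom(cfg)
  mri <- generate_mri_phantom(ph$truth, cfg, enhancing_erosion_px = 1)
  mov <- extract_ion_image(ph$dataset[[1]], 394.176)
  movm <- mov$values; movm[is.na(movm)] <- 0
  fixed <- resample_through(movm, mri$deformation$map)
  aff <- register_affine(mov, fixed, metric = "mse")
  # bring the MR-frame enhancing mask back into the MSI frame through the
  # estimated transform and compare with the high-drug (tumor) region
  enh_back <- apply_transform(invert_affine(aff),
                              new_roi_mask("enh", mri$enhancing_mr[[1]]))
  est_dice <- dice_coefficient(ph$truth$tumor_mask[[1]], enh_back)
  truth_dice <- dice_coefficient(ph$truth$tumor_mask[[1]],
                                 mri$enhancing_msi[[1]])
  expect_gt(truth_dice, 0.7)    # planted: enhancing smaller than tumor
  expect_gt(est_dice, 0.7)      # recovered through the estimated transform
  expect_lt(abs(est_dice - truth_dice), 0.1)
})

test_that("transform serialization writes valid JSON with full precision", {
  tmp <- withr::local_tempdir()
  aff <- make_affine(rotation_deg = 10, scale = 1.1, translation = c(5, -3),
                     center = c(16.5, 16.5))
  bsp <- bspline_transform(8, matrix(0.25, 7, 7), matrix(-0.5, 7, 7),
                           c(30, 30))
  path <- file.path(tmp, "chain.json")
  write_transform_json(transform_chain(aff, bsp), path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$type, "chain")
  expect_equal(matrix(unlist(parsed$affine$matrix), 2, 2), aff$matrix,
               tolerance = 1e-12)
  expect_equal(parsed$bspline$spacing, 8)
})
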