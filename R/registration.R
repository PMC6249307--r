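# t-SNE color embedding and multimodal affine + B-spline registration.

#' Project an MSI dataset into a t-SNE Lab color image
#'
#' Embeds each tissue pixel's binned spectrum into 3D with t-SNE and feeds
#' the three embedding axes into the L*, a*, b* channels of a perceptual
#' color space (min-max scaled into each channel's working range). Similar
#' spectra receive similar colors, so molecularly distinct structures appear
#' as distinct color regions — the image that guides registration against
#' anatomy-rich MR or histology frames.
#'
#' @param dataset an [msi_dataset][new_msi_dataset].
#' @param perplexity,iterations,seed t-SNE parameters (see [tsne_embed()]).
#' @param bin_width spectral bin width, Da.
#' @return A `color_embedding`: `embedding` (n x 3 t-SNE coordinates),
#'   `lab` (n x 3 Lab channel values), `rgb_image` (rows x cols x 3 sRGB
#'   array, `NA` off tissue), `intensity` (luminance matrix used as the
#'   registration scalar), `coords`, `grid_shape` and the per-axis scaling.
#' @export
embed_tsne_lab <- function(dataset, perplexity = 30, iterations = 500,
                           seed = 1L, bin_width = 0.005) {
  assert_that(inherits(dataset, "msi_dataset"), "`dataset` must be an msi_dataset")
  n_px <- length(dataset$spectra)
  assert_that(n_px >= 2, "need at least 2 tissue pixels")
  X <- bin_spectra(dataset, bin_width = bin_width)

  ranges <- list(L = c(10, 90), a = c(-60, 60), b = c(-60, 60))
  if (nrow(unique(X)) < 2) {
    warning("all spectra identical; returning a constant color image",
            call. = FALSE)
    Y <- matrix(0, n_px, 3)
    lab <- cbind(rep(50, n_px), 0, 0)
  } else {
    Y <- tsne_embed(X, dims = 3, perplexity = perplexity,
                    max_iter = iterations, seed = seed)
    lab <- vapply(1:3, function(j) {
      rng <- range(Y[, j])
      span <- diff(rng)
      tgt <- ranges[[j]]
      if (span == 0) rep(mean(tgt), n_px)
      else tgt[1] + (Y[, j] - rng[1]) / span * diff(tgt)
    }, numeric(n_px))
  }

  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  rgb <- pmin(pmax(rgb, 0), 1)
  img <- array(NA_real_, c(dataset$grid_shape, 3))
  for (ch in 1:3) {
    m <- matrix(NA_real_, dataset$grid_shape[1], dataset$grid_shape[2])
    m[dataset$coords] <- rgb[, ch]
    img[, , ch] <- m
  }
  lum <- matrix(NA_real_, dataset$grid_shape[1], dataset$grid_shape[2])
  lum[dataset$coords] <- lab[, 1]

  structure(list(
    embedding = Y, lab = lab, rgb_image = img, intensity = lum,
    coords = dataset$coords, grid_shape = dataset$grid_shape,
    scaling = ranges, perplexity = perplexity, iterations = iterations,
    seed = seed
  ), class = "color_embedding")
}

#' @export
print.color_embedding <- function(x, ...) {
  cat(sprintf("<color_embedding> %d pixels embedded in 3D (perplexity %.1f, %d iterations)\n",
              nrow(x$embedding), x$perplexity, x$iterations))
  invisible(x)
}

# Coerce registration inputs to a plain intensity matrix (NA -> 0).
as_reg_image <- function(x) {
  m <- if (inherits(x, "color_embedding")) x$intensity
  else if (inherits(x, c("ion_image", "concentration_map"))) x$values
  else if (is.matrix(x)) x
  else abort_msipk("unsupported image type for registration",
                   "msipk_invalid_argument")
  m[is.na(m)] <- 0
  m
}

downsample2 <- function(img) {
  n <- floor(nrow(img) / 2) * 2
  p <- floor(ncol(img) / 2) * 2
  img <- img[seq_len(n), seq_len(p), drop = FALSE]
  (img[seq(1, n, 2), seq(1, p, 2)] + img[seq(2, n, 2), seq(1, p, 2)] +
     img[seq(1, n, 2), seq(2, p, 2)] + img[seq(2, n, 2), seq(2, p, 2)]) / 4
}

warp_matrix <- function(moving, points, shape) {
  matrix(bilinear_sample(moving, points[, 1], points[, 2], fill = NA_real_),
         shape[1], shape[2])
}

zscore <- function(m) {
  mu <- mean(m); s <- stats::sd(m)
  if (s == 0) m - mu else (m - mu) / s
}

# Mattes-style mutual information with a partial-volume (soft-binned) joint
# histogram: each sample spreads bilinear weight over the 2 x 2 neighboring
# bins, which smooths the similarity landscape for the optimizer.
mutual_information <- function(a, b, bins = 32) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 10) return(0)
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  u <- norm01(a) * (bins - 1) + 1
  v <- norm01(b) * (bins - 1) + 1
  i0 <- pmin(floor(u), bins - 1); fu <- u - i0
  j0 <- pmin(floor(v), bins - 1); fv <- v - j0
  lin <- c(i0 + (j0 - 1) * bins, i0 + 1 + (j0 - 1) * bins,
           i0 + j0 * bins, i0 + 1 + j0 * bins)
  w <- c((1 - fu) * (1 - fv), fu * (1 - fv), (1 - fu) * fv, fu * fv)
  s <- rowsum(w, lin)
  H <- matrix(0, bins, bins)
  H[as.integer(rownames(s))] <- s
  H <- H / sum(H)
  px <- rowSums(H); py <- colSums(H)
  nz <- H > 0
  sum(H[nz] * log(H[nz] / outer(px, py)[nz]))
}

# Similarity over the overlap region only; transforms that push most of the
# fixed frame outside the moving image are rejected outright so the
# optimizer cannot cheat by shrinking the overlap.
similarity_value <- function(warped, fixed, metric, min_overlap = 0.25) {
  ok <- !is.na(warped)
  frac <- mean(ok)
  if (frac < min_overlap || sum(ok) < 10) return(1e6 * (1 + min_overlap - frac))
  if (metric == "mse") {
    mean((warped[ok] - fixed[ok])^2)
  } else {
    -mutual_information(warped, fixed)
  }
}

params_to_affine <- function(p, center) {
  make_affine(rotation_deg = p[1], scale = exp(p[2:3]), shear = p[4],
              translation = p[5:6], center = center)
}

#' Affine registration of a moving image to a fixed image
#'
#' Estimates the 2D affine transform (rotation, anisotropic scale, shear,
#' translation about the fixed-image center) that maps fixed-frame
#' coordinates onto the moving image so that the warped moving image best
#' matches the fixed one. Similarity is Mattes-style binned mutual
#' information by default (modality-crossing); `"mse"` mean squares (on
#' z-scored intensities) is available for same-modality problems.
#' Optimization is Nelder-Mead over a 3-level (default) resolution pyramid
#' with a centroid-based translation initialization.
#'
#' @param moving moving image (`color_embedding`, `ion_image`, or matrix).
#' @param fixed fixed image (e.g. an MR slice), same conventions.
#' @param metric `"mattes"` or `"mse"`.
#' @param levels resolution-pyramid depth.
#' @param max_iter Nelder-Mead iterations per level.
#' @param init optional [affine_transform()] initial guess.
#' @param similarity_floor final-similarity sanity floor; below it the
#'   registration is declared failed (Pearson correlation of the overlap for
#'   `"mse"`, mutual information for `"mattes"`).
#' @return An [affine_transform()] (fixed -> moving coordinates) with an
#'   `optimizer_trace` attribute.
#' @export
register_affine <- function(moving, fixed, metric = c("mattes", "mse"),
                            levels = 3, max_iter = 400, init = NULL,
                            similarity_floor = NULL) {
  metric <- match.arg(metric)
  mov <- as_reg_image(moving)
  fix <- as_reg_image(fixed)
  assert_that(any(mov > 0) && any(fix > 0),
              "registration images must be non-empty")
  if (metric == "mse") {
    mov <- zscore(mov); fix <- zscore(fix)
  }
  if (is.null(similarity_floor)) {
    similarity_floor <- if (metric == "mse") 0.25 else 0.12
  }

  # centroid init for translation (fixed -> moving direction)
  centroid <- function(m) {
    w <- m - min(m); s <- sum(w)
    if (s == 0) return(c(nrow(m), ncol(m)) / 2)
    idx <- which(w > 0, arr.ind = TRUE)
    c(sum(idx[, 1] * w[w > 0]), sum(idx[, 2] * w[w > 0])) / s
  }
  p <- c(0, 0, 0, 0, centroid(mov) - centroid(fix))
  if (!is.null(init)) {
    assert_that(inherits(init, "affine_transform"), "`init` must be affine")
    p[5:6] <- init$translation
  }

  pyr_mov <- list(mov); pyr_fix <- list(fix)
  if (levels > 1) {
    for (l in 2:levels) {
      pyr_mov[[l]] <- downsample2(pyr_mov[[l - 1]])
      pyr_fix[[l]] <- downsample2(pyr_fix[[l - 1]])
    }
  }

  # coarse multi-start over rotation: the MI/MSE landscape has rotational
  # local minima, so seed the coarsest level from the best of a small
  # angle sweep around the centroid-aligned pose
  {
    l0 <- levels
    fac0 <- 2^(l0 - 1)
    movl <- pyr_mov[[l0]]; fixl <- pyr_fix[[l0]]
    shape0 <- dim(fixl)
    center0 <- (shape0 + 1) / 2
    grid0 <- cbind(rep(seq_len(shape0[1]), shape0[2]),
                   rep(seq_len(shape0[2]), each = shape0[1]))
    sweep_obj <- function(ang) {
      tr <- params_to_affine(c(ang, p[2:4], p[5:6] / fac0), center0)
      warped <- warp_matrix(movl, transform_points(tr, grid0), shape0)
      similarity_value(warped, fixl, metric)
    }
    angles <- seq(-30, 30, by = 5)
    vals <- vapply(angles, sweep_obj, numeric(1))
    p[1] <- angles[which.min(vals)]
  }

  trace <- list()
  for (l in rev(seq_len(levels))) {
    fac <- 2^(l - 1)
    movl <- pyr_mov[[l]]; fixl <- pyr_fix[[l]]
    shape <- dim(fixl)
    center <- (shape + 1) / 2
    grid <- cbind(rep(seq_len(shape[1]), shape[2]),
                  rep(seq_len(shape[2]), each = shape[1]))
    obj <- function(pl) {
      tr <- params_to_affine(c(pl[1:4], pl[5:6]), center)
      pts <- transform_points(tr, grid)
      warped <- warp_matrix(movl, pts, shape)
      similarity_value(warped, fixl, metric)
    }
    pl <- c(p[1:4], p[5:6] / fac)
    ctrl <- list(maxit = max_iter, reltol = 1e-10,
                 parscale = c(2, 0.05, 0.05, 0.05, 1, 1))
    fit <- stats::optim(pl, obj, method = "Nelder-Mead", control = ctrl)
    if (l == 1) {  # restart at the finest level to escape simplex collapse
      fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = ctrl)
    }
    p <- c(fit$par[1:4], fit$par[5:6] * fac)
    trace[[length(trace) + 1]] <- list(level = l, value = fit$value,
                                       counts = fit$counts[1])
  }

  shape <- dim(fix)
  center <- (shape + 1) / 2
  result <- params_to_affine(p, center)
  grid <- cbind(rep(seq_len(shape[1]), shape[2]),
                rep(seq_len(shape[2]), each = shape[1]))
  warped <- warp_matrix(mov, transform_points(result, grid), shape)
  ok <- !is.na(warped)
  quality <- if (metric == "mse") {
    if (sum(ok) > 10 && stats::sd(warped[ok]) > 0 && stats::sd(fix[ok]) > 0) {
      stats::cor(warped[ok], fix[ok])
    } else -1
  } else {
    mutual_information(warped, fix)
  }
  if (quality < similarity_floor) {
    abort_msipk(sprintf(
      "affine registration failed: final %s similarity %.3f below floor %.3f (overlap %d px)",
      metric, quality, similarity_floor, sum(ok)),
      "msipk_registration_error")
  }
  attr(result, "optimizer_trace") <- trace
  attr(result, "similarity") <- quality
  result
}

#' B-spline refinement of an affine registration
#'
#' Refines an affine alignment with a cubic B-spline free-form deformation:
#' the total map is `T(x) = A(x) + d(x)` with `d` the B-spline displacement
#' field on the fixed frame. Control displacements are optimized by L-BFGS-B
#' with an analytic mean-squares gradient over a 2-level resolution schedule
#' (coarse pixel subset first, then all pixels); a small ridge penalty keeps
#' the field smooth. Cross-modality pairs should be histogram-matched
#' (`histogram_match = TRUE`) since the refinement metric is mean squares.
#'
#' @param moving,fixed images as in [register_affine()].
#' @param init the affine initialization (required).
#' @param spacing control-point spacing, px (in the full-resolution frame).
#' @param blur_schedule decreasing box-blur radii defining the
#'   coarse-to-fine smoothing schedule (the final 0 runs on the raw
#'   images); smoothing enlarges the capture range for displacements larger
#'   than a pixel without changing the control-grid resolution. A list of
#'   schedules fits one candidate field per schedule and keeps the one with
#'   the lowest mean-squares data term on the raw images (deterministic
#'   model selection).
#' @param max_iter L-BFGS-B iterations per level.
#' @param lambda smoothness penalty weight on first differences of
#'   neighboring control displacements; flat image regions inherit their
#'   displacement from informative neighbors instead of collapsing to zero.
#'   Recycled along `blur_schedule` candidates.
#' @param histogram_match match the moving histogram to the fixed one first.
#' @param init_bspline optional [bspline_transform()] warm start (e.g. a
#'   high-smoothness coarse pass continued at lower `lambda`).
#' @param min_improvement minimum relative mean-squares improvement over the
#'   affine-only alignment required to keep the fitted field; below it the
#'   identity (zero-displacement) field is returned, so refinement never
#'   degrades an already-affine alignment by chasing noise.
#' @return A [bspline_transform()] with an `optimizer_trace` attribute
#'   (objective per evaluation, decreasing).
#' @export
register_bspline <- function(moving, fixed, init, spacing = 8,
                             blur_schedule = list(c(3, 1, 0), c(4, 2, 1, 0)),
                             max_iter = 100,
                             lambda = c(1e-3, 3e-4), histogram_match = FALSE,
                             init_bspline = NULL, min_improvement = 0.05) {
  assert_that(inherits(init, "affine_transform"),
              "`init` must be an affine_transform from register_affine()")
  mov <- as_reg_image(moving)
  fix <- as_reg_image(fixed)
  if (histogram_match) {
    r <- rank(mov, ties.method = "average") / length(mov)
    mov <- matrix(stats::quantile(fix, r, type = 4), nrow(mov), ncol(mov))
  }
  mov <- zscore(mov); fix <- zscore(fix)
  shape <- dim(fix)
  gsz <- bspline_grid_size(shape, spacing)
  n_ctrl <- prod(gsz)

  shapef <- dim(fix)
  grid <- cbind(rep(seq_len(shapef[1]), shapef[2]),
                rep(seq_len(shapef[2]), each = shapef[1]))
  apts <- transform_points(init, grid)
  Wr <- bspline_weights_1d(grid[, 1], spacing, gsz[1])
  Wc <- bspline_weights_1d(grid[, 2], spacing, gsz[2])
  disp_of <- function(par) {
    Cr <- matrix(par[seq_len(n_ctrl)], gsz[1], gsz[2])
    Cc <- matrix(par[n_ctrl + seq_len(n_ctrl)], gsz[1], gsz[2])
    cbind(rowSums((Wr %*% Cr) * Wc), rowSums((Wr %*% Cc) * Wc))
  }

  # first-difference smoothness penalty on the control grid
  n_pairs <- 2 * ((gsz[1] - 1) * gsz[2] + gsz[1] * (gsz[2] - 1))
  smooth_pen <- function(par) {
    val <- 0
    for (off in c(0, n_ctrl)) {
      C <- matrix(par[off + seq_len(n_ctrl)], gsz[1], gsz[2])
      val <- val + sum(diff(C)^2) + sum(t(diff(t(C)))^2)
    }
    val / n_pairs
  }
  smooth_grad <- function(par) {
    g <- numeric(length(par))
    for (off in c(0, n_ctrl)) {
      C <- matrix(par[off + seq_len(n_ctrl)], gsz[1], gsz[2])
      G <- matrix(0, gsz[1], gsz[2])
      dr <- diff(C)
      G[-1, ] <- G[-1, ] + 2 * dr
      G[-gsz[1], ] <- G[-gsz[1], ] - 2 * dr
      dc <- t(diff(t(C)))
      G[, -1] <- G[, -1] + 2 * dc
      G[, -gsz[2]] <- G[, -gsz[2]] - 2 * dc
      g[off + seq_len(n_ctrl)] <- as.vector(G)
    }
    g / n_pairs
  }

  trace <- list()
  run_level <- function(par, blur, maxit) {
    level_trace <- numeric(0)
    movl <- if (blur > 0) box_blur(mov, blur) else mov
    fixl <- if (blur > 0) box_blur(fix, blur) else fix
    gr_r <- (rbind(movl[-1, ], movl[nrow(movl), ]) -
               rbind(movl[1, ], movl[-nrow(movl), ])) / 2
    gr_c <- (cbind(movl[, -1], movl[, ncol(movl)]) -
               cbind(movl[, 1], movl[, -ncol(movl)])) / 2
    fvals <- fixl[grid]
    fn <- function(par) {
      wpts <- apts + disp_of(par)
      w <- bilinear_sample(movl, wpts[, 1], wpts[, 2], fill = NA_real_)
      r <- w - fvals
      r[is.na(r)] <- 0
      val <- mean(r^2) + lam * smooth_pen(par)
      level_trace <<- c(level_trace, val)
      val
    }
    gr <- function(par) {
      wpts <- apts + disp_of(par)
      w <- bilinear_sample(movl, wpts[, 1], wpts[, 2], fill = NA_real_)
      r <- w - fvals
      r[is.na(r)] <- 0
      mr <- bilinear_sample(gr_r, wpts[, 1], wpts[, 2], fill = 0)
      mc <- bilinear_sample(gr_c, wpts[, 1], wpts[, 2], fill = 0)
      vr <- 2 * r * mr / length(r)
      vc <- 2 * r * mc / length(r)
      g_r <- crossprod(Wr, vr * Wc)
      g_c <- crossprod(Wr, vc * Wc)
      c(as.vector(g_r), as.vector(g_c)) + lam * smooth_grad(par)
    }
    out <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit))$par
    trace[[length(trace) + 1]] <<- level_trace
    out
  }

  unblurred_mse <- function(par) {
    wpts <- apts + disp_of(par)
    w <- bilinear_sample(mov, wpts[, 1], wpts[, 2], fill = NA_real_)
    r <- w - fix[grid]
    r[is.na(r)] <- 0
    mean(r^2)
  }
  baseline <- unblurred_mse(rep(0, 2 * n_ctrl))

  par0 <- if (!is.null(init_bspline)) {
    assert_that(inherits(init_bspline, "bspline_transform") &&
                  identical(dim(init_bspline$disp_r), gsz),
                "`init_bspline` must match the control grid")
    c(as.vector(init_bspline$disp_r), as.vector(init_bspline$disp_c))
  } else {
    rep(0, 2 * n_ctrl)
  }
  if (!is.list(blur_schedule)) blur_schedule <- list(blur_schedule)
  lambdas <- rep_len(lambda, length(blur_schedule))

  best_par <- NULL; best_mse <- Inf; best_trace <- NULL
  for (ci in seq_along(blur_schedule)) {
    lam <- lambdas[ci]
    trace <- list()
    par <- par0
    for (blur in blur_schedule[[ci]]) {
      par <- run_level(par, blur, max_iter)
    }
    cand_mse <- unblurred_mse(par)
    if (cand_mse < best_mse) {
      best_mse <- cand_mse; best_par <- par; best_trace <- trace
    }
  }
  par <- best_par
  trace <- best_trace

  final <- unblurred_mse(par)
  if (final > baseline * 2) {
    abort_msipk(sprintf(
      "B-spline refinement diverged: mean-squares rose from %.4g (affine only) to %.4g",
      baseline, final), "msipk_registration_error")
  }
  if (baseline > 0 && (1 - final / baseline) < min_improvement) {
    par <- rep(0, 2 * n_ctrl)  # no evidence of a non-rigid component
  }

  n_ctrl <- prod(gsz)
  out <- bspline_transform(
    spacing,
    matrix(par[seq_len(n_ctrl)], gsz[1], gsz[2]),
    matrix(par[n_ctrl + seq_len(n_ctrl)], gsz[1], gsz[2]),
    shape)
  attr(out, "optimizer_trace") <- trace
  out
}

#' Warp an image or mask through a transform chain
#'
#' Resamples the moving image on the fixed grid through the chain
#' (`warped(x) = moving(T(x))`). Scalar images are interpolated bilinearly
#' with missing pixels propagating as missing; masks use nearest-neighbor
#' interpolation and stay strictly binary.
#'
#' @param chain a [transform_chain()], [affine_transform()] or
#'   [bspline_transform()].
#' @param image an `ion_image`, `concentration_map`, `roi_mask`, logical or
#'   numeric matrix.
#' @param shape output (fixed-frame) grid shape; defaults to the input
#'   shape.
#' @return The warped object, same class as the input.
#' @export
apply_transform <- function(chain, image, shape = NULL) {
  assert_that(inherits(chain, c("transform_chain", "affine_transform",
                                "bspline_transform")),
              "`chain` must be a transform")
  vals <- if (inherits(image, c("ion_image", "concentration_map"))) {
    image$values
  } else if (inherits(image, "roi_mask")) {
    image$pixels
  } else image
  assert_that(is.matrix(vals), "`image` must be matrix-backed")
  shape <- shape %||% dim(vals)
  grid <- cbind(rep(seq_len(shape[1]), shape[2]),
                rep(seq_len(shape[2]), each = shape[1]))
  pts <- transform_points(chain, grid)
  out <- if (is.logical(vals)) {
    m <- nearest_sample(vals, pts[, 1], pts[, 2], fill = FALSE)
    m[is.na(m)] <- FALSE
    matrix(as.logical(m), shape[1], shape[2])
  } else {
    matrix(bilinear_sample(vals, pts[, 1], pts[, 2], fill = NA_real_),
           shape[1], shape[2])
  }
  if (inherits(image, c("ion_image", "concentration_map"))) {
    image$values <- out
    image
  } else if (inherits(image, "roi_mask")) {
    if (!any(out)) {
      abort_msipk(sprintf("ROI '%s' warped outside the frame", image$label),
                  "msipk_empty_roi")
    }
    new_roi_mask(image$label, out)
  } else out
}

#' Mean target registration error over control points
#'
#' Distance between an estimated transform and the ground-truth deformation,
#' averaged over control points in the fixed frame. Used to score phantom
#' registrations where the truth map is known analytically.
#'
#' @param estimate estimated transform (fixed -> moving).
#' @param truth ground-truth map: a transform object or a function mapping
#'   an n x 2 point matrix to n x 2.
#' @param points n x 2 matrix of fixed-frame control points.
#' @return Mean Euclidean error in pixels.
#' @export
target_registration_error <- function(estimate, truth, points) {
  points <- rbind2cols(points)
  est <- transform_points(estimate, points)
  tru <- if (is.function(truth)) truth(points) else
    transform_points(truth, points)
  mean(sqrt(rowSums((est - tru)^2)))
}

#' Dice overlap of two masks
#' @param a,b logical matrices or [new_roi_mask()]s of equal shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  assert_that(identical(dim(a), dim(b)), "masks must share a grid",
              "msipk_shape_error")
  2 * sum(a & b) / (sum(a) + sum(b))
}
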