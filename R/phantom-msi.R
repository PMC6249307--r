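#' Generate a multi-section MSI brain phantom with ground truth
#'
#' Builds a seeded, brain-shaped multi-section phantom carrying the structures
#' the analysis pipeline assumes: an elliptical tumor with a planted
#' core-to-edge drug gradient (`core_edge_ratio`, ~2-fold by default), a drug
#' metabolite channel at `metabolite_fraction` of the parent intensity plus a
#' ventricle hotspot, a sparse vessel (heme) map, and a biomarker channel
#' confined to the tumor. Each tissue pixel receives a centroided peak list
#' (channel peaks plus two endogenous background peaks) with uniform ppm
#' jitter on centroid positions and multiplicative lognormal intensity noise.
#'
#' In the tumor edge the planted drug concentration co-varies with distance
#' to vessels (delivery is vessel-limited at the invasive edge), while the
#' core receives a vessel-independent texture; region means are rescaled so
#' the noise-free core/edge mean ratio equals `core_edge_ratio` exactly.
#'
#' @param config a [phantom_config()].
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{list of [msi_dataset] sections (length `n_sections`).}
#'     \item{truth}{a `phantom_truth` object: per-section boolean masks
#'       (`tissue_mask`, `tumor_mask`, `core_mask`, `edge_mask`,
#'       `vessel_mask`, `ventricle_mask`), the noise-free
#'       `true_concentration` maps (ng/g), noise-free per-channel intensity
#'       images (`channels`), and slots for the MR deformation and omics
#'       effects filled by the companion generators.}
#'   }
#' @export
#' @examples
#' ph <- generate_msi_phantom(phantom_config(grid_shape = c(32, 32),
#'                                           n_sections = 2, noise_cv = 0))
#' length(ph$dataset)
generate_msi_phantom <- function(config) {
  assert_that(inherits(config, "phantom_config"),
              "`config` must be a phantom_config", "msipk_config_error")
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  K <- config$n_sections

  with_seed(config$seed, {
    sections <- vector("list", K)
    truth <- list(
      tissue_mask = vector("list", K), tumor_mask = vector("list", K),
      core_mask = vector("list", K), edge_mask = vector("list", K),
      vessel_mask = vector("list", K), ventricle_mask = vector("list", K),
      true_concentration = vector("list", K), channels = vector("list", K),
      deformation = NULL, omics_effects = NULL, config = config
    )
    mid <- (K + 1) / 2
    halfspan <- max(K / 2, 1)

    for (k in seq_len(K)) {
      zf <- 0.6 + 0.4 * sqrt(max(0, 1 - ((k - mid) / halfspan)^2))
      tissue <- ellipse_mask(nr, nc, c(nr / 2 + 0.5, nc / 2 + 0.5),
                             c(0.40 * nr, 0.44 * nc))
      ventricle <- ellipse_mask(nr, nc, c(0.45 * nr, 0.42 * nc),
                                c(0.07 * nr, 0.045 * nc)) & tissue
      tumor <- ellipse_mask(nr, nc, c(0.50 * nr, 0.66 * nc),
                            c(0.20 * nr * zf, 0.18 * nc * zf),
                            angle = 0.3) & tissue & !ventricle
      core <- erode_square(tumor, config$core_depth_px)
      assert_that(any(core),
                  "tumor too small for `core_depth_px` erosion; enlarge grid or shrink depth",
                  "msipk_config_error")
      edge <- tumor & !core

      vessel <- random_vessel_mask(nr, nc, tissue,
                                   n_walks = max(2L, round(nr * nc / 1500)),
                                   walk_len = round(nr * 0.5),
                                   seed_region = edge)

      conc <- plant_concentration(config, tissue, tumor, core, edge,
                                  ventricle, vessel)

      ch <- noise_free_channels(config, conc, tissue, tumor, ventricle,
                                vessel, core, edge)

      sections[[k]] <- render_spectra(config, ch, tissue, section_index = k)

      truth$tissue_mask[[k]] <- tissue
      truth$tumor_mask[[k]] <- tumor
      truth$core_mask[[k]] <- core
      truth$edge_mask[[k]] <- edge
      truth$vessel_mask[[k]] <- vessel
      truth$ventricle_mask[[k]] <- ventricle
      truth$true_concentration[[k]] <- conc
      truth$channels[[k]] <- ch
    }
    class(truth) <- "phantom_truth"
    list(dataset = sections, truth = truth)
  })
}

# Seeded branching-walk vessel skeleton, dilated by 1 px, clipped to tissue.
# Half of the walks start inside `seed_region` (the invasive tumor edge,
# where peritumoral vasculature concentrates), the rest anywhere on tissue.
random_vessel_mask <- function(nr, nc, tissue, n_walks, walk_len,
                               seed_region = NULL) {
  m <- matrix(FALSE, nr, nc)
  idx <- which(tissue)
  starts <- sample(idx, n_walks)
  if (!is.null(seed_region) && any(seed_region)) {
    n_edge <- max(1L, floor(n_walks / 2))
    starts[seq_len(n_edge)] <- sample(which(seed_region), n_edge,
                                      replace = n_edge > sum(seed_region))
  }
  for (s in starts) {
    r <- ((s - 1) %% nr) + 1
    c <- ((s - 1) %/% nr) + 1
    theta <- stats::runif(1, 0, 2 * pi)
    pos <- c(r, c)
    for (step in seq_len(walk_len)) {
      theta <- theta + stats::rnorm(1, 0, 0.35)
      pos <- pos + c(sin(theta), cos(theta))
      ri <- round(pos[1]); ci <- round(pos[2])
      if (ri < 1 || ci < 1 || ri > nr || ci > nc) break
      m[ri, ci] <- TRUE
      if (stats::runif(1) < 0.04) theta <- theta + stats::runif(1, -pi / 2, pi / 2)
    }
  }
  dilate_square(m, 1) & tissue
}

# Smooth multi-scale random field (unit sd): tissue-like molecular texture
# with structure at several correlation lengths, so images carry geometric
# information away from region boundaries.
texture_field <- function(nr, nc) {
  f <- box_blur(matrix(stats::rnorm(nr * nc), nr, nc), 1) * 0.6 +
    box_blur(matrix(stats::rnorm(nr * nc), nr, nc), 2) +
    box_blur(matrix(stats::rnorm(nr * nc), nr, nc), 4)
  f / max(stats::sd(f), 1e-12)
}

# Noise-free concentration field with region means rescaled so the planted
# core/edge ratio and normal-brain level are exact.
plant_concentration <- function(config, tissue, tumor, core, edge,
                                ventricle, vessel) {
  nr <- nrow(tissue); nc <- ncol(tissue)
  conc <- matrix(0, nr, nc)

  texture <- texture_field(nr, nc)

  core_field <- pmax(1 + 0.15 * texture, 0.05)
  conc[core] <- config$core_conc * core_field[core] / mean(core_field[core])

  # vessel signal = on-vessel plus a smooth perivascular halo; the same
  # functional form drives the heme channel, so edge drug and heme co-vary
  vsig <- vessel * 1 + 0.4 * box_blur(vessel * 1, 2)
  vmax <- max(vsig[edge], 0)
  vn <- if (vmax > 0) vsig / vmax else vsig
  edge_field <- pmax(0.4 + 1.2 * vn + 0.05 * texture, 0.05)
  edge_target <- config$core_conc / config$core_edge_ratio
  conc[edge] <- edge_target * edge_field[edge] / mean(edge_field[edge])

  brain <- tissue & !tumor & !ventricle
  brain_field <- pmax(1 + 0.15 * texture, 0.05)
  conc[brain] <- config$brain_conc * brain_field[brain] / mean(brain_field[brain])

  conc[ventricle] <- 0.4 * config$brain_conc
  conc
}

# Noise-free channel intensity images (NA off tissue). The drug channel is the
# calibration-linear image of the concentration field.
noise_free_channels <- function(config, conc, tissue, tumor, ventricle,
                                vessel, core, edge) {
  nr <- nrow(tissue); nc <- ncol(tissue)
  blank <- matrix(NA_real_, nr, nc)

  drug <- blank
  drug[tissue] <- config$cal_slope * conc[tissue] + config$cal_intercept

  metabolite <- blank
  metabolite[tissue] <- config$metabolite_fraction * drug[tissue]
  # ventricle hotspot (CSF accumulation), moderate relative to tissue levels
  hot <- mean(drug[tissue]) * config$metabolite_fraction * 2
  metabolite[ventricle] <- metabolite[ventricle] + hot

  vb <- box_blur(vessel * 1, 2)
  heme <- blank
  heme[tissue] <- 100 + 500 * (vessel[tissue]) + 200 * vb[tissue]

  biomarker <- blank
  biomarker[tissue] <- 0
  texture <- texture_field(nr, nc)
  biomarker[tumor] <- 800 * pmax(1 + 0.1 * texture[tumor], 0.05)

  lipid <- blank
  lipid[tissue] <- 1200 * pmax(1 + 0.12 * texture[tissue], 0.05)
  lipid[tumor] <- 500 * pmax(1 + 0.12 * texture[tumor], 0.05)
  lipid[ventricle] <- 800

  matrixpk <- blank
  matrixpk[tissue] <- 500

  list(drug = drug, metabolite = metabolite, heme = heme,
       biomarker = biomarker, lipid_bg = lipid, matrix_bg = matrixpk)
}

# Assemble centroided per-pixel spectra from the channel images, applying ppm
# jitter and multiplicative lognormal noise. Zero-intensity peaks are dropped
# (e.g. biomarker outside the tumor).
render_spectra <- function(config, channels, tissue, section_index) {
  mz_named <- stats::setNames(config$channels$mz, config$channels$name)
  mz_all <- c(mz_named, lipid_bg = 478.300, matrix_bg = 550.300)
  imgs <- channels[names(mz_all)]

  coords <- which(tissue, arr.ind = TRUE)
  n_px <- nrow(coords)
  cv <- config$noise_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  jit <- config$mz_jitter_ppm

  spectra <- vector("list", n_px)
  for (i in seq_len(n_px)) {
    r <- coords[i, 1]; c <- coords[i, 2]
    inten <- vapply(imgs, function(im) im[r, c], numeric(1))
    if (sdlog > 0) {
      inten <- inten * stats::rlnorm(length(inten),
                                     meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    mzv <- mz_all
    if (jit > 0) {
      mzv <- mzv * (1 + stats::runif(length(mzv), -jit, jit) * 1e-6)
    }
    keep <- inten > 0
    ord <- order(mzv[keep])
    spectra[[i]] <- list(mz = unname(mzv[keep][ord]),
                         intensity = unname(inten[keep][ord]))
  }

  new_msi_dataset(
    spectra = spectra,
    coords = coords,
    grid_shape = dim(tissue),
    pixel_size = config$pixel_size,
    z_spacing = config$z_spacing,
    section_index = section_index,
    metadata = list(polarity = "positive", mz_range = c(380, 620))
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  K <- length(x$tumor_mask)
  cat(sprintf("<phantom_truth> %d section(s), grid %d x %d\n", K,
              nrow(x$tumor_mask[[1]]), ncol(x$tumor_mask[[1]])))
  cat(sprintf("  tumor px (section 1): %d (core %d, edge %d)\n",
              sum(x$tumor_mask[[1]]), sum(x$core_mask[[1]]),
              sum(x$edge_mask[[1]])))
  if (!is.null(x$deformation)) cat("  MR deformation: recorded\n")
  invisible(x)
}
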