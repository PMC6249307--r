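# End-to-end orchestration: configuration, validation, staged execution,
# manifest with per-stage output hashes.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. By
#' default every stage runs on a freshly simulated phantom; supplying paths
#' switches a stage to user data.
#'
#' @param outdir output directory (created on run).
#' @param seed master seed recorded in the manifest and used for every
#'   stochastic stage.
#' @param stages character vector of stages to run, in pipeline order, from
#'   `"simulate"`, `"ionimage"`, `"quantify"`, `"segment"`, `"register"`,
#'   `"colocalize"`, `"integrate"`.
#' @param phantom named list of [phantom_config()] overrides.
#' @param channels channel table (`name`, `mz`) with optional `tolerance`
#'   column (default 0.001 Da).
#' @param calibration list: `slope`, `intercept`, `noise_cv` for the
#'   simulated mimetic series (or `path` to a calibration CSV).
#' @param segmentation list: `k` (clusters), `depth_px` (core/edge split).
#' @param registration list: `metric`, `mri` (list with `slice_index`),
#'   `spacing` (B-spline control spacing), `tsne_iterations`.
#' @param omics named list of [generate_omics()] overrides.
#' @param paths list of optional input paths: `msi` (imzML files), `mri`
#'   (NIfTI volume), `calibration` (CSV), `network` (TSV).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "msipk_run",
                            seed = 1L,
                            stages = c("simulate", "ionimage", "quantify",
                                       "segment", "register", "colocalize",
                                       "integrate"),
                            phantom = list(),
                            channels = NULL,
                            calibration = list(slope = 2, intercept = 0,
                                               noise_cv = 0.05),
                            segmentation = list(k = 2, depth_px = 2),
                            registration = list(metric = "mattes",
                                                mri = list(slice_index = 1),
                                                spacing = 8),
                            omics = list(),
                            paths = list()) {
  all_stages <- c("simulate", "ionimage", "quantify", "segment", "register",
                  "colocalize", "integrate")
  assert_that(all(stages %in% all_stages),
              sprintf("unknown stage(s): %s",
                      paste(setdiff(stages, all_stages), collapse = ", ")),
              "msipk_config_error")
  if (is.null(channels)) {
    channels <- default_channels()
  }
  channels <- tibble::as_tibble(channels)
  if (!"tolerance" %in% names(channels)) channels$tolerance <- 0.001
  cfg <- structure(list(
    outdir = outdir, seed = as.integer(seed),
    stages = intersect(all_stages, stages),
    phantom = phantom, channels = channels, calibration = calibration,
    segmentation = segmentation, registration = registration,
    omics = omics, paths = paths
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (!is.null(p) && !all(file.exists(p))) {
      abort_msipk(sprintf("configured %s path does not exist: %s", nm,
                          paste(p[!file.exists(p)], collapse = ", ")),
                  "msipk_config_error")
    }
  }
  if ("register" %in% cfg$stages && !"simulate" %in% cfg$stages &&
      is.null(cfg$paths$mri)) {
    abort_msipk("registration enabled without a simulated phantom or an MRI path",
                "msipk_config_error")
  }
  if (("ionimage" %in% cfg$stages || "quantify" %in% cfg$stages) &&
      !"simulate" %in% cfg$stages && is.null(cfg$paths$msi)) {
    abort_msipk("imaging stages enabled without a simulated phantom or MSI paths",
                "msipk_config_error")
  }
  invisible(cfg)
}

stage_files <- function(dir) {
  fs <- list.files(dir, full.names = TRUE, recursive = TRUE)
  if (!length(fs)) return(list())
  h <- tools::md5sum(fs)
  as.list(stats::setNames(unname(h), basename(fs)))
}

run_stage <- function(name, report, fun) {
  dir <- file.path(report$outdir, name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch(fun(dir), error = function(e) {
    abort_msipk(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "msipk_stage_error")
  })
  report$manifest$stages[[name]] <- list(files = stage_files(dir))
  report$results[[name]] <- res
  report
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order — phantom simulation, ion-image
#' extraction and 3D stacking, calibration and concentration mapping with
#' core/edge statistics, bisecting k-means segmentation, t-SNE/affine/
#' B-spline registration against the MR phantom, colocalization tables, and
#' multi-omic integration — writing each stage's outputs under
#' `outdir/<stage>/` and a run manifest (`manifest.json`) with seeds,
#' versions and per-stage output hashes. Reruns with the same configuration
#' and seed are bit-identical for deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report`: `outdir`, `manifest`, and the in-memory
#'   `results` of each stage.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must come from pipeline_config()")
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  report <- list(
    outdir = config$outdir,
    manifest = list(
      seed = config$seed,
      stages = list(),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("msipk")),
      stages_enabled = config$stages
    ),
    results = list()
  )

  phantom <- NULL; mri <- NULL

  if ("simulate" %in% config$stages) {
    report <- run_stage("simulate", report, function(dir) {
      pc <- do.call(phantom_config, utils::modifyList(
        list(seed = config$seed), config$phantom))
      ph <- generate_msi_phantom(pc)
      mr <- generate_mri_phantom(ph$truth, pc)
      write_imzml(ph$dataset[[1]], file.path(dir, "section_01.imzML"))
      write_mri_nifti(mr, file.path(dir, "mri_phantom.nii"))
      cal <- do.call(generate_calibration_series, utils::modifyList(
        list(seed = config$seed),
        config$calibration[setdiff(names(config$calibration), "path")]))
      write_calibration_csv(cal, file.path(dir, "calibration.csv"))
      list(phantom = ph, mri = mr, calibration = cal, config = pc)
    })
    phantom <- report$results$simulate$phantom
    mri <- report$results$simulate$mri
  }

  datasets <- if (!is.null(phantom)) phantom$dataset else {
    lapply(config$paths$msi, read_imzml)
  }

  images <- NULL
  if ("ionimage" %in% config$stages) {
    report <- run_stage("ionimage", report, function(dir) {
      per_channel <- purrr::pmap(config$channels, function(name, mz, tolerance) {
        imgs <- lapply(datasets, extract_ion_image, target_mz = mz,
                       tolerance = tolerance)
        vol <- stack_volume(imgs, datasets[[1]]$z_spacing %||% 160)
        utils::write.table(imgs[[1]]$values,
                           file.path(dir, sprintf("%s_section01.tsv", name)),
                           sep = "\t", row.names = FALSE, col.names = FALSE)
        vol
      })
      names(per_channel) <- config$channels$name
      per_channel
    })
    images <- report$results$ionimage
  }

  model <- NULL
  if ("quantify" %in% config$stages) {
    report <- run_stage("quantify", report, function(dir) {
      cal <- if (!is.null(config$paths$calibration)) {
        read_calibration_csv(config$paths$calibration)
      } else report$results$simulate$calibration
      m <- fit_calibration(cal)
      jsonlite::write_json(glance(m), file.path(dir, "calibration_model.json"),
                           auto_unbox = TRUE, digits = NA)
      maps <- lapply(images$drug$images, apply_calibration, model = m)
      stats <- NULL
      if (!is.null(phantom)) {
        rows <- purrr::imap(maps, function(map, k) {
          dplyr::bind_rows(
            roi_statistics(map, new_roi_mask("tumor", phantom$truth$tumor_mask[[k]])),
            roi_statistics(map, new_roi_mask("core", phantom$truth$core_mask[[k]])),
            roi_statistics(map, new_roi_mask("edge", phantom$truth$edge_mask[[k]]))
          ) |> dplyr::mutate(section = k)
        })
        stats <- dplyr::bind_rows(rows)
        utils::write.table(as.data.frame(stats),
                           file.path(dir, "roi_stats.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
      list(model = m, maps = maps, roi_stats = stats)
    })
    model <- report$results$quantify$model
  }

  if ("segment" %in% config$stages) {
    report <- run_stage("segment", report, function(dir) {
      seg <- segment_bisecting_kmeans(datasets[[1]],
                                      k = config$segmentation$k,
                                      seed = config$seed)
      ce <- split_core_edge(seg$masks$tumor,
                            depth_px = config$segmentation$depth_px)
      utils::write.table(seg$labels, file.path(dir, "labels_section01.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      list(segmentation = seg, core_edge = ce)
    })
  }

  if ("register" %in% config$stages) {
    report <- run_stage("register", report, function(dir) {
      slice <- config$registration$mri$slice_index %||% 1
      fixed <- if (!is.null(mri)) mri$volume[, , slice] else {
        read_mri_nifti(config$paths$mri)$volume[, , slice]
      }
      emb <- embed_tsne_lab(datasets[[slice]],
                            iterations = config$registration$tsne_iterations %||% 250,
                            seed = config$seed)
      aff <- register_affine(emb, fixed,
                             metric = config$registration$metric %||% "mse")
      bsp <- register_bspline(emb, fixed, aff,
                              spacing = config$registration$spacing %||% 8)
      chain <- transform_chain(aff, bsp)
      write_transform_json(chain, file.path(dir, "transform.json"))
      warped <- if (!is.null(images)) {
        apply_transform(chain, images$drug$images[[slice]])
      } else NULL
      list(embedding = emb, chain = chain, warped_drug = warped)
    })
  }

  if ("colocalize" %in% config$stages) {
    report <- run_stage("colocalize", report, function(dir) {
      assert_that(!is.null(images), "colocalization needs the ionimage stage")
      chans <- images[intersect(c("drug", "metabolite", "heme"),
                                names(images))]
      regions <- list()
      if (!is.null(phantom)) {
        regions <- list(
          tumor = purrr::map(phantom$truth$tumor_mask, identity),
          core = purrr::map(phantom$truth$core_mask, identity),
          edge = purrr::map(phantom$truth$edge_mask, identity)
        )
      }
      tbl <- correlation_table(chans, regions)
      write_correlation_tsv(tbl, file.path(dir, "colocalization.tsv"))
      tbl
    })
  }

  if ("integrate" %in% config$stages) {
    report <- run_stage("integrate", report, function(dir) {
      om <- do.call(generate_omics, utils::modifyList(
        list(seed = config$seed), config$omics))
      norm <- tmt_normalize(om$phospho)
      avg <- geometric_mean_replicates(norm)
      tx <- log_ratio_transform(om$transcripts, om$truth$reference_sample)
      plog <- avg
      plog$values <- log2(pmax(avg$values, 1e-9))
      cm <- feature_correlation_matrix(plog, tx)
      dend <- hierarchical_cluster(cm, linkage = "average")
      write_omics_tsv(norm, file.path(dir, "phospho_normalized.tsv"))
      write_omics_tsv(tx, file.path(dir, "transcripts_log2ratio.tsv"))
      write_newick(dend, file.path(dir, "integration_dendrogram.nwk"))
      mod_means <- colMeans(avg$values[om$truth$phospho_module, , drop = FALSE])
      utils::write.table(
        data.frame(sample = names(mod_means), module_mean = mod_means),
        file.path(dir, "dose_module_means.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      net <- if (!is.null(config$paths$network)) {
        filter_network_edges(read_network_tsv(config$paths$network))
      } else NULL
      list(omics = om, normalized = norm, averaged = avg,
           transcripts = tx, correlation = cm, dendrogram = dend,
           module_means = mod_means, network = net)
    })
  }

  jsonlite::write_json(report$manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d stage(s) in %s\n",
              length(x$manifest$stages), x$outdir))
  for (nm in names(x$manifest$stages)) {
    cat(sprintf("  %s: %d output file(s)\n", nm,
                length(x$manifest$stages[[nm]]$files)))
  }
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected. CLI-style overrides can be layered with `overrides`.
#'
#' @param path YAML file.
#' @param overrides named list applied over the file's values.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  assert_that(length(bad) == 0,
              sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
              "msipk_config_error")
  args <- utils::modifyList(raw, overrides)
  do.call(pipeline_config, args)
}
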