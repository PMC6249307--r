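#' Omics matrix (features x samples with annotations)
#'
#' Container for TMT phosphopeptide reporter intensities/ratios or FPKM
#' transcript abundances. Sample annotations carry condition/dose, TMT run,
#' the physical tumor identity (replicate grouping), the normalization-channel
#' flag and, for TMT, the per-sample crude-analysis median used for loading
#' normalization.
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param samples tibble with one row per column of `values`; must contain
#'   `sample_id` matching `colnames(values)`; recognized columns:
#'   `condition`, `dose`, `run`, `tumor_id`, `is_normalization_channel`,
#'   `crude_median`.
#' @param type `"tmt"` or `"fpkm"`. FPKM values must be >= 0; a TMT matrix
#'   must have exactly one normalization channel per run.
#' @return An `omics_matrix` object.
#' @export
new_omics_matrix <- function(values, samples, type = c("tmt", "fpkm")) {
  type <- match.arg(type)
  assert_that(is.matrix(values) && !is.null(colnames(values)) &&
                !is.null(rownames(values)),
              "`values` must be a matrix with row and column names")
  samples <- tibble::as_tibble(samples)
  assert_that("sample_id" %in% names(samples) &&
                identical(samples$sample_id, colnames(values)),
              "`samples$sample_id` must match colnames(values) in order")
  if (type == "fpkm") {
    assert_that(all(values >= 0, na.rm = TRUE), "FPKM values must be >= 0")
  }
  if (type == "tmt" && "is_normalization_channel" %in% names(samples) &&
      "run" %in% names(samples)) {
    per_run <- tapply(samples$is_normalization_channel, samples$run, sum)
    assert_that(all(per_run == 1),
                "each TMT run must have exactly one normalization channel")
  }
  structure(list(values = values, samples = samples, type = type),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d features x %d samples\n",
              x$type, nrow(x$values), ncol(x$values)))
  if ("condition" %in% names(x$samples)) {
    cat(sprintf("  conditions: %s\n",
                paste(unique(x$samples$condition), collapse = ", ")))
  }
  invisible(x)
}

#' Tidy an omics matrix to long format
#' @param x an `omics_matrix`.
#' @param ... unused.
#' @return Tibble with columns `feature_id`, `sample_id`, `value` plus the
#'   sample annotations.
#' @export
tidy.omics_matrix <- function(x, ...) {
  long <- tibble::tibble(
    feature_id = rep(rownames(x$values), ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Generate synthetic phospho/transcript matrices with planted structure
#'
#' Emulates the study's multi-omic design: two TMT-10-plex style runs (E1,
#' E2), each carrying one tumor per treatment condition, with the
#' vehicle-treated tumor shared by both runs so it serves as normalization
#' channel and technical replicate. A dose-responsive phosphopeptide module
#' (monotone decreasing with dose, emulating target inhibition) is planted
#' among background features. The transcript matrix (one column per physical
#' tumor) carries two anti-correlated blocks — transcripts suppressed vs.
#' induced by treatment — plus unstructured genes.
#'
#' @param n_phospho number of phosphopeptide features (default 210, the
#'   number of unique phosphotyrosine peptides reported by the study; the
#'   Methods' alternative count of 212 is equally valid — the count is a
#'   parameter, not a constant).
#' @param n_transcript number of transcript features.
#' @param conditions treatment labels, low to high dose.
#' @param doses numeric dose per condition (mg/kg).
#' @param n_runs number of TMT runs (default 2).
#' @param phospho_module_size features in the dose-responsive module.
#' @param transcript_block_sizes integer(2): sizes of the suppressed and
#'   induced transcript blocks.
#' @param noise_cv lognormal measurement noise CV.
#' @param seed integer seed.
#' @return List with `phospho` (TMT [new_omics_matrix()], features x
#'   (conditions x runs)), `transcripts` (FPKM matrix, features x tumors),
#'   and `truth` (planted module/block membership, the exact per-condition
#'   fold-changes, and the reference tumor id for log-ratio normalization).
#' @export
#' @examples
#' om <- generate_omics(n_phospho = 50, n_transcript = 60, seed = 3)
#' dim(om$phospho$values)
generate_omics <- function(n_phospho = 210, n_transcript = 500,
                           conditions = c("vehicle", "5", "33", "100"),
                           doses = c(0, 5, 33, 100),
                           n_runs = 2,
                           phospho_module_size = 30,
                           transcript_block_sizes = c(60, 60),
                           noise_cv = 0.1,
                           seed = 1L) {
  assert_that(length(conditions) >= 2, "need at least 2 conditions")
  assert_that(length(doses) == length(conditions),
              "`doses` must match `conditions`")
  assert_that(n_phospho >= phospho_module_size,
              "`n_phospho` smaller than the planted module")
  assert_that(n_transcript >= sum(transcript_block_sizes),
              "`n_transcript` smaller than the planted blocks")
  assert_that(n_runs >= 1, "`n_runs` must be >= 1")

  nc <- length(conditions)
  with_seed(seed, {
    runs <- paste0("E", seq_len(n_runs))
    layout <- expand.grid(condition = conditions, run = runs,
                          stringsAsFactors = FALSE)
    layout$dose <- doses[match(layout$condition, conditions)]
    # vehicle tumor shared across runs (normalization channel + tech rep)
    layout$tumor_id <- ifelse(layout$condition == conditions[1], "veh_ref",
                              paste0("t_", layout$condition, "_", layout$run))
    layout$is_normalization_channel <- layout$condition == conditions[1]
    layout$sample_id <- paste(layout$condition, layout$run, sep = "_")

    # planted monotone-decreasing dose response for the phospho module
    mod_profile <- seq(1, 0.25, length.out = nc)
    module_idx <- seq_len(phospho_module_size)
    effects <- matrix(1, n_phospho, nc,
                      dimnames = list(NULL, conditions))
    effects[module_idx, ] <- matrix(mod_profile, phospho_module_size, nc,
                                    byrow = TRUE)

    base <- stats::rlnorm(n_phospho, log(1000), 0.6)
    tumors <- unique(layout$tumor_id)
    bio <- stats::setNames(stats::rlnorm(length(tumors), 0, 0.15), tumors)
    run_factor <- stats::setNames(stats::rlnorm(n_runs, 0, 0.1), runs)
    loading <- stats::setNames(stats::runif(nrow(layout), 0.6, 1.6),
                               layout$sample_id)
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0

    pvals <- matrix(0, n_phospho, nrow(layout),
                    dimnames = list(sprintf("pY_%03d", seq_len(n_phospho)),
                                    layout$sample_id))
    for (j in seq_len(nrow(layout))) {
      mu <- base * effects[, layout$condition[j]] *
        bio[[layout$tumor_id[j]]] * run_factor[[layout$run[j]]] *
        loading[[layout$sample_id[j]]]
      noise <- if (sdlog > 0) {
        stats::rlnorm(n_phospho, -sdlog^2 / 2, sdlog)
      } else 1
      pvals[, j] <- mu * noise
    }
    samples <- tibble::as_tibble(layout[, c("sample_id", "condition", "dose",
                                            "run", "tumor_id",
                                            "is_normalization_channel")])
    samples$crude_median <- unname(loading[samples$sample_id])
    phospho <- new_omics_matrix(pvals, samples, type = "tmt")

    # transcripts: one column per physical tumor
    down_idx <- seq_len(transcript_block_sizes[1])
    up_idx <- transcript_block_sizes[1] + seq_len(transcript_block_sizes[2])
    down_profile <- seq(1, 0.3, length.out = nc)
    up_profile <- seq(1, 3.2, length.out = nc)
    t_effects <- matrix(1, n_transcript, nc, dimnames = list(NULL, conditions))
    t_effects[down_idx, ] <- matrix(down_profile, length(down_idx), nc,
                                    byrow = TRUE)
    t_effects[up_idx, ] <- matrix(up_profile, length(up_idx), nc, byrow = TRUE)

    t_base <- stats::rlnorm(n_transcript, log(20), 1)
    tumor_tbl <- unique(layout[, c("tumor_id", "condition", "dose")])
    tvals <- matrix(0, n_transcript, nrow(tumor_tbl),
                    dimnames = list(sprintf("tx_%04d", seq_len(n_transcript)),
                                    tumor_tbl$tumor_id))
    for (j in seq_len(nrow(tumor_tbl))) {
      mu <- t_base * t_effects[, tumor_tbl$condition[j]] *
        bio[[tumor_tbl$tumor_id[j]]]
      noise <- if (sdlog > 0) {
        stats::rlnorm(n_transcript, -sdlog^2 / 2, sdlog)
      } else 1
      tvals[, j] <- mu * noise
    }
    # a few true zeros among unstructured genes, as in real FPKM tables
    bg_idx <- setdiff(seq_len(n_transcript), c(down_idx, up_idx))
    if (length(bg_idx) > 4) {
      zero_idx <- sample(bg_idx, max(1, round(0.02 * length(bg_idx))))
      tvals[zero_idx, sample(ncol(tvals), 1)] <- 0
    }
    t_samples <- tibble::tibble(
      sample_id = tumor_tbl$tumor_id,
      condition = tumor_tbl$condition,
      dose = tumor_tbl$dose,
      tumor_id = tumor_tbl$tumor_id
    )
    transcripts <- new_omics_matrix(tvals, t_samples, type = "fpkm")

    truth <- list(
      phospho_module = rownames(pvals)[module_idx],
      phospho_effects = effects[module_idx, , drop = FALSE],
      transcript_blocks = list(down = rownames(tvals)[down_idx],
                               up = rownames(tvals)[up_idx]),
      transcript_effects = list(down = down_profile, up = up_profile),
      reference_sample = "veh_ref",
      conditions = conditions,
      doses = doses
    )
    list(phospho = phospho, transcripts = transcripts, truth = truth)
  })
}

#' Write / read an omics matrix as TSV
#'
#' Features x samples, with annotation header rows (`#condition`, `#run`,
#' etc.) preceding the data; first data column is `feature_id`.
#'
#' @param x an `omics_matrix`.
#' @param path TSV path.
#' @param type matrix type for reading.
#' @return `write_omics_tsv`: invisibly `path`; `read_omics_tsv`: an
#'   `omics_matrix`.
#' @export
write_omics_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  ann_cols <- setdiff(names(x$samples), "sample_id")
  for (a in ann_cols) {
    writeLines(paste(c(paste0("#", a), as.character(x$samples[[a]])),
                     collapse = "\t"), con)
  }
  writeLines(paste(c("feature_id", colnames(x$values)), collapse = "\t"), con)
  utils::write.table(x$values, con, sep = "\t", col.names = FALSE,
                     row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_omics_tsv
#' @export
read_omics_tsv <- function(path, type = c("tmt", "fpkm")) {
  type <- match.arg(type)
  lines <- readLines(path)
  ann_lines <- grep("^#", lines)
  header_i <- if (length(ann_lines)) max(ann_lines) + 1 else 1
  header <- strsplit(lines[header_i], "\t")[[1]]
  sample_ids <- header[-1]
  samples <- tibble::tibble(sample_id = sample_ids)
  for (i in ann_lines) {
    parts <- strsplit(lines[i], "\t")[[1]]
    nm <- sub("^#", "", parts[1])
    vals <- parts[-1]
    samples[[nm]] <- utils::type.convert(vals, as.is = TRUE)
  }
  dat <- utils::read.table(text = lines[-seq_len(header_i)], sep = "\t",
                           row.names = 1)
  m <- as.matrix(dat)
  colnames(m) <- sample_ids
  new_omics_matrix(m, samples, type = type)
}
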