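#' Calibration series
#'
#' A tissue-mimetic dilution series: one mean MSI intensity per known spiked
#' concentration. The study's mimetic model used 7 homogenate levels at
#' 50000, 10000, 7500, 5000, 2500, 1000 and 500 ng/g.
#'
#' @param nominal_conc spiked concentrations, ng/g (distinct, positive,
#'   length >= 3).
#' @param mean_intensity mean measured intensity per level (same length).
#' @return A `calibration_series` tibble with columns `nominal_conc`,
#'   `mean_intensity`. Fitting requires at least 3 levels
#'   ([fit_calibration()] enforces this); shorter series are representable
#'   for bookkeeping.
#' @export
calibration_series <- function(nominal_conc, mean_intensity) {
  assert_that(length(nominal_conc) == length(mean_intensity),
              "concentration and intensity vectors must match in length")
  assert_that(length(nominal_conc) >= 1,
              "a calibration series needs at least one level")
  assert_that(all(nominal_conc > 0), "concentrations must be positive")
  assert_that(!anyDuplicated(nominal_conc), "concentrations must be distinct")
  out <- tibble::tibble(nominal_conc = as.numeric(nominal_conc),
                        mean_intensity = as.numeric(mean_intensity))
  class(out) <- c("calibration_series", class(out))
  out
}

#' Default mimetic calibration levels (ng/g)
#'
#' The 7-level spiked homogenate design used by the study.
#' @return Numeric vector of 7 concentrations, ng/g.
#' @export
mimetic_levels <- function() {
  c(50000, 10000, 7500, 5000, 2500, 1000, 500)
}

#' Generate a synthetic spiked calibration series
#'
#' Simulates the tissue-mimetic model readout: per-level mean intensity
#' `slope * conc + intercept`, with optional multiplicative lognormal noise
#' of coefficient of variation `noise_cv`.
#'
#' @param levels spiked concentrations, ng/g (default: the 7-level design).
#' @param slope,intercept true linear map from ng/g to intensity.
#' @param noise_cv multiplicative noise CV (0 = exact line).
#' @param seed integer seed.
#' @return A [calibration_series()].
#' @export
#' @examples
#' generate_calibration_series(noise_cv = 0)
generate_calibration_series <- function(levels = mimetic_levels(),
                                        slope = 2, intercept = 0,
                                        noise_cv = 0, seed = 1L) {
  assert_that(length(levels) >= 1, "`levels` must be non-empty")
  assert_that(all(levels > 0), "`levels` must be positive")
  assert_that(!anyDuplicated(levels), "`levels` must be distinct")
  assert_that(noise_cv >= 0, "`noise_cv` must be >= 0")
  inten <- slope * levels + intercept
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    inten <- with_seed(seed, {
      inten * stats::rlnorm(length(inten), meanlog = -sdlog^2 / 2,
                            sdlog = sdlog)
    })
  }
  calibration_series(levels, inten)
}

#' Fit a linear calibration model
#'
#' Ordinary least squares of `mean_intensity` on `nominal_conc`
#' (`intensity = slope * conc + intercept`). The MSI curve is unweighted by
#' default; `weighting = "1/Y2"` applies the 1/Y^2 weighting used by the
#' reference LC-MS/MS assay.
#'
#' @param series a [calibration_series()].
#' @param weighting `"none"` (default) or `"1/Y2"`.
#' @return A `calibration_model`: slope, intercept (intensity per ng/g),
#'   `r_squared`, and `valid_range` (the fitted concentration span, ng/g).
#' @export
#' @examples
#' fit_calibration(generate_calibration_series(noise_cv = 0))
fit_calibration <- function(series, weighting = c("none", "1/Y2")) {
  weighting <- match.arg(weighting)
  assert_that(inherits(series, "calibration_series") ||
                (is.data.frame(series) &&
                   all(c("nominal_conc", "mean_intensity") %in% names(series))),
              "`series` must be a calibration_series")
  assert_that(nrow(series) >= 3, "need at least 3 calibration points")
  x <- series$nominal_conc
  y <- series$mean_intensity
  if (stats::sd(x) == 0) {
    abort_msipk("calibration concentrations are all equal (rank-deficient fit)",
                "msipk_fit_error")
  }
  w <- if (weighting == "1/Y2") 1 / pmax(y, .Machine$double.eps)^2 else NULL
  fit <- stats::lm(y ~ x, weights = w)
  # r^2 from the (weighted) residuals directly; summary.lm warns on an
  # exact line, which is a legitimate case for noiseless series
  wts <- w %||% rep(1, length(y))
  ybar <- sum(wts * y) / sum(wts)
  ss_tot <- sum(wts * (y - ybar)^2)
  ss_res <- sum(wts * stats::residuals(fit)^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    valid_range = range(x),
    weighting = weighting,
    n_points = length(x),
    fit = fit
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> intensity = %.6g * conc + %.6g (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  valid range: %g - %g ng/g (%d points, weighting %s)\n",
              x$valid_range[1], x$valid_range[2], x$n_points, x$weighting))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.calibration_model <- function(x, ...) {
  se <- suppressWarnings(summary(x$fit)$coefficients[, "Std. Error"])
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(se)
  )
}

#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    slope = x$slope,
    intercept = x$intercept,
    n = x$n_points,
    conc_min = x$valid_range[1],
    conc_max = x$valid_range[2]
  )
}

#' Convert an ion image to an absolute concentration map
#'
#' Inverts the calibration line per pixel: `conc = (intensity - intercept) /
#' slope`. Back-calculated negative concentrations are clipped to zero and
#' counted; values outside the calibration range are counted but retained.
#'
#' @param image an [ion_image][new_ion_image].
#' @param model a [fit_calibration()] model with positive slope.
#' @return A `concentration_map`: ng/g values (`NA` off tissue), with
#'   `n_clipped` and `n_out_of_range` counters and references to the source
#'   image window and model.
#' @export
apply_calibration <- function(image, model) {
  assert_that(inherits(image, "ion_image"), "`image` must be an ion_image")
  assert_that(inherits(model, "calibration_model"),
              "`model` must come from fit_calibration()")
  if (model$slope <= 0) {
    abort_msipk("calibration slope must be positive to invert", "msipk_fit_error")
  }
  conc <- (image$values - model$intercept) / model$slope
  neg <- !is.na(conc) & conc < 0
  conc[neg] <- 0
  oor <- !is.na(conc) &
    (conc < model$valid_range[1] | conc > model$valid_range[2])
  structure(list(
    values = conc,
    n_clipped = sum(neg),
    n_out_of_range = sum(oor),
    target_mz = image$target_mz,
    tolerance = image$tolerance,
    pixel_size = image$pixel_size,
    section_index = image$section_index,
    model = model[c("slope", "intercept", "r_squared", "valid_range")]
  ), class = "concentration_map")
}

#' @export
print.concentration_map <- function(x, ...) {
  cat(sprintf("<concentration_map> m/z %.4f, %d x %d px (%d present), ng/g\n",
              x$target_mz, nrow(x$values), ncol(x$values),
              sum(!is.na(x$values))))
  cat(sprintf("  clipped to 0: %d px; outside calibration range: %d px\n",
              x$n_clipped, x$n_out_of_range))
  invisible(x)
}

#' Write / read a calibration series as CSV
#'
#' Columns `nominal_ng_per_g`, `mean_intensity`.
#' @param series a [calibration_series()].
#' @param path CSV path.
#' @return `write_calibration_csv`: invisibly `path`;
#'   `read_calibration_csv`: a [calibration_series()].
#' @export
write_calibration_csv <- function(series, path) {
  utils::write.csv(
    data.frame(nominal_ng_per_g = series$nominal_conc,
               mean_intensity = series$mean_intensity),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  assert_that(all(c("nominal_ng_per_g", "mean_intensity") %in% names(df)),
              "CSV must have columns nominal_ng_per_g, mean_intensity",
              "msipk_format_error")
  calibration_series(df$nominal_ng_per_g, df$mean_intensity)
}
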