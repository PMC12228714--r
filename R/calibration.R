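#' Mean fluorescent intensity over a region
#'
#' The fluorescent intensity (FI) of a region is the arithmetic mean of one
#' colour channel over the pixels selected by the ROI mask, on the native
#' 8-bit scale `[0, 255]`.
#'
#' @param img an [rgb_image()].
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param roi logical matrix matching the image size with at least one
#'   `TRUE` pixel (see [load_roi_mask()], [apply_brightness_threshold()]).
#' @return mean intensity, a number in `[0, 255]`.
#' @export
mean_roi_intensity <- function(img, channel, roi) {
  stopifnot(inherits(img, "rgb_image"))
  if (!identical(dim(roi), dim(img)[1:2])) {
    abort("ROI dimensions do not match the image.", class = "wf_dimension_error")
  }
  if (!any(roi)) abort("ROI selects no pixels.", class = "wf_empty_roi")
  ch <- unclass(img)[, , channel_index(channel)]
  mean(ch[roi])
}

#' Fluorescence-to-pH calibration model
#'
#' The pH readout is a straight line `FI = a * pH + b` between the pH of a
#' buffered dye sample and the mean fluorescent intensity of its image in
#' one colour channel (the red channel for the SNARF dye, whose 640 nm
#' emission grows with pH). `fit_calibration()` fits the line by ordinary
#' least squares; the fit quality is the squared Pearson correlation of the
#' calibration points.
#'
#' The calibration data cover the linear response range pH 5-9; estimates
#' outside that range are returned as-is but flagged with a warning, since
#' the dye response flattens outside it.
#'
#' @param points a data frame with numeric columns `ph` and `fi` (mean
#'   intensity), one row per buffer; at least two distinct pH values.
#' @param channel colour channel the intensities came from.
#' @return an object of class `calibration_model` with fields `slope`
#'   (FI units per pH unit), `intercept` (FI units), `r_squared`, `channel`
#'   and `fit_points`.
#' @examples
#' pts <- data.frame(ph = 5:9, fi = 28.8 * (5:9) - 120.05)
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, channel = "R") {
  points <- tibble::as_tibble(points)
  if (!all(c("ph", "fi") %in% names(points))) {
    abort("`points` needs columns `ph` and `fi`.")
  }
  if (nrow(points) < 2L || length(unique(points$ph)) < 2L) {
    abort("calibration needs at least two points with distinct pH.",
          class = "wf_degenerate_design")
  }
  fit <- lm(fi ~ ph, data = points)
  r2 <- if (stats::sd(points$fi) == 0) 1 else cor(points$ph, points$fi)^2
  new_calibration_model(
    slope = unname(coef(fit)[["ph"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r_squared = r2,
    channel = channel,
    fit_points = points
  )
}

new_calibration_model <- function(slope, intercept, r_squared, channel,
                                  fit_points = NULL) {
  if (slope == 0) abort("calibration slope must be non-zero.")
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         channel = channel, fit_points = fit_points),
    class = "calibration_model"
  )
}

#' Packaged default pH calibration
#'
#' The calibration shipped with the package: `FI = 28.8 * pH - 120.05`
#' (red channel, R^2 = 0.957), applicable over the linear range pH 5-9.
#' Override it by fitting your own points with [fit_calibration()].
#'
#' @return a `calibration_model`.
#' @export
default_calibration <- function() {
  cal <- wf_defaults()$calibration
  new_calibration_model(cal$slope, cal$intercept, cal$r_squared, cal$channel)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> FI = %.4g * pH + %.6g  (channel %s, R^2 = %.3f)\n",
              x$slope, x$intercept, x$channel, x$r_squared))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x a `calibration_model`.
#' @param ... unused.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "ph"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname fit_calibration
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared,
                 nobs = if (is.null(x$fit_points)) NA_integer_ else nrow(x$fit_points))
}

#' Convert between pH and fluorescent intensity
#'
#' `predict_fi()` evaluates the calibration line forward (pH to expected
#' intensity, unclamped); `estimate_ph()` inverts it (intensity to pH).
#' Both are exact inverses of one another.
#'
#' @param model a `calibration_model`.
#' @param ph,fi numeric vectors.
#' @return numeric vector of intensities (`predict_fi`) or pH units
#'   (`estimate_ph`).
#' @export
predict_fi <- function(model, ph) {
  stopifnot(inherits(model, "calibration_model"))
  model$slope * ph + model$intercept
}

#' @rdname predict_fi
#' @param linear_range pH interval of validated linearity; estimates outside
#'   it trigger a warning (but are still returned).
#' @export
estimate_ph <- function(model, fi, linear_range = c(5, 9)) {
  stopifnot(inherits(model, "calibration_model"))
  ph <- (fi - model$intercept) / model$slope
  out_of_range <- !is.na(ph) & (ph < linear_range[1] | ph > linear_range[2])
  if (any(out_of_range)) {
    warn(sprintf("%d pH estimate(s) fall outside the calibrated linear range [%g, %g].",
                 sum(out_of_range), linear_range[1], linear_range[2]))
  }
  ph
}

#' Percent error of a pH estimate
#'
#' `100 * |actual - estimated| / actual`, the accuracy metric used to
#' compare estimated against bench-meter pH values.
#'
#' @param actual true pH (must be positive).
#' @param estimated estimated pH.
#' @return percent error, non-negative.
#' @export
percent_error <- function(actual, estimated) {
  if (any(actual <= 0)) abort("`actual` must be positive.", class = "wf_domain_error")
  100 * abs(actual - estimated) / actual
}
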