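#' Normalized full-wound NO intensity
#'
#' Mean green-channel intensity over the wound region, divided by 255 so
#' that the darkest possible region maps to 0 and a saturated one to 1.
#' The green channel carries the DAF-FM nitric-oxide signal.
#'
#' @param img an [rgb_image()].
#' @param roi logical wound mask (manual crop or brightness threshold).
#' @return normalized intensity in `[0, 1]`.
#' @export
extract_full_wound_fi <- function(img, roi) {
  mean_roi_intensity(img, "G", roi) / 255
}

#' Features of the highest-NO cluster
#'
#' From a green-channel segmentation (see [segment_wound()] with
#' `channels = "G"`, `order_channel = "G"`), selects the non-background
#' cluster with the highest mean green intensity -- the region of strongest
#' NO expression -- and returns its normalized mean intensity and its wound
#' area percentage, the fraction of retained (above-threshold) pixels that
#' belong to it.
#'
#' @param cmap a `cluster_map`.
#' @return a tibble with columns `cluster` (selected index), `cluster_fi`
#'   (mean green / 255) and `cluster_area` (fraction in `[0, 1]`).
#' @export
extract_highest_no_cluster <- function(cmap) {
  stopifnot(inherits(cmap, "cluster_map"))
  st <- dplyr::filter(cmap$stats, .data$cluster > 0)
  if (nrow(st) == 0L) abort("no non-background cluster present.", class = "wf_empty_roi")
  top <- st[which.max(st$mean_G), ]
  tibble::tibble(cluster = top$cluster,
                 cluster_fi = top$mean_G / 255,
                 cluster_area = top$n_pixels / sum(st$n_pixels))
}

#' Normalize wound samples for regression
#'
#' All regression variables live on `[0, 1]`: the day post-wounding is
#' divided by 6 (day 3 maps to 0.5, day 6 to 1), percent re-epithelialization
#' by 100, fluorescent intensities by 255 (done at extraction), and the
#' wound-area fraction is already fractional.
#'
#' @param data a data frame with numeric columns `day` (>= 0) and
#'   `re_epi_pct` (in `[0, 100]`); other columns pass through.
#' @return the input tibble with `day_norm` and `re_epi_norm` columns added.
#' @export
normalize_samples <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("day", "re_epi_pct") %in% names(data))) {
    abort("`data` needs columns `day` and `re_epi_pct`.")
  }
  if (any(data$day < 0)) abort("`day` must be >= 0.", class = "wf_domain_error")
  if (any(data$re_epi_pct < 0 | data$re_epi_pct > 100)) {
    abort("`re_epi_pct` must lie in [0, 100].", class = "wf_domain_error")
  }
  dplyr::mutate(data, day_norm = .data$day / 6,
                re_epi_norm = .data$re_epi_pct / 100)
}

#' Multi-output ridge regression on one wound feature
#'
#' Fits both normalized outcomes (healing day and percent
#' re-epithelialization) on a single normalized fluorescence feature with a
#' shared ridge penalty `alpha` and an unpenalized intercept, in closed
#' form: centre the feature and the outcomes, solve
#' `(Xc'Xc + alpha I) b = Xc'Yc`, and recover intercepts from the means.
#' With `alpha = 0` this is exactly ordinary least squares.
#'
#' @param data a data frame containing `feature` and the outcome columns.
#' @param feature name of the feature column (`"full_fi"`, `"cluster_fi"`
#'   or `"cluster_area"` in the standard pipeline).
#' @param alpha ridge penalty, `>= 0`.
#' @param outcomes outcome column names (normalized day and re-epi).
#' @return an object of class `ridge_model` with fields `alpha`, `feature`,
#'   `outcomes`, `coefficients` (one slope per outcome), `intercepts`, and
#'   the training `data`.
#' @examples
#' cohort <- generate_feature_cohort(cohort_config(n = 8, noise_sd = 0))
#' fit_multioutput_ridge(cohort, "full_fi")
#' @export
fit_multioutput_ridge <- function(data, feature, alpha = 0,
                                  outcomes = c("day_norm", "re_epi_norm")) {
  data <- tibble::as_tibble(data)
  if (!feature %in% names(data)) abort(sprintf("column `%s` not found.", feature))
  if (!all(outcomes %in% names(data))) abort("outcome columns not found.")
  if (alpha < 0) abort("`alpha` must be >= 0.", class = "wf_domain_error")
  x <- data[[feature]]
  Y <- as.matrix(data[outcomes])
  n <- length(x)
  if (n < 2L) abort("need at least two samples.", class = "wf_degenerate_design")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0 && alpha == 0) {
    abort("feature is constant: singular design with alpha = 0.",
          class = "wf_singular_design")
  }
  Yc <- sweep(Y, 2, colMeans(Y))
  slopes <- drop(crossprod(xc, Yc)) / (sxx + alpha)
  intercepts <- colMeans(Y) - slopes * mean(x)
  structure(
    list(alpha = alpha, feature = feature, outcomes = outcomes,
         coefficients = setNames(as.numeric(slopes), outcomes),
         intercepts = setNames(as.numeric(intercepts), outcomes),
         data = data),
    class = "ridge_model"
  )
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %s -> (%s), alpha = %g\n", x$feature,
              paste(x$outcomes, collapse = ", "), x$alpha))
  for (o in x$outcomes) {
    cat(sprintf("  %s = %.4g * %s + %.4g\n", o, x$coefficients[[o]],
                x$feature, x$intercepts[[o]]))
  }
  invisible(x)
}

#' @rdname fit_multioutput_ridge
#' @param x a `ridge_model`.
#' @param ... unused.
#' @method tidy ridge_model
#' @export
tidy.ridge_model <- function(x, ...) {
  tibble::tibble(
    outcome = rep(x$outcomes, each = 2L),
    term = rep(c("(Intercept)", x$feature), times = length(x$outcomes)),
    estimate = as.numeric(rbind(x$intercepts, x$coefficients))
  )
}

#' @rdname fit_multioutput_ridge
#' @method glance ridge_model
#' @export
glance.ridge_model <- function(x, ...) {
  m <- mse(as.matrix(x$data[x$outcomes]), as.matrix(predict(x, x$data)))
  tibble::tibble(alpha = x$alpha, nobs = nrow(x$data),
                 mse_day_norm = m[[1]], mse_re_epi_norm = m[[2]])
}

#' @rdname fit_multioutput_ridge
#' @param object a `ridge_model`.
#' @param newdata data frame containing the feature column.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  x <- newdata[[object$feature]]
  out <- lapply(object$outcomes, function(o) {
    object$coefficients[[o]] * x + object$intercepts[[o]]
  })
  names(out) <- object$outcomes
  tibble::as_tibble(out)
}

#' Mean squared error per outcome
#'
#' `mean((Y - Yhat)^2)` column by column.
#'
#' @param y,yhat numeric vectors or matrices of equal shape.
#' @return named numeric vector of per-column MSEs.
#' @export
mse <- function(y, yhat) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  if (!all(dim(y) == dim(yhat))) abort("`y` and `yhat` must have equal shape.")
  colMeans((y - yhat)^2)
}

#' Leave-one-out cross-validation of the ridge fit
#'
#' Fits the model n times, each time holding out one sample, and scores the
#' held-out predictions. With the study's 8 wound samples this is the
#' "8-fold" scheme: one sample per fold, fold order = sample order. Errors
#' are reported both on the normalized scale and de-normalized (day
#' residuals multiplied by 6, percent re-epithelialization residuals by
#' 100) so the day MSE is in days squared and the re-epi MSE in percentage
#' points squared. Folds whose training design is singular are dropped with
#' a warning.
#'
#' @inheritParams fit_multioutput_ridge
#' @return an object of class `cv_result`: list with `folds` (per-fold
#'   tibble of held-out squared errors) and `summary` (one-row tibble of
#'   normalized and de-normalized MSEs per outcome).
#' @export
loo_cv <- function(data, feature, alpha = 0,
                   outcomes = c("day_norm", "re_epi_norm")) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n < 3L) abort("need at least three samples for cross-validation.")
  scale_out <- setNames(c(6, 100), c("day_norm", "re_epi_norm"))[outcomes]
  folds <- purrr::map(seq_len(n), function(i) {
    fit <- tryCatch(
      fit_multioutput_ridge(data[-i, ], feature, alpha, outcomes),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    pred <- predict(fit, data[i, ])
    resid <- as.numeric(data[i, outcomes]) - as.numeric(pred)
    tibble::tibble(fold = i,
                   outcome = outcomes,
                   sq_error_norm = resid^2,
                   sq_error = (resid * scale_out)^2)
  })
  failed <- vapply(folds, is.null, logical(1))
  if (any(failed)) {
    warn(sprintf("%d fold(s) had a singular training design and were dropped.",
                 sum(failed)))
  }
  folds <- dplyr::bind_rows(folds)
  summ <- folds |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(mse_norm = mean(.data$sq_error_norm),
                     mse = mean(.data$sq_error), .groups = "drop")
  structure(list(folds = folds, summary = summ,
                 n_folds = n - sum(failed), feature = feature, alpha = alpha),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> leave-one-out over %d folds (%s, alpha = %g)\n",
              x$n_folds, x$feature, x$alpha))
  print(x$summary)
  invisible(x)
}

#' @rdname loo_cv
#' @param x a `cv_result`.
#' @param ... unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname loo_cv
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "outcome",
                             values_from = c("mse_norm", "mse"))
  dplyr::bind_cols(tibble::tibble(n_folds = x$n_folds, alpha = x$alpha), wide)
}
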