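stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "wf_pipeline_error", parent = e)
  })
}

#' End-to-end pH pipeline
#'
#' Runs the full pH mapping sequence for a set of wound images: focus-frame
#' selection, brightness threshold, (R, G, B, x, y) feature assembly,
#' k-means segmentation, canonical relabelling with calibrated per-cluster
#' pH, the cross-day pH series, the per-cluster `|delta pH|` table and
#' summary, and the centre-versus-periphery variance test.
#'
#' @param images a data frame with columns `wound_id`, `day` and `image`, a
#'   list-column of [rgb_image()] or [zstack()] objects.
#' @param calibration a [fit_calibration()] model (required).
#' @param k,threshold,seed,n_init,scaling,background segmentation
#'   parameters, see [segment_wound()].
#' @param frame_strategy z-stack frame selection, see [select_focused()].
#' @param reference peripheral-variance combination, see
#'   [delta_variance_test()].
#' @param out_dir optional directory; when given, the series, delta,
#'   summary and test tables are written as CSV, per-image label maps as
#'   PNG, and a `run_info.csv` records the parameters and config hash.
#' @return a list of class `ph_pipeline_result` with `maps` (input tibble
#'   plus a `map` column), `series`, `delta`, `summary`, `test`.
#' @export
run_ph_pipeline <- function(images, calibration = default_calibration(),
                            k = 5, threshold = 10, seed = 0, n_init = 10,
                            scaling = "minmax",
                            background = "exclude",
                            frame_strategy = "max-laplacian",
                            reference = "mean", out_dir = NULL) {
  images <- tibble::as_tibble(images)
  stage("validate-inputs", {
    if (!all(c("wound_id", "day", "image") %in% names(images))) {
      abort("`images` needs columns `wound_id`, `day`, `image`.")
    }
  })
  stage("calibration", {
    if (!inherits(calibration, "calibration_model")) {
      abort("a calibration_model is required to report cluster pH.")
    }
  })
  maps <- stage("segmentation", {
    dplyr::mutate(images, map = purrr::map(.data$image, function(im) {
      if (inherits(im, "zstack")) im <- select_focused(im, frame_strategy)
      segment_wound(im, k = k, threshold = threshold,
                    channels = c("R", "G", "B"), scaling = scaling,
                    seed = seed, n_init = n_init, background = background,
                    order_channel = calibration$channel,
                    calibration = calibration)
    }))
  })
  series <- stage("ph-series", build_ph_series(maps))
  delta <- stage("delta-ph", compute_delta_ph(series))
  summary <- stage("delta-summary", summarize_delta(delta))
  test <- stage("variance-test",
                delta_variance_test(delta, center_cluster = k - 1L,
                                    reference = reference))
  result <- structure(
    list(maps = maps, series = series, delta = delta, summary = summary,
         test = test,
         params = list(k = k, threshold = threshold, seed = seed,
                       n_init = n_init, scaling = scaling,
                       background = background, reference = reference)),
    class = "ph_pipeline_result"
  )
  if (!is.null(out_dir)) stage("write-artifacts", write_ph_artifacts(result, out_dir))
  result
}

write_ph_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$series, file.path(out_dir, "ph_series.csv"))
  readr::write_csv(result$delta, file.path(out_dir, "delta_ph.csv"))
  readr::write_csv(result$summary, file.path(out_dir, "delta_summary.csv"))
  readr::write_csv(tidy(result$test), file.path(out_dir, "variance_test.csv"))
  purrr::pwalk(result$maps[c("wound_id", "day", "map")], function(wound_id, day, map) {
    png::writePNG(map$labels / 255,
                  file.path(out_dir, sprintf("labels_%s_day%02d.png", wound_id, day)))
  })
  info <- tibble::as_tibble(result$params)
  info$config_hash <- config_hash(result$params)
  readr::write_csv(info, file.path(out_dir, "run_info.csv"))
  invisible(out_dir)
}

config_hash <- function(params) {
  s <- jsonlite::toJSON(params, auto_unbox = TRUE)
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' End-to-end NO prediction pipeline
#'
#' Extracts the chosen nitric-oxide feature for every wound sample,
#' normalizes all variables to `[0, 1]`, fits the multi-output ridge
#' regression of healing day and percent re-epithelialization on that
#' feature, and evaluates in-sample and leave-one-out MSE.
#'
#' Samples may carry images (list-column `image`, with optional list-column
#' `roi` of logical masks for the manual full-wound crop) or a precomputed
#' feature column named after `model`.
#'
#' @param samples a data frame with columns `wound_id`, `day`,
#'   `re_epi_pct`, and either images or the feature column.
#' @param model which feature drives the regression: `"full_fi"` (mean
#'   green over the wound crop), `"cluster_fi"` or `"cluster_area"` (from
#'   the highest-NO cluster of a green-channel segmentation).
#' @param alpha ridge penalty (0 = ordinary least squares).
#' @param k,threshold,seed,n_init segmentation parameters for the cluster
#'   features.
#' @param out_dir optional artifact directory (feature CSV, coefficients
#'   CSV, per-fold CV CSV, run info).
#' @return a list of class `no_pipeline_result` with `features` (the
#'   normalized sample table), `model` (a `ridge_model`), `mse` (in-sample,
#'   normalized and de-normalized) and `cv` (a `cv_result`).
#' @export
run_no_pipeline <- function(samples,
                            model = c("full_fi", "cluster_fi", "cluster_area"),
                            alpha = 0, k = 5, threshold = 10, seed = 0,
                            n_init = 10, out_dir = NULL) {
  model <- match.arg(model)
  samples <- tibble::as_tibble(samples)
  stage("validate-inputs", {
    if (!all(c("wound_id", "day", "re_epi_pct") %in% names(samples))) {
      abort("`samples` needs columns `wound_id`, `day`, `re_epi_pct`.")
    }
    if (nrow(samples) < 3L) abort("need at least three samples.")
  })
  features <- stage("feature-extraction", {
    if (model %in% names(samples)) {
      samples
    } else {
      if (!"image" %in% names(samples)) {
        abort(sprintf("supply images or a precomputed `%s` column.", model))
      }
      vals <- purrr::map2_dbl(
        samples$image,
        if ("roi" %in% names(samples)) samples$roi else vector("list", nrow(samples)),
        function(im, roi) {
          if (inherits(im, "zstack")) im <- select_focused(im)
          if (model == "full_fi") {
            roi <- roi %||% apply_brightness_threshold(im, threshold)
            extract_full_wound_fi(im, roi)
          } else {
            cm <- segment_wound(im, k = k, threshold = threshold,
                                channels = "G", seed = seed, n_init = n_init,
                                order_channel = "G")
            feats <- extract_highest_no_cluster(cm)
            feats[[if (model == "cluster_fi") "cluster_fi" else "cluster_area"]]
          }
        })
      samples[[model]] <- vals
      samples
    }
  })
  design <- stage("normalization", normalize_samples(features))
  fit <- stage("ridge-fit", fit_multioutput_ridge(design, model, alpha = alpha))
  pred <- predict(fit, design)
  resid <- as.matrix(design[fit$outcomes]) - as.matrix(pred)
  mse_tbl <- tibble::tibble(
    outcome = fit$outcomes,
    mse_norm = unname(colMeans(resid^2)),
    mse = unname(colMeans(sweep(resid, 2, c(6, 100), `*`)^2))
  )
  cv <- stage("cross-validation", loo_cv(design, model, alpha = alpha))
  result <- structure(
    list(features = design, model = fit, mse = mse_tbl, cv = cv,
         params = list(model = model, alpha = alpha, k = k,
                       threshold = threshold, seed = seed, n_init = n_init)),
    class = "no_pipeline_result"
  )
  if (!is.null(out_dir)) stage("write-artifacts", write_no_artifacts(result, out_dir))
  result
}

write_no_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- dplyr::select(result$features, -dplyr::any_of(c("image", "roi")))
  readr::write_csv(feats, file.path(out_dir, "features.csv"))
  readr::write_csv(tidy(result$model), file.path(out_dir, "coefficients.csv"))
  readr::write_csv(result$mse, file.path(out_dir, "mse.csv"))
  readr::write_csv(tidy(result$cv), file.path(out_dir, "cv_folds.csv"))
  info <- tibble::as_tibble(result$params)
  info$config_hash <- config_hash(result$params)
  readr::write_csv(info, file.path(out_dir, "run_info.csv"))
  invisible(out_dir)
}
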