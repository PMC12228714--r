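#' Plot a calibration fit
#'
#' Calibration points with the fitted fluorescence-versus-pH line.
#'
#' @param object a `calibration_model` with stored fit points.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot calibration_model
#' @export
autoplot.calibration_model <- function(object, ...) {
  if (is.null(object$fit_points)) {
    abort("this model carries no fit points to plot.")
  }
  ggplot2::ggplot(object$fit_points, ggplot2::aes(x = .data$ph, y = .data$fi)) +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(
      x = "pH", y = sprintf("fluorescent intensity (%s channel)", object$channel),
      title = sprintf("FI = %.3g pH %+.4g   (R² = %.3f)",
                      object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a segmented wound map
#'
#' Raster of the canonical cluster labels; clusters are filled by their
#' mean pH when the map is calibrated, otherwise by cluster index.
#' Background (label 0) is black.
#'
#' @param object a `cluster_map`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cluster_map
#' @export
autoplot.cluster_map <- function(object, ...) {
  lab <- object$labels
  df <- tibble::tibble(
    x = rep(0:(ncol(lab) - 1), each = nrow(lab)),
    y = rep(0:(nrow(lab) - 1), times = ncol(lab)),
    cluster = as.vector(lab)
  )
  if ("mean_ph" %in% names(object$stats)) {
    ph_of <- setNames(object$stats$mean_ph, object$stats$cluster)
    df$fill <- ifelse(df$cluster == 0, NA_real_, ph_of[as.character(df$cluster)])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$fill)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "mean pH", na.value = "black")
  } else {
    df$fill <- factor(df$cluster)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$fill)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_d(name = "cluster")
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (column)", y = "y (row)") +
    ggplot2::theme_minimal()
}

#' Plot the ridge regression relationships
#'
#' Scatter of the training samples against the feature, one panel per
#' outcome, with the fitted normalized linear relation.
#'
#' @param object a `ridge_model`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ridge_model
#' @export
autoplot.ridge_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data[c(object$feature, object$outcomes)],
                              dplyr::all_of(object$outcomes),
                              names_to = "outcome", values_to = "value")
  lines <- tibble::tibble(outcome = object$outcomes,
                          slope = as.numeric(object$coefficients),
                          intercept = as.numeric(object$intercepts))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[object$feature]], y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope, intercept = .data$intercept)) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(y = "normalized outcome") +
    ggplot2::theme_minimal()
}

#' Plot |delta pH| spread per cluster
#'
#' Boxplot of the day-to-day pH change magnitude by canonical cluster,
#' pooling wounds and transitions.
#'
#' @param delta a [compute_delta_ph()] tibble.
#' @return a ggplot.
#' @export
plot_delta_ph <- function(delta) {
  ggplot2::ggplot(tibble::as_tibble(delta),
                  ggplot2::aes(x = factor(.data$cluster), y = .data$delta_ph)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "cluster", y = "|ΔpH|") +
    ggplot2::theme_minimal()
}

#' Plot an inertia (elbow) curve
#'
#' @param curve an [inertia_curve()] tibble.
#' @return a ggplot.
#' @export
plot_inertia_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$inertia)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(x = "k", y = "within-cluster inertia") +
    ggplot2::theme_minimal()
}
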