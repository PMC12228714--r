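#' Tabulate per-cluster pH across wounds and days
#'
#' Collects the calibrated per-cluster statistics of a set of segmented
#' wound images into one long table of cluster mean pH and elements per
#' cluster, indexed by wound, day and canonical cluster.
#'
#' @param maps a data frame with columns `wound_id`, `day` (integer) and
#'   `map`, a list-column of [segment_wound()] results whose statistics
#'   carry a calibrated `mean_ph`.
#' @return a tibble (the pH series) with columns `wound_id`, `day`,
#'   `cluster`, `mean_ph`, `n_pixels`.
#' @export
build_ph_series <- function(maps) {
  maps <- tibble::as_tibble(maps)
  if (!all(c("wound_id", "day", "map") %in% names(maps))) {
    abort("`maps` needs columns `wound_id`, `day`, `map`.")
  }
  ok <- vapply(maps$map, function(m) {
    inherits(m, "cluster_map") && "mean_ph" %in% names(m$stats)
  }, logical(1))
  if (!all(ok)) {
    abort("every cluster map must carry calibrated mean pH (supply a calibration when segmenting).",
          class = "wf_missing_calibration")
  }
  maps |>
    dplyr::mutate(stats = purrr::map(.data$map, function(m) {
      dplyr::filter(m$stats, .data$cluster > 0)
    })) |>
    dplyr::select("wound_id", "day", "stats") |>
    tidyr::unnest("stats") |>
    dplyr::select("wound_id", "day", "cluster", "mean_ph", "n_pixels") |>
    dplyr::arrange(.data$wound_id, .data$day, .data$cluster)
}

#' Day-to-day magnitude of pH change per cluster
#'
#' For every wound and cluster, `|delta pH|` is the absolute difference of
#' the cluster's mean pH between consecutive imaging days. Day pairs with a
#' gap (missing day) are skipped with a warning, since the acquisition
#' protocol images daily.
#'
#' @param series a [build_ph_series()] tibble.
#' @return a tibble with columns `wound_id`, `day_from`, `day_to`,
#'   `cluster`, `delta_ph` (>= 0).
#' @export
compute_delta_ph <- function(series) {
  series <- dplyr::arrange(tibble::as_tibble(series),
                           .data$wound_id, .data$cluster, .data$day)
  out <- series |>
    dplyr::group_by(.data$wound_id, .data$cluster) |>
    dplyr::mutate(
      day_to = dplyr::lead(.data$day),
      ph_to = dplyr::lead(.data$mean_ph)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$day_to))
  gaps <- out$day_to - out$day > 1L
  if (any(gaps)) {
    warn(sprintf("skipping %d day transition(s) with gaps (non-consecutive days).",
                 sum(gaps)))
    out <- out[!gaps, ]
  }
  if (nrow(out) == 0L) abort("need at least two consecutive days per wound.")
  tibble::tibble(
    wound_id = out$wound_id,
    day_from = out$day,
    day_to = out$day_to,
    cluster = out$cluster,
    delta_ph = abs(out$ph_to - out$mean_ph)
  )
}

#' Per-cluster spread of the pH change magnitude
#'
#' Mean, standard deviation and variance (n - 1 denominator) of
#' `|delta pH|` per cluster, pooled over wounds and day transitions.
#'
#' @param table a [compute_delta_ph()] tibble.
#' @return a tibble with columns `cluster`, `n`, `mean`, `sd`, `variance`.
#' @export
summarize_delta <- function(table) {
  out <- tibble::as_tibble(table) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$delta_ph),
                     sd = stats::sd(.data$delta_ph),
                     variance = stats::var(.data$delta_ph),
                     .groups = "drop")
  if (any(out$n < 2L)) {
    abort("variance is undefined for clusters with a single |delta pH| value.",
          class = "wf_degenerate_design")
  }
  out
}

#' Upper-tail chi-squared probability
#'
#' Survival function of the chi-squared distribution, the one-sided p-value
#' of the variance test.
#'
#' @param x non-negative test statistic.
#' @param df degrees of freedom (>= 1).
#' @return `P(X > x)` for `X ~ chi-squared(df)`.
#' @export
chi2_sf <- function(x, df) {
  if (any(x < 0)) abort("`x` must be non-negative.", class = "wf_domain_error")
  if (any(df < 1)) abort("`df` must be >= 1.", class = "wf_domain_error")
  pchisq(x, df, lower.tail = FALSE)
}

#' One-sample chi-squared test for variance
#'
#' Tests whether the variance of a sample exceeds a reference variance
#' `sigma0_sq` using the statistic `chi2 = (n - 1) * s^2 / sigma0^2` with
#' `n - 1` degrees of freedom and an upper-tail (one-sided) p-value. Used to
#' ask whether the wound-centre cluster's `|delta pH|` spread exceeds that
#' of the peripheral clusters.
#'
#' @param values numeric sample (n >= 2).
#' @param sigma0_sq reference variance (> 0).
#' @return an object of class `variance_test` with fields `statistic`, `df`,
#'   `s_squared`, `sigma0_squared`, `p_value`, `n`.
#' @export
variance_test <- function(values, sigma0_sq) {
  if (length(values) < 2L) abort("need at least two values.", class = "wf_domain_error")
  if (sigma0_sq <= 0) abort("`sigma0_sq` must be positive.", class = "wf_domain_error")
  n <- length(values)
  s2 <- stats::var(values)
  chi2 <- (n - 1) * s2 / sigma0_sq
  structure(
    list(statistic = chi2, df = n - 1L, s_squared = s2,
         sigma0_squared = sigma0_sq, p_value = chi2_sf(chi2, n - 1L), n = n),
    class = "variance_test"
  )
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("Chi-squared variance test: chi2(%d) = %.4g, one-sided p = %.3f\n",
              x$df, x$statistic, x$p_value))
  cat(sprintf("  s^2 = %.4g vs sigma0^2 = %.4g (n = %d)\n",
              x$s_squared, x$sigma0_squared, x$n))
  invisible(x)
}

#' @rdname variance_test
#' @param x a `variance_test`.
#' @param ... unused.
#' @method tidy variance_test
#' @export
tidy.variance_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, s.squared = x$s_squared,
                 sigma0.squared = x$sigma0_squared, p.value = x$p_value,
                 n = x$n)
}

#' @rdname variance_test
#' @method glance variance_test
#' @export
glance.variance_test <- function(x, ...) tidy(x)

#' Centre-versus-periphery variance test of |delta pH|
#'
#' The headline spatial-stability comparison: is the `|delta pH|` variance
#' of the wound-centre cluster significantly greater than in the peripheral
#' clusters? The reference variance is built from the peripheral clusters'
#' sample variances either as their plain mean (`reference = "mean"`,
#' default) or as the df-weighted pooled variance (`reference = "pooled"`).
#'
#' @param table a [compute_delta_ph()] tibble.
#' @param center_cluster index of the centre cluster (the brightest /
#'   highest-pH canonical cluster; 4 in a k = 5 segmentation).
#' @param reference how to combine the peripheral variances.
#' @return a [variance_test()] result.
#' @export
delta_variance_test <- function(table, center_cluster = 4,
                                reference = c("mean", "pooled")) {
  reference <- match.arg(reference)
  table <- tibble::as_tibble(table)
  centre <- table$delta_ph[table$cluster == center_cluster]
  periph <- table[table$cluster != center_cluster, ]
  if (length(centre) < 2L || nrow(periph) < 2L) {
    abort("need at least two |delta pH| values in the centre and the periphery.",
          class = "wf_domain_error")
  }
  per <- periph |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(v = stats::var(.data$delta_ph), n = dplyr::n(),
                     .groups = "drop")
  sigma0 <- switch(reference,
    mean = mean(per$v),
    pooled = sum((per$n - 1) * per$v) / sum(per$n - 1)
  )
  variance_test(centre, sigma0)
}
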