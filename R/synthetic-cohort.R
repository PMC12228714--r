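#' Configuration for a synthetic wound-feature cohort
#'
#' Describes a cohort of wound-day observations obeying the packaged
#' normalized linear relations between one NO fluorescence feature and the
#' two outcomes (healing day and percent re-epithelialization). The feature
#' is drawn uniformly over `feature_range`; each normalized outcome is
#' `slope * feature + intercept` plus Gaussian noise, clipped to `[0, 1]`;
#' the de-normalized `day` and `re_epi_pct` columns are recovered through
#' the inverse normalization rules (`x 6` days, `x 100` percent).
#'
#' By default `feature_range` is computed from the coefficients as the
#' widest sub-interval of `[0, 1]` over which both noise-free outcomes stay
#' inside `[0, 1]`, so that a noise-free cohort satisfies the configured
#' relations exactly (no clipping).
#'
#' @param n number of samples (>= 2).
#' @param feature which feature the cohort is built on: `"full_fi"`,
#'   `"cluster_fi"` or `"cluster_area"`.
#' @param day_coef,re_epi_coef lists `list(slope =, intercept =)` for the
#'   normalized-day and normalized-re-epi relations; defaults are the
#'   packaged coefficients for `feature`.
#' @param feature_range length-2 numeric in `[0, 1]`, or `NULL` for the
#'   automatic range described above.
#' @param noise_sd Gaussian noise sd on the normalized outcomes (>= 0).
#' @param seed RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n = 8, feature = c("full_fi", "cluster_fi", "cluster_area"),
                          day_coef = NULL, re_epi_coef = NULL,
                          feature_range = NULL, noise_sd = 0.05, seed = 1) {
  feature <- match.arg(feature)
  if (n < 2L) abort("`n` must be >= 2.", class = "wf_config_error")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "wf_config_error")
  defs <- wf_defaults()$regression[[feature]]
  day_coef <- day_coef %||% defs$day
  re_epi_coef <- re_epi_coef %||% defs$re_epi
  if (is.null(feature_range)) {
    feature_range <- admissible_range(day_coef, re_epi_coef)
  }
  if (feature_range[1] < 0 || feature_range[2] > 1 ||
      feature_range[1] >= feature_range[2]) {
    abort("`feature_range` must be an increasing interval within [0, 1].",
          class = "wf_config_error")
  }
  structure(
    list(n = as.integer(n), feature = feature, day_coef = day_coef,
         re_epi_coef = re_epi_coef, feature_range = feature_range,
         noise_sd = noise_sd, seed = seed),
    class = "cohort_config"
  )
}

# Widest sub-interval of [0, 1] keeping both linear outcomes inside [0, 1].
admissible_range <- function(day_coef, re_epi_coef) {
  lo <- 0; hi <- 1
  for (cf in list(day_coef, re_epi_coef)) {
    a <- cf$slope; b <- cf$intercept
    bounds <- sort(c((0 - b) / a, (1 - b) / a))
    lo <- max(lo, bounds[1]); hi <- min(hi, bounds[2])
  }
  if (lo >= hi) abort("coefficients admit no feature range within [0, 1].",
                      class = "wf_config_error")
  c(lo, hi)
}

#' Generate a synthetic wound-feature cohort
#'
#' @param cfg a [cohort_config()].
#' @return a tibble of wound samples with columns `wound_id`, the feature
#'   column (named after `cfg$feature`), `day_norm`, `re_epi_norm`, `day`
#'   and `re_epi_pct`.
#' @examples
#' generate_feature_cohort(cohort_config(n = 8, noise_sd = 0))
#' @export
generate_feature_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(cfg$seed, {
    f <- runif(cfg$n, cfg$feature_range[1], cfg$feature_range[2])
    day_norm <- cfg$day_coef$slope * f + cfg$day_coef$intercept +
      rnorm(cfg$n, 0, cfg$noise_sd)
    re_epi_norm <- cfg$re_epi_coef$slope * f + cfg$re_epi_coef$intercept +
      rnorm(cfg$n, 0, cfg$noise_sd)
    day_norm <- pmin(pmax(day_norm, 0), 1)
    re_epi_norm <- pmin(pmax(re_epi_norm, 0), 1)
    out <- tibble::tibble(
      wound_id = sprintf("w%02d", seq_len(cfg$n)),
      feature = f,
      day_norm = day_norm,
      re_epi_norm = re_epi_norm,
      day = day_norm * 6,
      re_epi_pct = re_epi_norm * 100
    )
    names(out)[names(out) == "feature"] <- cfg$feature
    out
  })
}
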