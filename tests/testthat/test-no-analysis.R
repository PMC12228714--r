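test_that("full-wound NO intensity is the normalized mean green", {
  expect_equal(extract_full_wound_fi(uniform_image(0, 255, 0),
                                     matrix(TRUE, 4, 4)), 1.0)
  expect_equal(extract_full_wound_fi(uniform_image(0, 0, 0),
                                     matrix(TRUE, 4, 4)), 0.0)
  img <- random_image(41, 12, 12)
  roi <- withr::with_seed(42, matrix(sample(c(TRUE, FALSE), 144, TRUE), 12))
  acc <- 0; n <- 0
  for (i in 1:12) for (j in 1:12) if (roi[i, j]) {
    acc <- acc + unclass(img)[i, j, 2]; n <- n + 1
  }
  expect_equal(extract_full_wound_fi(img, roi), acc / n / 255)
})

test_that("the highest-NO cluster matches the phantom capillary geometry", {
  cfg <- no_phantom_config(size = 96, radius = 40, n_capillaries = 6,
                           noise_sd = 0, seed = 2)
  out <- generate_no_phantom(cfg)
  cmap <- segment_wound(out$image, channels = "G", order_channel = "G")
  feats <- extract_highest_no_cluster(cmap)
  truth_frac <- out$truth$capillary_fraction
  n_retained <- sum(cmap$labels > 0)
  expect_lte(abs(feats$cluster_area - truth_frac), 2 / n_retained)
  expect_equal(feats$cluster_fi, cfg$capillary_intensity / 255, tolerance = 0.01)
  expect_equal(feats$cluster, 4)        # canonical: brightest cluster is last
})

test_that("highest-NO selection is invariant to raw label permutations", {
  out <- generate_no_phantom(no_phantom_config(size = 48, radius = 20,
                                               noise_sd = 0, seed = 5))
  img <- out$image
  mask <- apply_brightness_threshold(img, 10)
  feats <- build_feature_table(img, mask, channels = "G")
  fit <- kmeans_cluster(feats, 4, seed = 0)
  base <- extract_highest_no_cluster(
    relabel_and_stats(fit$cluster, img, mask, 5, order_channel = "G"))
  perm <- withr::with_seed(1, sample(4))[fit$cluster]
  permuted <- extract_highest_no_cluster(
    relabel_and_stats(perm, img, mask, 5, order_channel = "G"))
  expect_equal(base, permuted)
})

test_that("a uniform wound yields one cluster holding the whole area", {
  img <- uniform_image(0, 120, 0, 6, 6)
  mask <- apply_brightness_threshold(img, 10)
  cmap <- relabel_and_stats(rep(1L, sum(mask)), img, mask, k = 5,
                            order_channel = "G")
  feats <- extract_highest_no_cluster(cmap)
  expect_equal(feats$cluster_area, 1.0)
  expect_equal(feats$cluster_fi, 120 / 255)
})

test_that("normalization follows the day/6 and percent/100 rules", {
  d <- normalize_samples(tibble::tibble(day = c(3, 6, 0), re_epi_pct = c(53.6, 100, 0)))
  expect_equal(d$day_norm, c(0.5, 1, 0))
  expect_equal(d$re_epi_norm, c(0.536, 1, 0))
  expect_error(normalize_samples(tibble::tibble(day = -1, re_epi_pct = 10)),
               class = "wf_domain_error")
  expect_error(normalize_samples(tibble::tibble(day = 1, re_epi_pct = 101)),
               class = "wf_domain_error")
})

test_that("alpha = 0 ridge equals the OLS oracle on random designs", {
  for (s in 1:10) {
    dat <- withr::with_seed(s, {
      n <- sample(3:50, 1)
      tibble::tibble(full_fi = runif(n),
                     day_norm = runif(n), re_epi_norm = runif(n))
    })
    fit <- fit_multioutput_ridge(dat, "full_fi", alpha = 0)
    for (o in c("day_norm", "re_epi_norm")) {
      oracle <- ols_oracle(dat$full_fi, dat[[o]])
      expect_equal(fit$coefficients[[o]], unname(oracle["slope"]), tolerance = 1e-8)
      expect_equal(fit$intercepts[[o]], unname(oracle["intercept"]), tolerance = 1e-8)
    }
  }
})

test_that("all six packaged coefficient pairs are recovered from noise-free cohorts", {
  expected <- list(
    full_fi = list(day = c(0.85, 0.57), re_epi = c(0.40, 0.25)),
    cluster_fi = list(day = c(1.08, 0.03), re_epi = c(0.56, -0.04)),
    cluster_area = list(day = c(-1.08, 0.92), re_epi = c(-1.13, 0.51))
  )
  for (feature in names(expected)) {
    co <- generate_feature_cohort(cohort_config(n = 8, feature = feature,
                                                noise_sd = 0, seed = 3))
    fit <- fit_multioutput_ridge(co, feature, alpha = 0)
    expect_equal(fit$coefficients[["day_norm"]], expected[[feature]]$day[1],
                 tolerance = 1e-9)
    expect_equal(fit$intercepts[["day_norm"]], expected[[feature]]$day[2],
                 tolerance = 1e-9)
    expect_equal(fit$coefficients[["re_epi_norm"]], expected[[feature]]$re_epi[1],
                 tolerance = 1e-9)
    expect_equal(fit$intercepts[["re_epi_norm"]], expected[[feature]]$re_epi[2],
                 tolerance = 1e-9)
  }
})

test_that("heavy regularization shrinks slopes to zero and the degenerate design errors", {
  co <- generate_feature_cohort(cohort_config(n = 8, noise_sd = 0, seed = 1))
  big <- fit_multioutput_ridge(co, "full_fi", alpha = 1e6)
  expect_lt(abs(big$coefficients[["day_norm"]]), 1e-4)
  expect_equal(big$intercepts[["day_norm"]], mean(co$day_norm), tolerance = 1e-4)

  two <- tibble::tibble(full_fi = c(0, 1), day_norm = c(0, 1), re_epi_norm = c(0, 1))
  fit2 <- fit_multioutput_ridge(two, "full_fi", alpha = 0)
  expect_equal(fit2$coefficients[["day_norm"]], 1)

  flat <- tibble::tibble(full_fi = rep(0.5, 5), day_norm = runif(5),
                         re_epi_norm = runif(5))
  expect_error(fit_multioutput_ridge(flat, "full_fi", alpha = 0),
               class = "wf_singular_design")
})

test_that("slope signs follow the NO biology encoded in the defaults", {
  for (feature in c("full_fi", "cluster_fi", "cluster_area")) {
    co <- generate_feature_cohort(cohort_config(n = 30, feature = feature,
                                                noise_sd = 0.05, seed = 7))
    fit <- fit_multioutput_ridge(co, feature, alpha = 0)
    expected_sign <- if (feature == "cluster_area") -1 else 1
    expect_equal(sign(fit$coefficients[["day_norm"]]), expected_sign)
    expect_equal(sign(fit$coefficients[["re_epi_norm"]]), expected_sign)
  }
})

test_that("mse averages squared residuals per outcome", {
  expect_equal(unname(mse(c(1, 2), c(1, 2))), 0)
  expect_equal(unname(mse(c(0, 1), c(1, 1))), 0.5)
  y <- withr::with_seed(2, matrix(runif(20), 10))
  yh <- withr::with_seed(3, matrix(runif(20), 10))
  oracle <- c(0, 0)
  for (i in 1:10) for (j in 1:2) {
    oracle[j] <- oracle[j] + (y[i, j] - yh[i, j])^2 / 10
  }
  expect_equal(unname(mse(y, yh)), oracle)
  expect_error(mse(1:3, 1:4))
})

test_that("leave-one-out CV has one fold per sample and is conservative", {
  co <- generate_feature_cohort(cohort_config(n = 8, noise_sd = 0, seed = 2))
  cv <- loo_cv(co, "full_fi")
  expect_equal(cv$n_folds, 8)
  expect_equal(max(cv$folds$fold), 8)
  expect_equal(cv$summary$mse, c(0, 0), tolerance = 1e-18)

  # CV error never beats the in-sample error for OLS (hat-matrix identity)
  diffs <- vapply(1:100, function(s) {
    co <- generate_feature_cohort(cohort_config(n = 8, noise_sd = 0.05, seed = s))
    fit <- fit_multioutput_ridge(co, "full_fi", alpha = 0)
    ins <- mse(as.matrix(co[c("day_norm", "re_epi_norm")]),
               as.matrix(predict(fit, co)))
    cv <- loo_cv(co, "full_fi")
    mean(cv$summary$mse_norm) - mean(ins)
  }, numeric(1))
  expect_true(all(diffs >= -1e-12))
  expect_gt(mean(diffs), 0)
})

test_that("prediction round-trips through the normalization rules", {
  co <- generate_feature_cohort(cohort_config(n = 8, noise_sd = 0, seed = 4))
  fit <- fit_multioutput_ridge(co, "full_fi")
  pred <- predict(fit, co)
  days <- pred$day_norm * 6
  expect_equal(days / 6, pred$day_norm, tolerance = 1e-9)
  expect_equal(days, co$day, tolerance = 1e-9)   # noise-free: exact recovery
  expect_equal(pred$re_epi_norm * 100, co$re_epi_pct, tolerance = 1e-9)
})
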