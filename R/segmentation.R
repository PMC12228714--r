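#' Brightness threshold
#'
#' Retains the wound-bed pixels and drops the dark background: a pixel is
#' kept when the mean of its R, G, B values is at least `threshold`.
#'
#' @param img an [rgb_image()].
#' @param threshold brightness cut-off on the 0-255 scale (default 10).
#' @return logical retention mask (same shape as the image).
#' @export
apply_brightness_threshold <- function(img, threshold = 10) {
  stopifnot(inherits(img, "rgb_image"))
  a <- unclass(img)
  bright <- (a[, , 1, drop = FALSE] + a[, , 2, drop = FALSE] +
               a[, , 3, drop = FALSE]) / 3
  mask <- matrix(bright >= threshold, dim(a)[1], dim(a)[2])
  if (!any(mask)) {
    abort("no wound pixels above threshold.", class = "wf_empty_roi")
  }
  mask
}

#' Pixel feature table for clustering
#'
#' One row per retained pixel with the selected channel intensities and the
#' 0-based pixel positions `x` (column) and `y` (row). With
#' `scaling = "minmax"` every column is independently mapped to `[0, 1]`
#' (a constant column maps to 0); without scaling, raw 8-bit intensities sit
#' next to pixel coordinates of hundreds, and position would dominate the
#' clustering distance.
#'
#' Rows are ordered column-major (all rows of image column 1, then column 2,
#' ...), the order used consistently by [relabel_and_stats()].
#'
#' @param img an [rgb_image()].
#' @param mask logical retention mask.
#' @param channels subset of `c("R", "G", "B")`; pH mapping uses all three,
#'   NO mapping uses `"G"` only.
#' @param scaling `"minmax"` (default) or `"none"`.
#' @return a tibble with the channel columns, `x` and `y`, and attributes
#'   `scaling` and `mask`.
#' @export
build_feature_table <- function(img, mask, channels = c("R", "G", "B"),
                                scaling = c("minmax", "none")) {
  stopifnot(inherits(img, "rgb_image"))
  scaling <- match.arg(scaling)
  if (length(channels) < 1L) abort("`channels` must name at least one channel.")
  if (!any(mask)) abort("mask selects no pixels.", class = "wf_empty_roi")
  a <- unclass(img)
  keep <- which(mask)                       # column-major
  h <- nrow(mask)
  cols <- lapply(channels, function(ch) a[, , channel_index(ch)][keep])
  names(cols) <- channels
  cols$x <- (keep - 1L) %/% h               # 0-based column
  cols$y <- (keep - 1L) %% h                # 0-based row
  tab <- tibble::as_tibble(cols)
  if (scaling == "minmax") {
    tab <- dplyr::mutate(tab, dplyr::across(
      dplyr::everything(),
      function(v) {
        rng <- range(v)
        if (rng[1] == rng[2]) rep(0, length(v)) else (v - rng[1]) / (rng[2] - rng[1])
      }
    ))
  }
  attr(tab, "scaling") <- scaling
  attr(tab, "mask") <- mask
  tab
}

# k-means++ seeding: first centre uniform, then points sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j, ] <- X[sample.int(n, 1L), ]
    } else {
      centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

# Squared Euclidean distances from every row of X to every centre.
dist2_to_centers <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

lloyd <- function(X, centers, max_iter = 300L) {
  n <- nrow(X); k <- nrow(centers)
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    assign_new <- max.col(-d2, ties.method = "first")  # tie -> lowest index
    # re-seed any emptied centre at the worst-fit point (unless the fit is
    # already perfect, e.g. duplicated rows)
    for (j in which(tabulate(assign_new, k) == 0L)) {
      cur <- d2[cbind(seq_len(n), assign_new)]
      if (max(cur) <= 0) break
      far <- which.max(cur)
      centers[j, ] <- X[far, ]
      assign_new[far] <- j
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), assign_new)]))
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[assign_new == j, , drop = FALSE])
    }
  }
  d2 <- dist2_to_centers(X, centers)
  inertia <- sum(d2[cbind(seq_len(n), assign_old)])
  list(cluster = assign_old, centers = centers, inertia = inertia,
       inertia_trace = trace, n_iter = iter)
}

#' k-means clustering of pixel features
#'
#' Lloyd's algorithm with k-means++ initialization, restarted `n_init`
#' times with the lowest-inertia solution kept. Iteration stops when the
#' assignments stabilize or after `max_iter` sweeps. Ties in the
#' nearest-centre assignment are broken towards the lowest centre index and
#' all sampling is driven by `seed`, so results are reproducible.
#'
#' @param features a [build_feature_table()] tibble (or any all-numeric
#'   data frame / matrix).
#' @param k number of clusters, at most the number of rows.
#' @param seed integer RNG seed.
#' @param n_init number of k-means++ restarts.
#' @param max_iter iteration cap per restart.
#' @return an object of class `wf_kmeans`: list with `cluster` (1-based
#'   labels per row), `centers`, `inertia` (total within-cluster sum of
#'   squares), `inertia_trace` (objective after each assignment step of the
#'   winning restart), `n_iter`, `k`, `seed`.
#' @export
kmeans_cluster <- function(features, k, seed = 0, n_init = 10, max_iter = 300) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (nrow(X) < k) {
    abort(sprintf("cannot form %d clusters from %d rows.", k, nrow(X)))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- lloyd(X, kmeanspp_init(X, k), max_iter = as.integer(max_iter))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(c(best, list(k = k, seed = seed, n_init = n_init)),
            class = "wf_kmeans")
}

#' @export
print.wf_kmeans <- function(x, ...) {
  cat(sprintf("<wf_kmeans> k = %d, n = %d, inertia = %.4g (%d iterations)\n",
              x$k, length(x$cluster), x$inertia, x$n_iter))
  invisible(x)
}

#' Canonical cluster labels and per-cluster statistics
#'
#' Builds the labelled wound map: background (sub-threshold) pixels get
#' label 0 and the clustered pixels are renumbered `1 ... k-1` in ascending
#' order of their mean intensity in `order_channel`, so cluster indices are
#' comparable across wounds and days (cluster `k-1` is always the brightest
#' -- for pH images, the wound centre). Per-cluster statistics include the
#' pixel count ("elements per cluster"), mean channel intensities, the area
#' fraction of retained pixels, and -- when a calibration is supplied -- the
#' mean pH obtained by converting the cluster's mean intensity in the
#' calibration channel.
#'
#' @param labels raw cluster labels per retained pixel (a [kmeans_cluster()]
#'   fit or an integer vector in column-major mask order).
#' @param img the clustered [rgb_image()].
#' @param mask logical retention mask used to build the features.
#' @param k total number of labels including background (the clustered
#'   labels must have `k - 1` distinct values at most).
#' @param order_channel channel whose mean orders the clusters.
#' @param calibration optional [fit_calibration()] model for mean pH.
#' @return an object of class `cluster_map`: list with `labels` (integer
#'   matrix, 0 = background), `k`, `stats` (tibble), `order_channel`,
#'   `inertia` and `seed` when available.
#' @export
relabel_and_stats <- function(labels, img, mask, k, order_channel = "R",
                              calibration = NULL) {
  fit <- NULL
  if (inherits(labels, "wf_kmeans")) {
    fit <- labels
    labels <- fit$cluster
  }
  n_keep <- sum(mask)
  if (length(labels) != n_keep) {
    abort("`labels` must cover every retained pixel.", class = "wf_dimension_error")
  }
  if (length(unique(labels)) > k - 1L) {
    abort(sprintf("found %d clusters but k = %d allows only %d non-background labels.",
                  length(unique(labels)), k, k - 1L))
  }
  a <- unclass(img)
  keep <- which(mask)
  ord_vals <- a[, , channel_index(order_channel)][keep]
  means <- tapply(ord_vals, labels, mean)
  new_of_old <- setNames(rank(means, ties.method = "first"), names(means))
  canon <- as.integer(new_of_old[as.character(labels)])

  lab_mat <- matrix(0L, nrow(mask), ncol(mask))
  lab_mat[keep] <- canon

  chans <- list(R = a[, , 1][keep], G = a[, , 2][keep], B = a[, , 3][keep])
  stats <- tibble::tibble(cluster = sort(unique(canon))) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_pixels = sum(canon == .data$cluster),
      mean_R = mean(chans$R[canon == .data$cluster]),
      mean_G = mean(chans$G[canon == .data$cluster]),
      mean_B = mean(chans$B[canon == .data$cluster]),
      area_fraction = .data$n_pixels / n_keep
    ) |>
    dplyr::ungroup()
  if (!is.null(calibration)) {
    fi <- stats[[paste0("mean_", calibration$channel)]]
    stats$mean_ph <- estimate_ph(calibration, fi)
  }
  structure(
    list(labels = lab_mat, k = k, stats = stats, order_channel = order_channel,
         inertia = fit$inertia %||% NA_real_, seed = fit$seed %||% NA_integer_),
    class = "cluster_map"
  )
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> k = %d, %d retained pixels in %d clusters\n",
              x$k, sum(x$labels > 0), nrow(x$stats)))
  print(x$stats)
  invisible(x)
}

#' @rdname relabel_and_stats
#' @param x a `cluster_map`.
#' @param ... unused.
#' @method tidy cluster_map
#' @export
tidy.cluster_map <- function(x, ...) x$stats

#' @rdname relabel_and_stats
#' @method glance cluster_map
#' @export
glance.cluster_map <- function(x, ...) {
  tibble::tibble(k = x$k, n_retained = sum(x$labels > 0),
                 inertia = x$inertia, seed = x$seed)
}

#' Segment a wound image
#'
#' The full segmentation sequence: brightness threshold, feature assembly,
#' k-means, canonical relabelling and per-cluster statistics. Two readings
#' of the background label are supported. The default (`background =
#' "exclude"`) assigns sub-threshold pixels label 0 without clustering them
#' and partitions the retained pixels into `k - 1` clusters, so a `k = 5`
#' segmentation reports clusters 1-4 plus background. The alternative
#' (`background = "cluster"`) runs k-means with all `k` centres over every
#' pixel and maps the cluster holding the majority of sub-threshold pixels
#' to label 0.
#'
#' @inheritParams build_feature_table
#' @inheritParams kmeans_cluster
#' @param threshold brightness cut-off, see [apply_brightness_threshold()].
#' @param background background handling mode (see Details).
#' @param order_channel channel that orders the canonical labels.
#' @param calibration optional calibration model for per-cluster mean pH.
#' @return a `cluster_map` (see [relabel_and_stats()]).
#' @export
segment_wound <- function(img, k = 5, threshold = 10,
                          channels = c("R", "G", "B"),
                          scaling = c("minmax", "none"),
                          seed = 0, n_init = 10,
                          background = c("exclude", "cluster"),
                          order_channel = "R", calibration = NULL) {
  scaling <- match.arg(scaling)
  background <- match.arg(background)
  mask <- apply_brightness_threshold(img, threshold)
  if (background == "exclude") {
    feats <- build_feature_table(img, mask, channels, scaling)
    fit <- kmeans_cluster(feats, k - 1L, seed = seed, n_init = n_init)
    relabel_and_stats(fit, img, mask, k, order_channel, calibration)
  } else {
    all_mask <- matrix(TRUE, nrow(mask), ncol(mask))
    feats <- build_feature_table(img, all_mask, channels, scaling)
    fit <- kmeans_cluster(feats, k, seed = seed, n_init = n_init)
    # majority sub-threshold cluster -> background
    below <- as.vector(!mask)      # column-major, same order as features
    bg_frac <- tapply(below, fit$cluster, mean)
    bg_cluster <- as.integer(names(bg_frac)[which.max(bg_frac)])
    keep_rows <- fit$cluster != bg_cluster
    eff_mask <- matrix(FALSE, nrow(mask), ncol(mask))
    eff_mask[which(all_mask)[keep_rows]] <- TRUE
    labs <- fit$cluster[keep_rows]
    labs <- as.integer(factor(labs))         # compact to 1..k-1 (or fewer)
    out <- relabel_and_stats(labs, img, eff_mask, k, order_channel, calibration)
    out$inertia <- fit$inertia
    out$seed <- fit$seed
    out
  }
}

#' Within-cluster inertia across candidate k
#'
#' Utility for picking `k` from an elbow plot: runs [kmeans_cluster()] for
#' each candidate and tabulates the total within-cluster sum of squares,
#' which is non-increasing in `k` up to restart noise.
#'
#' @inheritParams kmeans_cluster
#' @param k_range integer vector of candidate cluster counts.
#' @return a tibble with columns `k` and `inertia`.
#' @export
inertia_curve <- function(features, k_range, seed = 0, n_init = 10) {
  if (max(k_range) > nrow(features)) {
    abort("largest k exceeds the number of rows.")
  }
  tibble::tibble(
    k = as.integer(k_range),
    inertia = vapply(k_range, function(k) {
      kmeans_cluster(features, k, seed = seed, n_init = n_init)$inertia
    }, numeric(1))
  )
}
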