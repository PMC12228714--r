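#' Configuration for the NO wound phantom
#'
#' Describes a synthetic DAF-FM nitric-oxide image: the green channel is
#' dark outside the circular wound, sits at a diffuse level inside it, and
#' carries bright curvilinear capillary-like structures drawn as seeded
#' random walks -- a stand-in for the vessel geometry seen in real wounds,
#' for which no quantitative model is available. The red and blue channels
#' stay at the background level (blocked by the emission filter).
#'
#' @param size image side in pixels.
#' @param center wound centre `c(x, y)`, 0-based; default image centre.
#' @param radius wound radius in pixels.
#' @param n_capillaries number of capillary segments (0 allowed; the truth
#'   mask is then empty).
#' @param capillary_width stroke width in pixels.
#' @param capillary_intensity green value on capillaries; must exceed
#'   `diffuse_intensity`.
#' @param diffuse_intensity green value of the non-capillary wound bed;
#'   must exceed `background`.
#' @param background intensity outside the wound.
#' @param noise_sd Gaussian noise sd added before quantization.
#' @param seed RNG seed.
#' @return a `no_phantom_config` list.
#' @export
no_phantom_config <- function(size = 96, center = NULL, radius = 40,
                              n_capillaries = 6, capillary_width = 2,
                              capillary_intensity = 200,
                              diffuse_intensity = 60, background = 8,
                              noise_sd = 0, seed = 1) {
  center <- center %||% c((size - 1) / 2, (size - 1) / 2)
  if (!(capillary_intensity > diffuse_intensity &&
        diffuse_intensity > background)) {
    abort("need capillary_intensity > diffuse_intensity > background.",
          class = "wf_config_error")
  }
  if (radius <= 0) abort("`radius` must be positive.", class = "wf_config_error")
  structure(
    list(size = size, center = center, radius = radius,
         n_capillaries = n_capillaries, capillary_width = capillary_width,
         capillary_intensity = capillary_intensity,
         diffuse_intensity = diffuse_intensity, background = background,
         noise_sd = noise_sd, seed = seed),
    class = "no_phantom_config"
  )
}

# Persistent-direction random walk inside the wound disc; returns visited
# (x, y) points at unit steps.
capillary_walk <- function(cfg) {
  theta0 <- runif(1, 0, 2 * pi)
  r0 <- cfg$radius * sqrt(runif(1)) * 0.8          # start inside the wound
  p <- cfg$center + r0 * c(cos(theta0), sin(theta0))
  dir <- runif(1, 0, 2 * pi)
  n_steps <- ceiling(1.5 * cfg$radius)
  pts <- matrix(NA_real_, n_steps + 1L, 2)
  pts[1, ] <- p
  for (s in seq_len(n_steps)) {
    dir <- dir + rnorm(1, 0, 0.3)                  # gentle curvature
    p <- p + c(cos(dir), sin(dir))
    if (sqrt(sum((p - cfg$center)^2)) > cfg$radius) break
    pts[s + 1L, ] <- p
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

#' Generate a nitric-oxide wound phantom
#'
#' @param cfg a [no_phantom_config()].
#' @return a list with `image` (an [rgb_image()]) and `truth`, carrying
#'   `capillary_mask`, `wound_mask` and `capillary_fraction` (capillary
#'   pixels / wound pixels). With zero capillaries the mask is all-`FALSE`.
#' @export
generate_no_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "no_phantom_config"))
  n <- cfg$size
  x <- matrix(rep(0:(n - 1), each = n), n)
  y <- matrix(rep(0:(n - 1), times = n), n)
  wound <- sqrt((x - cfg$center[1])^2 + (y - cfg$center[2])^2) <= cfg$radius

  cap <- matrix(FALSE, n, n)
  withr::with_seed(cfg$seed, {
    half_w <- cfg$capillary_width / 2
    for (i in seq_len(cfg$n_capillaries)) {
      pts <- capillary_walk(cfg)
      for (j in seq_len(nrow(pts))) {
        px <- pts[j, 1]; py <- pts[j, 2]
        xs <- max(0, floor(px - half_w)):min(n - 1, ceiling(px + half_w))
        ys <- max(0, floor(py - half_w)):min(n - 1, ceiling(py + half_w))
        sel <- expand.grid(yy = ys, xx = xs)
        hit <- (sel$xx - px)^2 + (sel$yy - py)^2 <= half_w^2
        cap[cbind(sel$yy[hit] + 1L, sel$xx[hit] + 1L)] <- TRUE
      }
    }
    cap <- cap & wound
    green <- matrix(cfg$background, n, n)
    green[wound] <- cfg$diffuse_intensity
    green[cap] <- cfg$capillary_intensity
    if (cfg$noise_sd > 0) green <- green + rnorm(length(green), 0, cfg$noise_sd)
    flat <- matrix(cfg$background, n, n)
    img <- rgb_image(array(c(quantize8(flat), quantize8(green), quantize8(flat)),
                           c(n, n, 3)))
    list(
      image = img,
      truth = list(capillary_mask = cap, wound_mask = wound,
                   capillary_fraction = sum(cap) / sum(wound))
    )
  })
}
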