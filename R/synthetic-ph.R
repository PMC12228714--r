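#' Configuration for the pH wound phantom
#'
#' Describes a synthetic wound-bed fluorescence image: a circular wound on
#' a dark background whose red channel encodes a concentric pH field
#' through the active calibration line, with the highest pH at the centre
#' decreasing outward. Three radial profiles are available: `"linear"` and
#' `"quadratic"` interpolate `center_ph -> edge_ph` continuously in the
#' (squared) relative radius; `"stepped"` quantizes the wound into
#' `n_rings` concentric equal-area bands with equally spaced pH levels,
#' giving a discrete ring structure with recoverable ground-truth labels.
#' The green and blue channels carry a low-amplitude radial texture
#' standing in for the weak out-of-band signal that leaks through the
#' emission filter and traces the wound topology.
#'
#' @param size image side in pixels (square image).
#' @param center wound centre `c(x, y)` in 0-based pixel coordinates;
#'   default is the image centre.
#' @param radius wound radius in pixels.
#' @param center_ph,edge_ph pH at the wound centre and edge, within
#'   `[4, 10]`.
#' @param profile radial pH profile (see Details).
#' @param n_rings number of bands for the stepped profile.
#' @param background background intensity (0-255, below the brightness
#'   threshold of the analysis).
#' @param noise_sd per-channel Gaussian noise standard deviation, added
#'   before 8-bit quantization.
#' @param texture_amplitude peak amplitude (0-255) of the green/blue
#'   radial texture.
#' @param n_frames number of focus frames in the generated stack.
#' @param focus_frame 1-based index of the sharp frame; other frames are
#'   blurred in proportion to their distance from it.
#' @param blur_step Gaussian blur sigma (pixels) added per frame of focus
#'   distance.
#' @param calibration the [fit_calibration()] model rendered through;
#'   default the packaged line.
#' @param seed RNG seed; equal seeds give bit-identical phantoms.
#' @return a `ph_phantom_config` list.
#' @export
ph_phantom_config <- function(size = 96, center = NULL, radius = 40,
                              center_ph = 8.5, edge_ph = 6.5,
                              profile = c("linear", "quadratic", "stepped"),
                              n_rings = 4, background = 8, noise_sd = 0,
                              texture_amplitude = 15, n_frames = 11,
                              focus_frame = 6, blur_step = 0.7,
                              calibration = default_calibration(), seed = 1) {
  profile <- match.arg(profile)
  center <- center %||% c((size - 1) / 2, (size - 1) / 2)
  if (radius <= 0) abort("`radius` must be positive.", class = "wf_config_error")
  if (background < 0 || background >= 255) {
    abort("`background` must lie in [0, 255).", class = "wf_config_error")
  }
  for (p in c(center_ph, edge_ph)) {
    if (p < 4 || p > 10) abort("pH values must lie in [4, 10].", class = "wf_config_error")
  }
  structure(
    list(size = size, center = center, radius = radius,
         center_ph = center_ph, edge_ph = edge_ph, profile = profile,
         n_rings = n_rings, background = background, noise_sd = noise_sd,
         texture_amplitude = texture_amplitude, n_frames = n_frames,
         focus_frame = focus_frame, blur_step = blur_step,
         calibration = calibration, seed = seed),
    class = "ph_phantom_config"
  )
}

# Separable Gaussian blur with reflected edges; sigma in pixels.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  pad_idx <- function(n) c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  conv1 <- function(m) {     # along rows
    mp <- m[pad_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(kern)) {
      out <- out + kern[i] * mp[(i - 1) + seq_len(nrow(m)), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(mat))))
}

quantize8 <- function(mat) pmax(pmin(round(mat), 255), 0)

#' Generate a pH wound phantom z-stack
#'
#' Renders the configured concentric pH field through the calibration line
#' into the red channel (`FI = a * pH + b`, then noise, then clamping and
#' rounding to 8-bit, mimicking sensor quantization), adds the green/blue
#' radial texture, and replicates the scene across a focus stack in which
#' blur grows with distance from the designated focus frame.
#'
#' @param cfg a [ph_phantom_config()].
#' @return a list with `stack` (a [zstack()]) and `truth`, which carries
#'   `ph_field` (per-pixel true pH, `NA` outside the wound), `rings`
#'   (integer ground-truth region labels, 0 outside, 1 = edge band up to
#'   `n_rings` = centre band), `wound_mask`, and `fi_field` (the noise-free
#'   real-valued red channel before quantization).
#' @export
generate_ph_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "ph_phantom_config"))
  n <- cfg$size
  x <- matrix(rep(0:(n - 1), each = n), n)      # column index
  y <- matrix(rep(0:(n - 1), times = n), n)     # row index
  r <- sqrt((x - cfg$center[1])^2 + (y - cfg$center[2])^2)
  inside <- r <= cfg$radius
  t_rel <- pmin(r / cfg$radius, 1)

  n_rings <- as.integer(cfg$n_rings)
  ring_edges <- sqrt(seq(0, 1, length.out = n_rings + 1))   # equal-area bands
  band <- findInterval(t_rel, ring_edges, rightmost.closed = TRUE,
                       left.open = TRUE)
  band[t_rel == 0] <- 1L

  f <- switch(cfg$profile,
    linear = t_rel,
    quadratic = t_rel^2,
    stepped = (band - 1) / (n_rings - 1)
  )
  ph_field <- cfg$center_ph + (cfg$edge_ph - cfg$center_ph) * f
  fi_field <- predict_fi(cfg$calibration, ph_field)
  if (max(fi_field[inside]) <= cfg$background) {
    abort("wound indistinguishable from background: rendered centre intensity <= background.",
          class = "wf_config_error")
  }

  # Green/blue topology texture: radial ramp riding on a rim offset, so the
  # wound boundary is a sharp step the focus metric can see; the offset is
  # affine and therefore invisible to min-max-scaled clustering features.
  amp <- cfg$texture_amplitude
  red0 <- ifelse(inside, fi_field, cfg$background)
  green0 <- ifelse(inside, cfg$background + amp * (0.4 + 0.6 * (1 - f)),
                   cfg$background)
  blue0 <- green0

  frames <- withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_frames), function(i) {
      sigma <- cfg$blur_step * abs(i - cfg$focus_frame)
      chans <- lapply(list(red0, green0, blue0), function(ch) {
        ch <- gaussian_blur(ch, sigma)
        if (cfg$noise_sd > 0) ch <- ch + rnorm(length(ch), 0, cfg$noise_sd)
        quantize8(ch)
      })
      rgb_image(array(c(chans[[1]], chans[[2]], chans[[3]]), c(n, n, 3)))
    })
  })

  rings <- matrix(0L, n, n)
  rings[inside] <- n_rings + 1L - band[inside]   # 1 = edge band, n_rings = centre
  truth <- list(
    ph_field = ifelse(inside, ph_field, NA_real_),
    rings = rings,
    wound_mask = inside,
    fi_field = ifelse(inside, fi_field, NA_real_)
  )
  list(stack = zstack(frames), truth = truth)
}
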