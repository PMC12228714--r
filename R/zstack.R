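#' Focus stack of RGB frames
#'
#' A `zstack` holds an ordered series of [rgb_image()] frames of one scene
#' captured at stepped focus-stage positions. The acquisition convention is
#' 11 frames with stage positions evenly spaced from 0 to 1000.
#'
#' @param frames list of [rgb_image()] objects, all the same size.
#' @param positions numeric focus-stage positions in `[0, 1000]`, strictly
#'   increasing, one per frame. Defaults to an even spacing over `[0, 1000]`.
#' @return an object of class `zstack`.
#' @export
zstack <- function(frames, positions = NULL) {
  if (length(frames) < 1L) abort("a zstack needs at least one frame.")
  if (!all(vapply(frames, inherits, logical(1), "rgb_image"))) {
    abort("all frames must be rgb_image objects.")
  }
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all frames must share the same dimensions.", class = "wf_dimension_error")
  }
  positions <- positions %||% seq(0, 1000, length.out = length(frames))
  if (length(positions) != length(frames)) {
    abort("`positions` must have one entry per frame.")
  }
  if (any(diff(positions) <= 0)) abort("`positions` must be strictly increasing.")
  if (min(positions) < 0 || max(positions) > 1000) {
    abort("`positions` must lie in [0, 1000].")
  }
  structure(list(frames = frames, positions = as.numeric(positions)),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<zstack> %d frames of %d x %d, stage positions %g..%g\n",
              length(x$frames), d[1], d[2], min(x$positions), max(x$positions)))
  invisible(x)
}

#' @export
length.zstack <- function(x) length(x$frames)

# Variance of the 3x3 (4-neighbour) Laplacian of one channel, interior pixels.
laplacian_variance <- function(img, channel = "G") {
  ch <- unclass(img)[, , channel_index(channel)]
  h <- nrow(ch); w <- ncol(ch)
  if (h < 3L || w < 3L) return(0)
  core <- ch[2:(h - 1), 2:(w - 1)]
  lap <- ch[1:(h - 2), 2:(w - 1)] + ch[3:h, 2:(w - 1)] +
    ch[2:(h - 1), 1:(w - 2)] + ch[2:(h - 1), 3:w] - 4 * core
  stats::var(as.vector(lap))
}

#' Select the analysis frame from a focus stack
#'
#' The default strategy picks the frame with the greatest variance of a
#' 3x3 Laplacian of the green channel, a standard sharpness score; ties are
#' broken by the lowest frame index. `strategy = "first"` returns frame 1
#' and `strategy = "index"` a caller-chosen frame.
#'
#' @param stack a [zstack()].
#' @param strategy one of `"max-laplacian"`, `"first"`, `"index"`.
#' @param index 1-based frame index, used when `strategy = "index"`.
#' @return the selected [rgb_image()] with attribute `frame_index` (1-based).
#' @export
select_focused <- function(stack,
                           strategy = c("max-laplacian", "first", "index"),
                           index = NULL) {
  stopifnot(inherits(stack, "zstack"))
  strategy <- match.arg(strategy)
  i <- switch(strategy,
    "first" = 1L,
    "index" = {
      if (is.null(index) || index < 1L || index > length(stack$frames)) {
        abort("`index` must name an existing frame.")
      }
      as.integer(index)
    },
    "max-laplacian" = {
      scores <- vapply(stack$frames, laplacian_variance, numeric(1))
      which.max(scores)   # ties -> lowest index
    }
  )
  out <- stack$frames[[i]]
  attr(out, "frame_index") <- i
  out
}
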