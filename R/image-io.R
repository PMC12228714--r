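#' 8-bit RGB image container
#'
#' An `rgb_image` is a `height x width x 3` numeric array of whole-number
#' pixel intensities in `[0, 255]`, channel order R, G, B. Pixel coordinates
#' follow the image-processing convention used throughout the package:
#' 0-based, `x` is the column index, `y` the row index, origin at the image
#' top-left. The convention matters because `x` and `y` are used directly as
#' clustering features (see [build_feature_table()]).
#'
#' @param pixels numeric array `h x w x 3` with values in `[0, 255]`.
#' @param pixel_size optional physical pixel pitch in micrometres per pixel.
#' @return an object of class `rgb_image`.
#' @seealso [read_rgb_image()], [write_rgb_image()]
#' @export
rgb_image <- function(pixels, pixel_size = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be a height x width x 3 array.", class = "wf_format_error")
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    abort("image must have height and width >= 1.", class = "wf_format_error")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("pixel values must lie in [0, 255].", class = "wf_format_error")
  }
  structure(round(pixels), pixel_size = pixel_size, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 channels (R,G,B), 8-bit\n", d[1], d[2]))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(unclass(x))

channel_index <- function(channel) {
  i <- match(channel, c("R", "G", "B"))
  if (is.na(i)) abort('`channel` must be one of "R", "G", "B".')
  i
}

#' Read an 8-bit RGB image from PNG or TIFF
#'
#' 16-bit TIFF input is rescaled to 8-bit by integer (floor) division of the
#' raw 16-bit values by 257, so that full scale maps exactly to full scale
#' (65535 -> 255). Files must carry exactly three channels; greyscale or
#' RGBA input raises a format error naming the channel count found.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return an [rgb_image()].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read image: file '%s' does not exist.", path),
          class = "wf_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    bits <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample") %||% 8L
  } else {
    abort(sprintf("unsupported image format '%s' (need PNG or TIFF).", ext),
          class = "wf_format_error")
  }
  nch <- if (length(dim(raw)) == 3L) dim(raw)[3] else 1L
  if (nch != 3L) {
    abort(sprintf("expected a 3-channel RGB image, found %d channel%s.",
                  nch, if (nch == 1L) "" else "s"),
          class = "wf_format_error")
  }
  vals <- round(raw * (2^bits - 1))      # back to raw integer codes
  if (bits == 16L) vals <- vals %/% 257 else if (bits != 8L) {
    vals <- floor(vals / (2^bits - 1) * 255)
  }
  rgb_image(array(vals, dim(raw)[1:3]))
}

#' Write an 8-bit RGB image to PNG or TIFF
#'
#' @param img an [rgb_image()].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  ext <- tolower(tools::file_ext(path))
  arr <- unclass(img) / 255
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  } else {
    abort(sprintf("unsupported image format '%s' (need PNG or TIFF).", ext),
          class = "wf_format_error")
  }
  invisible(path)
}
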