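#' Load a region-of-interest mask
#'
#' Manual wound crops (e.g. exported from ImageJ) are exchanged in one of two
#' plain formats: a binary PNG of the same size as the image, where any
#' non-zero pixel is inside the ROI, or a JSON polygon
#' `{"vertices": [[x, y], ...]}` with at least three vertices in 0-based
#' pixel coordinates (`x` = column, `y` = row). Polygons are rasterized by
#' the even-odd rule: a pixel belongs to the ROI when its centre falls
#' inside the polygon.
#'
#' @param path path to a `.png` mask or `.json` polygon.
#' @param shape integer vector `c(height, width)` of the image the mask crops.
#' @return a logical `height x width` matrix with at least one `TRUE` pixel
#'   and attribute `source` (`"binary-image"` or `"polygon"`).
#' @export
load_roi_mask <- function(path, shape) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read ROI: file '%s' does not exist.", path),
          class = "wf_io_error")
  }
  shape <- as.integer(shape)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    mask <- raw > 0
    src <- "binary-image"
  } else if (ext == "json") {
    poly <- jsonlite::fromJSON(path)
    verts <- poly$vertices
    if (is.null(verts) || NROW(verts) < 3L) {
      abort("polygon ROI needs at least 3 vertices.", class = "wf_format_error")
    }
    mask <- rasterize_polygon(as.matrix(verts), shape)
    src <- "polygon"
  } else {
    abort(sprintf("unsupported ROI format '%s' (need PNG or JSON).", ext),
          class = "wf_format_error")
  }
  if (!identical(dim(mask), shape)) {
    abort(sprintf("ROI mask is %d x %d but the image is %d x %d.",
                  nrow(mask), ncol(mask), shape[1], shape[2]),
          class = "wf_dimension_error")
  }
  if (!any(mask)) abort("ROI mask selects no pixels.", class = "wf_empty_roi")
  structure(mask, source = src)
}

# Even-odd ray-casting rasterization at 0-based pixel centres (x = col, y = row).
rasterize_polygon <- function(vertices, shape) {
  h <- shape[1]; w <- shape[2]
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  nv <- nrow(vertices)
  crossings <- integer(length(px))
  for (i in seq_len(nv)) {
    j <- if (i == 1L) nv else i - 1L
    x1 <- vertices[i, 1]; y1 <- vertices[i, 2]
    x2 <- vertices[j, 1]; y2 <- vertices[j, 2]
    straddles <- (y1 > py) != (y2 > py)
    if (!any(straddles)) next
    xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
    crossings <- crossings + as.integer(straddles & px < xint)
  }
  matrix(crossings %% 2L == 1L, nrow = h, ncol = w)
}
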