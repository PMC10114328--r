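# Internal raster convention: a "pixel image" is a numeric array of dim
# c(H, W, 3), integral values in 0..255, row-major semantics (row 1 = top).
# A "gray image" is an H x W matrix on the same scale.

#' Validate and coerce a pixel image
#'
#' Pixel images are H x W x 3 arrays of 8-bit channel values (0-255).
#' This coercion checks the invariants once so downstream operations
#' can assume them.
#'
#' @param x numeric array, dim H x W x 3, values in 0..255.
#' @return the validated array (storage mode double, values rounded).
#' @export
as_pixel_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L)
    stop("a pixel image must be an H x W x 3 array", call. = FALSE)
  if (dim(x)[1L] < 1L || dim(x)[2L] < 1L || length(x) == 0L)
    stop("empty raster: H and W must be >= 1", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  x <- round(x)
  storage.mode(x) <- "double"
  x
}

#' Read a fundus image from disk
#'
#' Accepts 8-bit PNG or JPEG; grayscale and RGBA rasters are promoted /
#' flattened to RGB.
#'
#' @param path file path (.png, .jpg, .jpeg).
#' @return pixel image array (H x W x 3, 0-255).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' (PNG or JPEG expected)", call. = FALSE)
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3L] == 4L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  as_pixel_image(round(raw * 255))
}

#' Write a pixel image as PNG
#'
#' @param img pixel image array.
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_pixel_image(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

# EBImage stores rasters x-major in [0,1]; transpose both ways.
to_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

from_ebimage <- function(e) {
  a <- aperm(EBImage::imageData(e), c(2L, 1L, 3L))
  pmin(pmax(round(a * 255), 0), 255)
}

#' Resize a pixel image with bilinear interpolation
#'
#' @param img pixel image array.
#' @param height,width target size in pixels.
#' @return resized pixel image.
#' @export
resize_image <- function(img, height, width = height) {
  img <- as_pixel_image(img)
  if (dim(img)[1L] == height && dim(img)[2L] == width) return(img)
  from_ebimage(EBImage::resize(to_ebimage(img), w = width, h = height))
}
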