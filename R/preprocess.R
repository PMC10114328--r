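# Preprocessing SOP: black-border auto-crop, circular crop, HSV hue/value
# histogram equalization, final resize. Coordinates are 0-based with
# half-open bounding boxes [r0, r1) x [c0, c1).

#' Preprocessing configuration
#'
#' Settings for [run_sop()]: the clip tolerance used to locate the retinal
#' disc, the final square output side fed to the network, and which HSV
#' channels are histogram-equalized.
#'
#' @param tolerance integer >= 0; a pixel belongs to the foreground when its
#'   gray value is strictly above this. Default 7.
#' @param output_side final square side in pixels after resizing. Default 224,
#'   the backbone's native input.
#' @param equalize_channels subset of `c("hue", "saturation", "value")`.
#'   Default hue and value; saturation is left untouched.
#' @param quality `NULL` to skip the quality gate, otherwise a
#'   [quality_thresholds()] object.
#' @return an object of class `sop_config`.
#' @export
sop_config <- function(tolerance = 7L, output_side = 224L,
                       equalize_channels = c("hue", "value"),
                       quality = quality_thresholds()) {
  stopifnot(tolerance >= 0, output_side >= 8)
  equalize_channels <- match.arg(equalize_channels,
                                 c("hue", "saturation", "value"),
                                 several.ok = TRUE)
  structure(list(tolerance = as.integer(tolerance),
                 output_side = as.integer(output_side),
                 equalize_channels = equalize_channels,
                 quality = quality),
            class = "sop_config")
}

#' Convert an RGB image to grayscale
#'
#' Standard luma weighting 0.299 R + 0.587 G + 0.114 B, rounded to integers,
#' so pure white maps to 255 and pure black to 0.
#'
#' @param img pixel image array.
#' @return H x W matrix of gray values 0-255.
#' @export
rgb_to_gray <- function(img) {
  img <- as_pixel_image(img)
  round(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
}

#' Build the clipping mask
#'
#' The mask is 1 exactly where the gray value is strictly greater than the
#' tolerance, 0 where it is less than or equal; it marks the informative
#' (non-border) pixels.
#'
#' @param gray H x W gray matrix (0-255).
#' @param tolerance integer >= 0.
#' @return H x W 0/1 integer matrix.
#' @export
build_clip_mask <- function(gray, tolerance = 7L) {
  stopifnot(is.matrix(gray), tolerance >= 0)
  mask <- (gray > tolerance) * 1L
  storage.mode(mask) <- "integer"
  mask
}

#' Tightest bounding box of the mask content
#'
#' @param mask 0/1 matrix.
#' @return `list(r0, r1, c0, c1)` (0-based, half-open) covering every
#'   1-valued element, or `NULL` when the mask contains no 1.
#' @export
content_bbox <- function(mask) {
  stopifnot(is.matrix(mask))
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) return(NULL)
  list(r0 = min(rows) - 1L, r1 = max(rows),
       c0 = min(cols) - 1L, c1 = max(cols))
}

#' Auto-crop uninformative black borders
#'
#' Gray conversion, clip mask, tight bounding box, then extraction of that
#' rectangle from the RGB image. An image with no pixel above tolerance is
#' returned unchanged with a warning.
#'
#' @param img pixel image array.
#' @param tolerance clip tolerance (default 7).
#' @return cropped pixel image.
#' @export
autocrop <- function(img, tolerance = 7L) {
  img <- as_pixel_image(img)
  bb <- content_bbox(build_clip_mask(rgb_to_gray(img), tolerance))
  if (is.null(bb)) {
    warning("no pixel above tolerance; returning input unchanged")
    return(img)
  }
  img[(bb$r0 + 1L):bb$r1, (bb$c0 + 1L):bb$c1, , drop = FALSE]
}

# Disc membership: pixel (i, j) (0-based) is inside when the distance from
# its center (i + 0.5, j + 0.5) to (L/2, L/2) is <= L/2.
disc_mask <- function(L) {
  ctr <- L / 2
  d2 <- outer((seq_len(L) - 0.5 - ctr)^2, (seq_len(L) - 0.5 - ctr)^2, "+")
  d2 <= ctr^2
}

#' Circular crop about the image center
#'
#' Resizes the (already auto-cropped) image to an L x L square where
#' L = max(H, W), zeroes every pixel whose center falls outside the central
#' disc of radius L/2, then auto-crops once more. The result is square with
#' black corners, so later resizing cannot deform the retina.
#'
#' @param img pixel image array.
#' @param tolerance clip tolerance for the final re-crop.
#' @return square pixel image.
#' @export
circular_crop <- function(img, tolerance = 7L) {
  img <- as_pixel_image(img)
  L <- max(dim(img)[1:2])
  sq <- resize_image(img, L, L)
  inside <- disc_mask(L)
  sq <- sq * as.vector(inside)          # recycled over the 3 channels
  suppressWarnings(autocrop(sq, tolerance))
}

# Histogram equalization of one discrete 0..255 channel:
# T(v) = round((cdf(v) - cdf_min) / (N - cdf_min) * 255), with cdf_min the
# count at the lowest occupied level. A single-level histogram maps to 0.
equalize_levels <- function(q) {
  counts <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(counts > 0L)[1L]]
  n <- length(q)
  if (n == cdf_min) return(rep(0L, n))  # degenerate: one occupied level
  lut <- as.integer(round((cdf - cdf_min) / (n - cdf_min) * 255))
  lut[lut < 0L] <- 0L
  lut[q + 1L]
}

#' Equalize HSV channels of an image
#'
#' Converts to HSV, independently histogram-equalizes each selected channel
#' on a discrete 0-255 scale (hue is rescaled to that full scale internally,
#' avoiding the 0-179 dialect of some imaging stacks), and converts back to
#' RGB. Unselected channels pass through untouched.
#'
#' @param img pixel image array.
#' @param channels subset of `c("hue", "saturation", "value")`.
#' @return pixel image with enhanced contrast.
#' @export
equalize_hsv <- function(img, channels = c("hue", "value")) {
  img <- as_pixel_image(img)
  if (length(channels) == 0L) return(img)
  channels <- match.arg(channels, c("hue", "saturation", "value"),
                        several.ok = TRUE)
  d <- dim(img)
  rgb <- matrix(aperm(img, c(3L, 1L, 2L)), nrow = 3L)   # 3 x Npx
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)   # rows h, s, v in [0,1]
  sel <- c(hue = "h", saturation = "s", value = "v")[channels]
  for (ch in sel) {
    q <- as.integer(round(hsv[ch, ] * 255))
    hsv[ch, ] <- equalize_levels(q) / 255
  }
  out <- grDevices::col2rgb(grDevices::hsv(hsv["h", ], hsv["s", ], hsv["v", ]))
  aperm(array(as.numeric(out), dim = c(3L, d[1L], d[2L])), c(2L, 3L, 1L))
}

#' Run the full preprocessing SOP on one image
#'
#' Order: border auto-crop, circular crop, quality gate, HSV equalization
#' (skipped for rejected images), resize to the configured square side.
#'
#' @param img pixel image array.
#' @param cfg an [sop_config()].
#' @return list with elements `image` (processed raster), `rejected`
#'   (logical), `quality` (label or `NA` when the gate is disabled),
#'   `metrics` (quality metrics or `NULL`) and `steps` (character log).
#' @export
run_sop <- function(img, cfg = sop_config()) {
  stopifnot(inherits(cfg, "sop_config"))
  img <- as_pixel_image(img)
  steps <- character()
  blank <- is.null(content_bbox(build_clip_mask(rgb_to_gray(img), cfg$tolerance)))
  if (!blank) {
    img <- suppressWarnings(autocrop(img, cfg$tolerance))
    steps <- c(steps, "autocrop")
    img <- circular_crop(img, cfg$tolerance)
    steps <- c(steps, "circular_crop")
  }
  quality <- NA_character_
  metrics <- NULL
  if (!is.null(cfg$quality)) {
    qa <- assess_quality(img, cfg$quality, tolerance = cfg$tolerance)
    quality <- qa$label
    metrics <- qa$metrics
    steps <- c(steps, paste0("quality:", quality))
  }
  rejected <- blank || identical(quality, "reject")
  if (!rejected) {
    img <- equalize_hsv(img, cfg$equalize_channels)
    steps <- c(steps, "equalize_hsv")
  }
  img <- resize_image(img, cfg$output_side, cfg$output_side)
  steps <- c(steps, sprintf("resize:%d", cfg$output_side))
  list(image = img, rejected = rejected, quality = quality,
       metrics = metrics, steps = steps)
}
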