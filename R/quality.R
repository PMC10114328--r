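# Three-label image quality gate (reject / usable / good). The published
# pipeline delegated this triage to an external pretrained quality network;
# here a transparent three-metric heuristic carries the same label
# vocabulary and filtering contract, and can be swapped for a learned gate.

#' Quality gate thresholds
#'
#' Lower bounds on the three quality metrics. `good` thresholds must
#' dominate `usable` thresholds componentwise. Defaults were calibrated once
#' against the synthetic generator's sharp, blurred and darkened fixtures.
#'
#' @param min_foreground_good,min_foreground_usable minimum fraction of
#'   pixels above the clip tolerance.
#' @param min_sharpness_good,min_sharpness_usable minimum Laplacian variance
#'   of the gray image (intensity^2 units).
#' @param min_mean_value_usable minimum mean HSV value channel (0-255).
#' @return object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(min_foreground_good = 0.25,
                               min_foreground_usable = 0.10,
                               min_sharpness_good = 60,
                               min_sharpness_usable = 8,
                               min_mean_value_usable = 40) {
  stopifnot(min_foreground_good >= min_foreground_usable,
            min_sharpness_good >= min_sharpness_usable)
  structure(list(min_foreground_good = min_foreground_good,
                 min_foreground_usable = min_foreground_usable,
                 min_sharpness_good = min_sharpness_good,
                 min_sharpness_usable = min_sharpness_usable,
                 min_mean_value_usable = min_mean_value_usable),
            class = "quality_thresholds")
}

# Variance of the 4-neighbour Laplacian over the interior of a gray image.
laplacian_variance <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3L || w < 3L) return(0)
  core <- gray[2:(h - 1L), 2:(w - 1L)]
  lap <- gray[1:(h - 2L), 2:(w - 1L)] + gray[3:h, 2:(w - 1L)] +
    gray[2:(h - 1L), 1:(w - 2L)] + gray[2:(h - 1L), 3:w] - 4 * core
  stats::var(as.vector(lap))
}

#' Compute quality metrics for an image
#'
#' @param img pixel image array.
#' @param tolerance clip tolerance used for the foreground fraction.
#' @return list with `foreground_fraction` (0-1), `sharpness` (Laplacian
#'   variance) and `mean_value` (mean HSV value, 0-255).
#' @export
quality_metrics <- function(img, tolerance = 7L) {
  img <- as_pixel_image(img)
  gray <- rgb_to_gray(img)
  list(foreground_fraction = mean(gray > tolerance),
       sharpness = laplacian_variance(gray),
       mean_value = mean(pmax(img[, , 1L], img[, , 2L], img[, , 3L])))
}

#' Assign a quality label to an image
#'
#' `good` when all good thresholds are met, `usable` when all usable
#' thresholds are met, otherwise `reject`.
#'
#' @param img pixel image array.
#' @param th a [quality_thresholds()] object.
#' @param tolerance clip tolerance for the foreground metric.
#' @return list with `label` (one of good/usable/reject) and `metrics`.
#' @export
assess_quality <- function(img, th = quality_thresholds(), tolerance = 7L) {
  stopifnot(inherits(th, "quality_thresholds"))
  m <- quality_metrics(img, tolerance)
  usable_ok <- m$foreground_fraction >= th$min_foreground_usable &&
    m$sharpness >= th$min_sharpness_usable &&
    m$mean_value >= th$min_mean_value_usable
  good_ok <- usable_ok &&
    m$foreground_fraction >= th$min_foreground_good &&
    m$sharpness >= th$min_sharpness_good
  label <- if (good_ok) "good" else if (usable_ok) "usable" else "reject"
  list(label = label, metrics = m)
}

#' Filter a record list down to usable and good images
#'
#' @param records list of records, each a list carrying an `image` element
#'   (or a precomputed `quality` label, which is trusted when present).
#' @param th a [quality_thresholds()] object.
#' @param tolerance clip tolerance.
#' @return the records labeled good or usable, original order preserved.
#' @export
filter_usable <- function(records, th = quality_thresholds(), tolerance = 7L) {
  if (length(records) == 0L) return(records)
  keep <- vapply(records, function(r) {
    lab <- r$quality
    if (is.null(lab) || is.na(lab)) lab <- assess_quality(r$image, th, tolerance)$label
    lab %in% c("good", "usable")
  }, logical(1L))
  records[keep]
}
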