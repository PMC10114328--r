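# Synthetic fundus image generator. Emulates the gross structure of a
# retinal photograph as seen by the preprocessing SOP and the classifier:
# a bright, radially shaded disc on a black field with optional black
# border padding, dark vessel-like curves, red blob lesions standing in
# for hemorrhages on DR-positive images, and blur/darkening degradations
# for the quality gate. Not a generative model of real fundus statistics.

#' Synthetic fundus specification
#'
#' @param side square image side in pixels (>= 32). Default 128.
#' @param border_width black padding frame in pixels. Default 8.
#' @param disc_color base RGB of the retinal disc. Default c(205, 120, 60),
#'   the warm orange of a fundus photograph.
#' @param vessel_count number of dark vessel-like curves. Default 4.
#' @param lesion_count_range integer `[min, max]` count of red blob lesions
#'   on DR images. Default c(3, 8).
#' @param lesion_radius_range lesion radius range in pixels. Default c(4, 9).
#' @param noise_sd additive Gaussian noise sd inside the disc (intensity
#'   units). Default 5.
#' @param blur_sigma Gaussian blur sigma applied to degraded-quality
#'   variants. Default 2.5.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(side = 128L, border_width = 8L,
                           disc_color = c(205, 120, 60),
                           vessel_count = 4L,
                           lesion_count_range = c(3L, 8L),
                           lesion_radius_range = c(4, 9),
                           noise_sd = 5, blur_sigma = 2.5) {
  stopifnot(side >= 32, border_width >= 0, length(disc_color) == 3,
            all(lesion_count_range >= 0), all(lesion_radius_range >= 0),
            noise_sd >= 0, blur_sigma >= 0)
  radius <- (side - 2 * border_width) / 2 - 1
  if (max(lesion_radius_range) >= radius / 2)
    stop("lesion radius too large for the retinal disc", call. = FALSE)
  structure(list(side = as.integer(side),
                 border_width = as.integer(border_width),
                 disc_color = disc_color,
                 vessel_count = as.integer(vessel_count),
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = lesion_radius_range,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 radius = radius),
            class = "synthetic_spec")
}

# Paint a filled disc of given color into img (H x W x 3), centered at
# (cy, cx) with radius r, only where inside_mask allows.
paint_blob <- function(img, cy, cx, r, color, inside = NULL) {
  S <- dim(img)[1L]
  d2 <- outer((seq_len(S) - 0.5 - cy)^2, (seq_len(S) - 0.5 - cx)^2, "+")
  hit <- d2 <= r^2
  if (!is.null(inside)) hit <- hit & inside
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[hit] <- color[ch]
    img[, , ch] <- pl
  }
  img
}

#' Generate one synthetic fundus image
#'
#' Deterministic for a given seed. DR-positive images (`label = 1`) carry
#' red blob lesions whose centers are recorded; quality degradations are
#' Gaussian blur (`usable`) or blur plus darkening (`reject`).
#'
#' @param spec a [synthetic_spec()].
#' @param label 0 (no DR) or 1 (DR).
#' @param quality_class one of `"good"`, `"usable"`, `"reject"`.
#' @param seed integer seed; the draw is bit-reproducible.
#' @return list with `image` (pixel image), `label`, `quality_class` and
#'   `lesion_centers` (k x 2 matrix of 0-based row/col centers; 0 rows when
#'   label is 0).
#' @export
generate_fundus <- function(spec = synthetic_spec(), label = 0L,
                            quality_class = c("good", "usable", "reject"),
                            seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), label %in% c(0L, 1L))
  quality_class <- match.arg(quality_class)
  with_seed(seed, {
    S <- spec$side
    ctr <- S / 2
    R <- spec$radius
    d2 <- outer((seq_len(S) - 0.5 - ctr)^2, (seq_len(S) - 0.5 - ctr)^2, "+")
    inside <- d2 <= R^2
    shade <- 1 - 0.35 * pmin(d2 / R^2, 1)        # radial falloff
    img <- array(0, dim = c(S, S, 3L))
    for (ch in 1:3) img[, , ch] <- spec$disc_color[ch] * shade * inside

    # optic-disc-like bright spot, off-center
    img <- paint_blob(img, ctr - 0.3 * R, ctr + 0.45 * R, 0.16 * R,
                      c(235, 200, 120), inside)

    # vessels: dark random-walk curves radiating from near the center
    if (spec$vessel_count > 0) {
      for (v in seq_len(spec$vessel_count)) {
        len <- max(4L, round(0.75 * R))
        ang <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(len, 0, 0.15))
        rr <- round(ctr + cumsum(sin(ang)))
        cc <- round(ctr + cumsum(cos(ang)))
        ok <- rr >= 1 & rr <= S & cc >= 1 & cc <= S
        rr <- rr[ok]; cc <- cc[ok]
        keep <- inside[cbind(rr, cc)]
        px <- cbind(rr[keep], cc[keep])
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[px] <- c(70, 30, 25)[ch]
          img[, , ch] <- pl
        }
      }
    }

    # lesions: red blobs fully inside the disc, centers recorded
    centers <- matrix(numeric(0), ncol = 2L,
                      dimnames = list(NULL, c("row", "col")))
    if (label == 1L) {
      k <- if (spec$lesion_count_range[1L] == spec$lesion_count_range[2L])
        spec$lesion_count_range[1L]
      else sample(spec$lesion_count_range[1L]:spec$lesion_count_range[2L], 1L)
      for (i in seq_len(k)) {
        r <- stats::runif(1, spec$lesion_radius_range[1L],
                          spec$lesion_radius_range[2L])
        rad <- (R - r - 1) * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        cy <- ctr + rad * sin(th)
        cx <- ctr + rad * cos(th)
        img <- paint_blob(img, cy, cx, r, c(120, 22, 22), inside)
        centers <- rbind(centers, c(cy - 0.5, cx - 0.5))  # 0-based centers
      }
    }

    # sensor noise inside the disc only; the digital border stays black
    if (spec$noise_sd > 0) {
      noise <- array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
      img <- img + noise * as.vector(inside)
    }
    img <- clamp255(round(img))

    if (quality_class != "good") {
      img <- blur_image(img, spec$blur_sigma)
      if (quality_class == "reject") img <- clamp255(round(img * 0.22))
    }
    list(image = as_pixel_image(img), label = as.integer(label),
         quality_class = quality_class, lesion_centers = centers)
  })
}

# Gaussian blur on the 0-255 raster.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  from_ebimage(EBImage::gblur(to_ebimage(img), sigma = sigma))
}

#' Generate a synthetic labeled dataset on disk
#'
#' Writes `n0` healthy and `n1` DR images as PNG, a Kaggle-dialect
#' `labels.csv` (`image,level`; level 0 for healthy, uniform 1-4 for DR),
#' and a `splits.json` manifest with disjoint train/val/test image ids.
#' `val_n` and `test_n` are total (balanced) split sizes; the remaining
#' images form the training split.
#'
#' @param spec a [synthetic_spec()].
#' @param n0,n1 number of healthy / DR images.
#' @param val_n,test_n even split sizes (half per class).
#' @param dir output directory, created if needed.
#' @param seed master seed; every image and the level draw derive from it.
#' @return invisibly, a list with `dir`, `labels` (data.frame) and `splits`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), n0, n1,
                             val_n = 0L, test_n = 0L, dir, seed = 1L) {
  stopifnot(n0 >= 1, n1 >= 1, val_n >= 0, test_n >= 0,
            val_n %% 2 == 0, test_n %% 2 == 0)
  if ((val_n + test_n) / 2 >= min(n0, n1))
    stop("n0/n1 too small for the requested val/test splits", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n0 + n1
  labels <- c(rep(0L, n0), rep(1L, n1))
  ids <- sprintf("img_%05d", seq_len(n))
  seeds <- derive_seeds(seed, n + 1L)
  levels <- with_seed(seeds[n + 1L], ifelse(labels == 0L, 0L,
                                            sample(1:4, n, replace = TRUE)))
  for (i in seq_len(n)) {
    s <- generate_fundus(spec, labels[i], "good", seed = seeds[i])
    write_image(s$image, file.path(dir, paste0(ids[i], ".png")))
  }
  lab_df <- data.frame(image = ids, level = levels)
  utils::write.csv(lab_df, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  splits <- with_seed(seeds[n + 1L] %% 1000003L + 1L, {
    by_class <- split(ids, labels)
    pick <- function(pool, k) sample(pool, k)
    val <- c(pick(by_class[["0"]], val_n / 2), pick(by_class[["1"]], val_n / 2))
    rest0 <- setdiff(by_class[["0"]], val)
    rest1 <- setdiff(by_class[["1"]], val)
    test <- c(pick(rest0, test_n / 2), pick(rest1, test_n / 2))
    train <- setdiff(ids, c(val, test))
    list(train = train, val = val, test = test)
  })
  jsonlite::write_json(splits, file.path(dir, "splits.json"))
  invisible(list(dir = dir, labels = lab_df, splits = splits))
}
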