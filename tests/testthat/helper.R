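# Shared fixtures and independent brute-force oracles. Oracles use naive
# loops on purpose: they must not share code with the implementation.

# Exhaustive clip mask: elementwise loop.
brute_mask <- function(gray, tol) {
  out <- matrix(0L, nrow(gray), ncol(gray))
  for (i in seq_len(nrow(gray)))
    for (j in seq_len(ncol(gray)))
      if (gray[i, j] > tol) out[i, j] <- 1L
  out
}

# Exhaustive bounding box: scan every row/column for any 1 (0-based,
# half-open).
brute_bbox <- function(mask) {
  rows <- integer(); cols <- integer()
  for (i in seq_len(nrow(mask)))
    if (any(mask[i, ] == 1L)) rows <- c(rows, i)
  for (j in seq_len(ncol(mask)))
    if (any(mask[, j] == 1L)) cols <- c(cols, j)
  if (length(rows) == 0L) return(NULL)
  list(r0 = min(rows) - 1L, r1 = max(rows), c0 = min(cols) - 1L,
       c1 = max(cols))
}

# Count pixels whose center lies inside the central disc of an L x L square.
brute_disc_count <- function(L) {
  n <- 0L
  for (i in 0:(L - 1L))
    for (j in 0:(L - 1L))
      if ((i + 0.5 - L / 2)^2 + (j + 0.5 - L / 2)^2 <= (L / 2)^2) n <- n + 1L
  n
}

# Direct CDF histogram equalization of one 0-255 integer vector.
brute_equalize <- function(q) {
  n <- length(q)
  cdf <- vapply(0:255, function(v) sum(q <= v), numeric(1))
  cdf_min <- min(cdf[cdf > 0])
  if (n == cdf_min) return(rep(0L, n))
  vapply(q, function(v) as.integer(round((cdf[v + 1] - cdf_min) /
                                           (n - cdf_min) * 255)), integer(1))
}

# A small random RGB raster.
random_raster <- function(side = 16L, seed = 1L) {
  set.seed(seed)
  array(sample(0:255, side * side * 3L, replace = TRUE),
        dim = c(side, side, 3L))
}

# A bright block framed by a black border.
framed_image <- function(side = 10L, border = 3L, value = 200) {
  img <- array(0, dim = c(side, side, 3L))
  core <- (border + 1L):(side - border)
  img[core, core, ] <- value
  img
}

# Tiny desk models, built once per session.
tiny_model <- local({
  cache <- list()
  function(revised = TRUE, side = 32L, width = 0.0625, seed = 7L,
           merge_op = "multiplication") {
    key <- paste(revised, side, width, seed, merge_op)
    if (is.null(cache[[key]]))
      cache[[key]] <<- drnet(model_config(side, width, init_seed = seed),
                             revised = revised,
                             fusion = fusion_spec(merge_op))
    cache[[key]]
  }
})

# Fresh empty scratch directory (caller unlinks it).
withr_like_tempdir <- function() {
  d <- tempfile("fundusdr-test-")
  dir.create(d)
  d
}

good_fundus <- function(seed = 11L, label = 0L, spec = synthetic_spec()) {
  generate_fundus(spec, label, "good", seed = seed)
}
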