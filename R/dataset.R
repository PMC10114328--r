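# Label-file reading, severity binarization and balanced split selection.
# The label dialect is the Kaggle DR CSV: columns `image,level`, severity
# level 0 (healthy) through 4 (proliferative DR); all four DR stages
# collapse to binary label 1.

#' Read a Kaggle-dialect label file
#'
#' @param path CSV file with header columns `image` and `level`.
#' @return data.frame with columns `image` (character), `level` (integer
#'   0-4) and `binary_label` (0/1).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image", "level") %in% names(df)))
    stop("label file must have columns `image` and `level`", call. = FALSE)
  lev <- suppressWarnings(as.integer(df$level))
  bad <- which(is.na(lev) | lev < 0L | lev > 4L)
  if (length(bad) > 0L)
    stop("invalid severity level in row ", bad[1L],
         " (image ", df$image[bad[1L]], "): must be an integer 0-4",
         call. = FALSE)
  dup <- df$image[duplicated(df$image)]
  if (length(dup) > 0L)
    stop("duplicate image id in label file: ", dup[1L], call. = FALSE)
  data.frame(image = as.character(df$image), level = lev,
             binary_label = binarize(lev), stringsAsFactors = FALSE)
}

#' Collapse a severity level to the binary DR label
#'
#' Level 0 (healthy) maps to 0; levels 1-4 (any DR stage) map to 1.
#'
#' @param level integer vector of severity levels 0-4.
#' @return integer vector of 0/1 labels.
#' @export
binarize <- function(level) {
  if (any(is.na(level) | level < 0 | level > 4))
    stop("severity level must be in 0-4", call. = FALSE)
  as.integer(level != 0)
}

#' Balanced split specification
#'
#' @param n_train_per_class training images drawn per binary class
#'   (the published selection used 1500).
#' @param n_val,n_test total validation / test sizes, balanced half per
#'   class (the published selection used 300 each).
#' @param seed sampling seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(n_train_per_class = 1500L, n_val = 300L,
                       n_test = 300L, seed = 1L) {
  stopifnot(n_train_per_class >= 1, n_val >= 1, n_test >= 1,
            n_val %% 2 == 0, n_test %% 2 == 0)
  structure(list(n_train_per_class = as.integer(n_train_per_class),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Draw disjoint balanced train/validation/test splits
#'
#' Seeded sampling without replacement: the training split holds
#' `n_train_per_class` images of each binary class; validation and test each
#' hold their totals balanced per class; the three sets are pairwise
#' disjoint by image id.
#'
#' @param records data.frame from [read_labels()].
#' @param spec a [split_spec()].
#' @return list of data.frames `train`, `val`, `test`.
#' @export
make_splits <- function(records, spec) {
  stopifnot(is.data.frame(records), inherits(spec, "split_spec"))
  ids0 <- records$image[records$binary_label == 0L]
  ids1 <- records$image[records$binary_label == 1L]
  need <- spec$n_train_per_class + spec$n_val / 2 + spec$n_test / 2
  for (cls in list(c("0", length(ids0)), c("1", length(ids1)))) {
    avail <- as.integer(cls[2L])
    if (avail < need)
      stop("class ", cls[1L], " has ", avail, " images but ", need,
           " are required (shortfall ", need - avail, ")", call. = FALSE)
  }
  sel <- with_seed(spec$seed, {
    pick <- function(pool, k) if (k == 0L) character() else sample(pool, k)
    tr <- c(pick(ids0, spec$n_train_per_class),
            pick(ids1, spec$n_train_per_class))
    rest0 <- setdiff(ids0, tr); rest1 <- setdiff(ids1, tr)
    va <- c(pick(rest0, spec$n_val / 2), pick(rest1, spec$n_val / 2))
    te <- c(pick(setdiff(rest0, va), spec$n_test / 2),
            pick(setdiff(rest1, va), spec$n_test / 2))
    list(train = tr, val = va, test = te)
  })
  lapply(sel, function(ids)
    records[match(ids, records$image), , drop = FALSE])
}

#' Write a split manifest as JSON
#'
#' @param splits list from [make_splits()].
#' @param path output `splits.json` path.
#' @return `path`, invisibly.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(lapply(splits, function(s)
    if (is.data.frame(s)) s$image else s), path)
  invisible(path)
}

#' Read a split manifest
#'
#' @param path `splits.json` path.
#' @return list of character vectors `train`, `val`, `test`.
#' @export
read_splits <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
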