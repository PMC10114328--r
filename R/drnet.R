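# The classifier: a 50-layer bottleneck residual network ("ResNet-50"
# geometry) whose stage-5 intermediate block outputs can be merged
# elementwise before a regularized sigmoid head (the "revised" structure),
# or left as the plain conv5_block3_out head (the original structure).
# Parameter containers are environments so the SGD step and the batch-norm
# running statistics mutate in place.

MERGE_OPS <- c("addition", "subtraction", "multiplication", "average", "maximum")
TAP_NAMES <- c("conv5_block1_out", "conv5_block2_out")

#' Fusion specification for the revised head
#'
#' Which two stage-5 block outputs are tapped and how they are merged
#' elementwise. The default, multiplication of `conv5_block1_out` with
#' `conv5_block2_out`, is the combination found to grade DR best.
#'
#' @param merge_op one of addition, subtraction, multiplication, average,
#'   maximum.
#' @param layer_a,layer_b tapped layer names (stage-5 block outputs 1 or 2).
#' @return object of class `fusion_spec`.
#' @export
fusion_spec <- function(merge_op = "multiplication",
                        layer_a = "conv5_block1_out",
                        layer_b = "conv5_block2_out") {
  if (!merge_op %in% MERGE_OPS)
    stop("unknown merge_op '", merge_op, "'; must be one of ",
         paste(MERGE_OPS, collapse = ", "), call. = FALSE)
  if (!layer_a %in% TAP_NAMES || !layer_b %in% TAP_NAMES)
    stop("fusion taps must be among ", paste(TAP_NAMES, collapse = ", "),
         call. = FALSE)
  structure(list(merge_op = merge_op, layer_a = layer_a, layer_b = layer_b),
            class = "fusion_spec")
}

#' Regularizer specification for the classification head
#'
#' An L2 penalty on the head's kernel and an L1 penalty on its activations,
#' both added to the training loss.
#'
#' @param kernel_l2 weight of the kernel L2 penalty (>= 0). Default 1e-4.
#' @param activity_l1 weight of the activity L1 penalty (>= 0). Default 1e-5.
#' @return object of class `regularizer_spec`.
#' @export
regularizer_spec <- function(kernel_l2 = 1e-4, activity_l1 = 1e-5) {
  if (kernel_l2 < 0 || activity_l1 < 0)
    stop("regularizer weights must be non-negative", call. = FALSE)
  structure(list(kernel_l2 = kernel_l2, activity_l1 = activity_l1),
            class = "regularizer_spec")
}

#' Model configuration
#'
#' @param input_side square input side in pixels; must be divisible by 32 so
#'   the stage-5 feature maps are well defined. Default 224.
#' @param width_multiplier channel width scaling in (0, 1]; 1 reproduces the
#'   standard ResNet-50 widths, smaller values give desk-scale models.
#' @param init_seed seed for the random weight initialization.
#' @return object of class `model_config`.
#' @export
model_config <- function(input_side = 224L, width_multiplier = 1,
                         init_seed = 1L) {
  if (input_side %% 32 != 0)
    stop("input_side must be divisible by 32 (got ", input_side, ")",
         call. = FALSE)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("width_multiplier must be in (0, 1]", call. = FALSE)
  structure(list(input_side = as.integer(input_side),
                 width_multiplier = width_multiplier,
                 init_seed = as.integer(init_seed)),
            class = "model_config")
}

make_conv <- function(Cin, Cout, k) {
  e <- new.env(parent = emptyenv())
  e$kind <- "conv"
  e$k <- k
  fan_in <- k * k * Cin
  e$W <- matrix(stats::rnorm(Cout * fan_in, 0, sqrt(2 / fan_in)), Cout, fan_in)
  e$vW <- matrix(0, Cout, fan_in)
  e
}

make_bn <- function(C) {
  e <- new.env(parent = emptyenv())
  e$kind <- "bn"
  e$gamma <- rep(1, C); e$beta <- rep(0, C)
  e$rmean <- rep(0, C); e$rvar <- rep(1, C)
  e$vgamma <- rep(0, C); e$vbeta <- rep(0, C)
  e$acc_mean <- rep(0, C); e$acc_var <- rep(0, C); e$acc_n <- 0L
  e
}

make_block <- function(Cin, Cmid, Cout, stride, project) {
  list(conv1 = make_conv(Cin, Cmid, 1L), bn1 = make_bn(Cmid),
       conv2 = make_conv(Cmid, Cmid, 3L), bn2 = make_bn(Cmid),
       conv3 = make_conv(Cmid, Cout, 1L), bn3 = make_bn(Cout),
       proj = if (project) list(conv = make_conv(Cin, Cout, 1L),
                                bn = make_bn(Cout)),
       stride = stride)
}

block_layers <- function(blk) {
  c(list(blk$conv1, blk$bn1, blk$conv2, blk$bn2, blk$conv3, blk$bn3),
    if (!is.null(blk$proj)) list(blk$proj$conv, blk$proj$bn))
}

#' Construct the (revised) residual network classifier
#'
#' Builds the bottleneck residual network with stages of 3/4/6/3 blocks and
#' named stage-5 outputs `conv5_block1_out` .. `conv5_block3_out`. With
#' `revised = TRUE` the head global-average-pools the elementwise merge of
#' the two fusion taps; with `revised = FALSE` it pools `conv5_block3_out`
#' (the original structure). Either way a single sigmoid unit with the
#' configured kernel-L2 and activity-L1 penalties produces the DR
#' probability. Weights are randomly initialized (He) from `init_seed`;
#' builds are bit-reproducible.
#'
#' @param cfg a [model_config()].
#' @param revised logical; use the merged-feature head.
#' @param fusion a [fusion_spec()].
#' @param reg a [regularizer_spec()].
#' @return object of class `drnet`.
#' @export
drnet <- function(cfg = model_config(), revised = TRUE,
                  fusion = fusion_spec(), reg = regularizer_spec()) {
  stopifnot(inherits(cfg, "model_config"), inherits(fusion, "fusion_spec"),
            inherits(reg, "regularizer_spec"))
  w <- cfg$width_multiplier
  ch <- function(base) max(1L, as.integer(round(base * w)))
  mids <- vapply(c(64, 128, 256, 512), ch, integer(1))
  outs <- vapply(c(256, 512, 1024, 2048), ch, integer(1))
  nblocks <- c(3L, 4L, 6L, 3L)
  strides <- c(1L, 2L, 2L, 2L)
  net <- with_seed(cfg$init_seed, {
    stem <- list(conv = make_conv(3L, ch(64), 7L), bn = make_bn(ch(64)))
    stages <- vector("list", 4L)
    Cin <- ch(64)
    for (si in 1:4) {
      blocks <- vector("list", nblocks[si])
      for (bi in seq_len(nblocks[si])) {
        first <- bi == 1L
        blocks[[bi]] <- make_block(Cin, mids[si], outs[si],
                                   stride = if (first) strides[si] else 1L,
                                   project = first)
        Cin <- outs[si]
      }
      stages[[si]] <- blocks
    }
    head_in <- outs[4L]
    head <- new.env(parent = emptyenv())
    head$kind <- "dense"
    head$w <- stats::rnorm(head_in, 0, sqrt(2 / (head_in + 1)))
    head$b <- 0
    head$vw <- rep(0, head_in); head$vb <- 0
    list(stem = stem, stages = stages, head = head)
  })
  layers <- c(list(net$stem$conv, net$stem$bn),
              unlist(lapply(net$stages,
                            function(st) unlist(lapply(st, block_layers),
                                                recursive = FALSE)),
                     recursive = FALSE),
              list(net$head))
  structure(list(cfg = cfg, revised = revised, fusion = fusion, reg = reg,
                 net = net, layers = layers),
            class = "drnet")
}

#' Build the plain ResNet-50 backbone classifier
#'
#' The original structure: head on `conv5_block3_out`. See [drnet()].
#'
#' @inheritParams drnet
#' @return a `drnet` with `revised = FALSE`.
#' @export
build_backbone <- function(cfg = model_config(), reg = regularizer_spec()) {
  drnet(cfg, revised = FALSE, reg = reg)
}

#' Build the revised model with merged stage-5 features
#'
#' @inheritParams drnet
#' @return a `drnet` with `revised = TRUE`.
#' @export
build_revised_model <- function(cfg = model_config(), fusion = fusion_spec(),
                                reg = regularizer_spec()) {
  drnet(cfg, revised = TRUE, fusion = fusion, reg = reg)
}

#' Merge two feature tensors elementwise
#'
#' @param a,b numeric arrays of identical shape.
#' @param op one of addition, subtraction, multiplication, average, maximum.
#' @return elementwise merged array.
#' @export
merge_features <- function(a, b, op = "multiplication") {
  if (!op %in% MERGE_OPS)
    stop("unknown merge op '", op, "'", call. = FALSE)
  da <- dim(a) %||% length(a); db <- dim(b) %||% length(b)
  if (!identical(da, db))
    stop("shape mismatch: a is [", paste(da, collapse = "x"),
         "], b is [", paste(db, collapse = "x"), "]", call. = FALSE)
  switch(op,
         addition = a + b,
         subtraction = a - b,
         multiplication = a * b,
         average = (a + b) / 2,
         maximum = pmax(a, b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Gradients of the merge w.r.t. both arguments (ties in maximum go to a).
merge_bwd <- function(dm, a, b, op) {
  switch(op,
         addition = list(da = dm, db = dm),
         subtraction = list(da = dm, db = -dm),
         multiplication = list(da = dm * b, db = dm * a),
         average = list(da = dm / 2, db = dm / 2),
         maximum = list(da = dm * (a >= b), db = dm * (b > a)))
}

#' Regularization penalty
#'
#' The conventional forms: `kernel_l2 * sum(w^2) + activity_l1 * sum(|a|)`.
#'
#' @param weights numeric array of kernel weights.
#' @param activations numeric array of layer outputs.
#' @param reg a [regularizer_spec()].
#' @return non-negative scalar.
#' @export
penalty <- function(weights, activations, reg = regularizer_spec()) {
  stopifnot(inherits(reg, "regularizer_spec"),
            all(is.finite(weights)), all(is.finite(activations)))
  reg$kernel_l2 * sum(weights^2) + reg$activity_l1 * sum(abs(activations))
}

# --- forward / backward through the whole network ---------------------------

block_fwd <- function(x, blk, training, refresh = FALSE) {
  c1 <- conv_fwd(x, blk$conv1$W, 1L, blk$stride, 0L)
  b1 <- bn_fwd(c1$out, blk$bn1, training, refresh = refresh)
  a1 <- relu(b1$out)
  c2 <- conv_fwd(a1, blk$conv2$W, 3L, 1L, 1L)
  b2 <- bn_fwd(c2$out, blk$bn2, training, refresh = refresh)
  a2 <- relu(b2$out)
  c3 <- conv_fwd(a2, blk$conv3$W, 1L, 1L, 0L)
  b3 <- bn_fwd(c3$out, blk$bn3, training, refresh = refresh)
  if (!is.null(blk$proj)) {
    cp <- conv_fwd(x, blk$proj$conv$W, 1L, blk$stride, 0L)
    bp <- bn_fwd(cp$out, blk$proj$bn, training, refresh = refresh)
    idp <- bp$out
  } else {
    cp <- NULL; bp <- NULL; idp <- x
  }
  out <- relu(b3$out + idp)
  list(out = out,
       cache = if (training && !refresh)
         list(c1 = c1, b1 = b1, a1 = a1, c2 = c2,
                                  b2 = b2, a2 = a2, c3 = c3, b3 = b3,
                                  cp = cp, bp = bp, out = out))
}

block_bwd <- function(dout, blk, cc) {
  dsum <- dout * (cc$out > 0)
  db3 <- bn_bwd(dsum, blk$bn3, cc$b3)
  g3 <- conv_bwd(db3, blk$conv3$W, cc$c3$Xc, cc$c3$in_dim, 1L, 1L, 0L)
  blk$conv3$gW <- g3$dW
  da2 <- g3$dX * (cc$a2 > 0)
  db2 <- bn_bwd(da2, blk$bn2, cc$b2)
  g2 <- conv_bwd(db2, blk$conv2$W, cc$c2$Xc, cc$c2$in_dim, 3L, 1L, 1L)
  blk$conv2$gW <- g2$dW
  da1 <- g2$dX * (cc$a1 > 0)
  db1 <- bn_bwd(da1, blk$bn1, cc$b1)
  g1 <- conv_bwd(db1, blk$conv1$W, cc$c1$Xc, cc$c1$in_dim, 1L, blk$stride, 0L)
  blk$conv1$gW <- g1$dW
  dx <- g1$dX
  if (!is.null(blk$proj)) {
    dbp <- bn_bwd(dsum, blk$proj$bn, cc$bp)
    gp <- conv_bwd(dbp, blk$proj$conv$W, cc$cp$Xc, cc$cp$in_dim,
                   1L, blk$stride, 0L)
    blk$proj$conv$gW <- gp$dW
    dx <- dx + gp$dX
  } else {
    dx <- dx + dsum
  }
  dx
}

# Forward pass over a batch x of dim (H, W, 3, N), inputs already scaled to
# [0, 1]. Returns probabilities plus (in training mode) every cache needed
# by model_bwd; `collect` asks for named block outputs.
model_fwd <- function(model, x, training = FALSE, collect = character(),
                      compute_all = FALSE, refresh = FALSE) {
  net <- model$net
  named <- list()
  cs <- conv_fwd(x, net$stem$conv$W, 7L, 2L, 3L)
  bs <- bn_fwd(cs$out, net$stem$bn, training, refresh = refresh)
  as_ <- relu(bs$out)
  pl <- pool_fwd(as_)
  h <- pl$out
  st_caches <- vector("list", 4L)
  want <- function(nm) compute_all || nm %in% collect
  for (si in 1:3) {
    blocks <- net$stages[[si]]
    bc <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      r <- block_fwd(h, blocks[[bi]], training, refresh)
      h <- r$out
      bc[[bi]] <- r$cache
      nm <- sprintf("conv%d_block%d_out", si + 1L, bi)
      if (want(nm)) named[[nm]] <- h
    }
    st_caches[[si]] <- bc
  }
  s5 <- net$stages[[4L]]
  r1 <- block_fwd(h, s5[[1L]], training, refresh)
  r2 <- block_fwd(r1$out, s5[[2L]], training, refresh)
  named[["conv5_block1_out"]] <- r1$out
  named[["conv5_block2_out"]] <- r2$out
  need3 <- !model$revised || compute_all || "conv5_block3_out" %in% collect
  r3 <- if (need3) block_fwd(r2$out, s5[[3L]], training, refresh)
  if (need3) named[["conv5_block3_out"]] <- r3$out
  if (model$revised) {
    a <- named[[model$fusion$layer_a]]
    b <- named[[model$fusion$layer_b]]
    feat <- merge_features(a, b, model$fusion$merge_op)
  } else {
    feat <- r3$out
  }
  g <- gap_fwd(feat)
  z <- colSums(g * net$head$w) + net$head$b
  prob <- sigmoid(z)
  list(prob = prob, z = z, g = g, feat_dim = dim(feat), named = named,
       caches = if (training && !refresh)
         list(cs = cs, bs = bs, as_ = as_, pl = pl, st = st_caches,
              r1 = r1, r2 = r2, r3 = r3))
}

# Backward pass. dz is dLoss/dz (length N). Fills gW/ggamma/gbeta/... on
# every layer environment reached by the head.
model_bwd <- function(model, x, fw, dz) {
  net <- model$net
  cc <- fw$caches
  g <- fw$g
  net$head$gw <- drop(g %*% dz) + 2 * model$reg$kernel_l2 * net$head$w
  net$head$gb <- sum(dz)
  dg <- outer(net$head$w, dz)
  dfeat <- gap_bwd(dg, fw$feat_dim)
  if (model$revised) {
    a <- fw$named[[model$fusion$layer_a]]
    b <- fw$named[[model$fusion$layer_b]]
    mb <- merge_bwd(dfeat, a, b, model$fusion$merge_op)
    zero <- array(0, dim = dim(a))
    d1 <- zero; d2 <- zero
    if (model$fusion$layer_a == "conv5_block1_out") d1 <- d1 + mb$da
    else d2 <- d2 + mb$da
    if (model$fusion$layer_b == "conv5_block1_out") d1 <- d1 + mb$db
    else d2 <- d2 + mb$db
    d1 <- d1 + block_bwd(d2, net$stages[[4L]][[2L]], cc$r2$cache)
    dh <- block_bwd(d1, net$stages[[4L]][[1L]], cc$r1$cache)
  } else {
    d3 <- block_bwd(dfeat, net$stages[[4L]][[3L]], cc$r3$cache)
    d2 <- block_bwd(d3, net$stages[[4L]][[2L]], cc$r2$cache)
    dh <- block_bwd(d2, net$stages[[4L]][[1L]], cc$r1$cache)
  }
  for (si in 3:1) {
    blocks <- net$stages[[si]]
    for (bi in rev(seq_along(blocks)))
      dh <- block_bwd(dh, blocks[[bi]], cc$st[[si]][[bi]])
  }
  dp <- pool_bwd(dh, cc$pl)
  ds <- dp * (cc$as_ > 0)
  dbs <- bn_bwd(ds, net$stem$bn, cc$bs)
  gs <- conv_bwd(dbs, net$stem$conv$W, cc$cs$Xc, cc$cs$in_dim, 7L, 2L, 3L)
  net$stem$conv$gW <- gs$dW
  invisible(NULL)
}

# One SGD-with-momentum step over every parameter environment. Layers the
# backward pass never reached (stage-5 block 3 of a revised model) carry no
# gradient and are left untouched.
sgd_step <- function(model, lr, mu = 0.9) {
  for (ly in model$layers) {
    if (ly$kind == "conv") {
      if (is.null(ly$gW)) next
      ly$vW <- mu * ly$vW - lr * ly$gW
      ly$W <- ly$W + ly$vW
    } else if (ly$kind == "bn") {
      if (is.null(ly$ggamma)) next
      ly$vgamma <- mu * ly$vgamma - lr * ly$ggamma
      ly$gamma <- ly$gamma + ly$vgamma
      ly$vbeta <- mu * ly$vbeta - lr * ly$gbeta
      ly$beta <- ly$beta + ly$vbeta
    } else {
      ly$vw <- mu * ly$vw - lr * ly$gw
      ly$w <- ly$w + ly$vw
      ly$vb <- mu * ly$vb - lr * ly$gb
      ly$b <- ly$b + ly$vb
    }
  }
  invisible(NULL)
}

# All trainable weights as a flat named list (for reproducibility checks
# and serialization).
drnet_weights <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    out[[i]] <- switch(ly$kind,
                       conv = list(W = ly$W),
                       bn = list(gamma = ly$gamma, beta = ly$beta,
                                 rmean = ly$rmean, rvar = ly$rvar),
                       list(w = ly$w, b = ly$b))
  }
  out
}

#' @export
print.drnet <- function(x, ...) {
  cat("Residual DR classifier (", if (x$revised) "revised" else "original",
      " structure)\n", sep = "")
  cat("  input:", x$cfg$input_side, "x", x$cfg$input_side,
      " width multiplier:", x$cfg$width_multiplier, "\n")
  if (x$revised)
    cat("  fusion:", x$fusion$merge_op, "of", x$fusion$layer_a, "and",
        x$fusion$layer_b, "\n")
  cat("  head: global average pool -> 1 sigmoid unit",
      sprintf("(kernel L2 %.1e, activity L1 %.1e)\n",
              x$reg$kernel_l2, x$reg$activity_l1))
  np <- sum(vapply(drnet_weights(x),
                   function(l) sum(vapply(l, length, integer(1))), numeric(1)))
  cat("  parameters:", format(np, big.mark = ","), "\n")
  invisible(x)
}

#' Predict DR probabilities for a batch of images
#'
#' @param object a `drnet` model.
#' @param newdata either a 4-d array (H, W, 3, N) of 0-255 images, a single
#'   pixel image, or a list of pixel images.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels at the
#'   0.5 threshold.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return numeric vector of length N.
#' @export
predict.drnet <- function(object, newdata, type = c("prob", "class"),
                          batch_size = 32L, ...) {
  type <- match.arg(type)
  x <- as_input_array(newdata, object$cfg$input_side)
  n <- dim(x)[4L]
  probs <- numeric(n)
  for (i0 in seq(1L, n, by = batch_size)) {
    i1 <- min(i0 + batch_size - 1L, n)
    fw <- model_fwd(object, x[, , , i0:i1, drop = FALSE], training = FALSE)
    probs[i0:i1] <- fw$prob
  }
  if (type == "class") as.integer(probs >= 0.5) else probs
}

# Coerce user-facing image input to the network tensor (values in [0, 1]).
as_input_array <- function(newdata, side) {
  if (is.list(newdata) && !is.array(newdata)) {
    imgs <- lapply(newdata, function(im) resize_image(as_pixel_image(im), side))
    x <- array(0, dim = c(side, side, 3L, length(imgs)))
    for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
    return(x / 255)
  }
  d <- dim(newdata)
  if (length(d) == 3L) {
    img <- resize_image(as_pixel_image(newdata), side)
    return(array(img / 255, dim = c(side, side, 3L, 1L)))
  }
  if (length(d) == 4L) {
    if (d[1L] != side || d[2L] != side)
      stop("batch array must be ", side, "x", side, " (got ",
           d[1L], "x", d[2L], ")", call. = FALSE)
    mx <- max(newdata)
    return(if (mx > 1.5) newdata / 255 else newdata)
  }
  stop("cannot interpret newdata as images", call. = FALSE)
}
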