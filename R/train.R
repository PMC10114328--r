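# Model fitting: SGD with momentum, per-epoch validation, plateau schedule
# on the validation loss, reproducible from a single seed.

# Deep copy of a drnet (parameter containers are environments, so fitting
# would otherwise mutate the caller's model).
clone_env <- function(e) {
  e2 <- new.env(parent = emptyenv())
  for (nm in ls(e, all.names = TRUE)) assign(nm, get(nm, envir = e), envir = e2)
  e2
}

clone_drnet <- function(model) {
  cb <- function(blk) {
    blk$conv1 <- clone_env(blk$conv1); blk$bn1 <- clone_env(blk$bn1)
    blk$conv2 <- clone_env(blk$conv2); blk$bn2 <- clone_env(blk$bn2)
    blk$conv3 <- clone_env(blk$conv3); blk$bn3 <- clone_env(blk$bn3)
    if (!is.null(blk$proj))
      blk$proj <- list(conv = clone_env(blk$proj$conv),
                       bn = clone_env(blk$proj$bn))
    blk
  }
  net <- model$net
  net$stem <- list(conv = clone_env(net$stem$conv), bn = clone_env(net$stem$bn))
  net$stages <- lapply(net$stages, function(st) lapply(st, cb))
  net$head <- clone_env(net$head)
  model$net <- net
  model$layers <- c(list(net$stem$conv, net$stem$bn),
                    unlist(lapply(net$stages,
                                  function(st) unlist(lapply(st, block_layers),
                                                      recursive = FALSE)),
                           recursive = FALSE),
                    list(net$head))
  model
}

#' Stack pixel images into a network input batch
#'
#' @param images list of pixel images (resized as needed).
#' @param side target square side.
#' @return array (side, side, 3, N) of 0-255 values.
#' @export
stack_images <- function(images, side) {
  x <- array(0, dim = c(side, side, 3L, length(images)))
  for (i in seq_along(images))
    x[, , , i] <- resize_image(as_pixel_image(images[[i]]), side)
  x
}

# Recompute every batch-norm layer's inference statistics with the current
# weights by forward passes over x (statistics recalibration; the momentum
# running averages lag badly after only a few dozen updates).
refresh_bn_stats <- function(model, x, batch_size = 32L) {
  for (ly in model$layers) {
    if (ly$kind == "bn") {
      ly$acc_mean[] <- 0; ly$acc_var[] <- 0; ly$acc_n <- 0L
    }
  }
  n <- dim(x)[4L]
  for (i0 in seq(1L, n, by = batch_size)) {
    i1 <- min(i0 + batch_size - 1L, n)
    model_fwd(model, x[, , , i0:i1, drop = FALSE], training = TRUE,
              refresh = TRUE)
  }
  for (ly in model$layers) {
    if (ly$kind == "bn" && ly$acc_n > 0L) {
      ly$rmean <- ly$acc_mean / ly$acc_n
      ly$rvar <- ly$acc_var / ly$acc_n
    }
  }
  invisible(NULL)
}

#' Fit the DR classifier
#'
#' Trains by mini-batch stochastic gradient descent with momentum. The loss
#' is mean binary cross-entropy plus the head's kernel-L2 and activity-L1
#' penalties. After each epoch the model is evaluated on the validation set
#' and the reduce-on-plateau schedule is stepped on the validation loss.
#' The run is bit-reproducible given `seed`; the input model is not
#' modified.
#'
#' @param object a [drnet()] model.
#' @param x training images: array (side, side, 3, N), values 0-255 or 0-1.
#' @param y training labels (0/1, length N).
#' @param validation list with elements `x` and `y` (same formats), disjoint
#'   from the training data.
#' @param epochs number of epochs. Default 70.
#' @param batch_size mini-batch size. Default 32.
#' @param schedule a [schedule_state()] (initial lr 0.01, factor 0.5).
#' @param momentum SGD momentum. Default 0.9.
#' @param seed shuffling seed.
#' @param verbose print one line per epoch.
#' @return object of class `drnet_fit` with elements `model` (trained copy),
#'   `history` (data.frame epoch/train_acc/train_loss/val_acc/val_loss/lr)
#'   and `schedule` (final state).
#' @export
fit_drnet <- function(object, x, y, validation, epochs = 70L,
                      batch_size = 32L, schedule = schedule_state(),
                      momentum = 0.9, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(object, "drnet"), epochs >= 1, batch_size >= 1)
  if (length(y) == 0L || is.null(x) || length(x) == 0L)
    stop("empty training set", call. = FALSE)
  if (length(validation$y) == 0L)
    stop("empty validation set", call. = FALSE)
  model <- clone_drnet(object)
  x <- as_input_array(x, model$cfg$input_side)
  vx <- as_input_array(validation$x, model$cfg$input_side)
  y <- as.numeric(y); vy <- as.numeric(validation$y)
  stopifnot(dim(x)[4L] == length(y), dim(vx)[4L] == length(vy))
  n <- length(y)
  reg <- model$reg
  epoch_seeds <- derive_seeds(seed, epochs)
  hist <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    lr_epoch <- schedule$lr
    idx <- with_seed(epoch_seeds[e], sample.int(n))
    acc_sum <- 0; loss_sum <- 0
    for (i0 in seq(1L, n, by = batch_size)) {
      take <- idx[i0:min(i0 + batch_size - 1L, n)]
      nb <- length(take)
      xb <- x[, , , take, drop = FALSE]
      yb <- y[take]
      fw <- model_fwd(model, xb, training = TRUE)
      p <- fw$prob
      pen <- penalty(model$net$head$w, p, reg)
      loss <- cross_entropy(yb, p) + pen
      dz <- (p - yb) / nb + reg$activity_l1 * p * (1 - p)
      model_bwd(model, xb, fw, dz)
      sgd_step(model, lr_epoch, momentum)
      acc_sum <- acc_sum + sum((p >= 0.5) == (yb == 1))
      loss_sum <- loss_sum + nb * loss
    }
    refresh_bn_stats(model, x, batch_size)
    vp <- predict.drnet(model, vx, batch_size = batch_size)
    val_loss <- cross_entropy(vy, vp) + penalty(model$net$head$w, vp, reg)
    val_acc <- accuracy(confusion_counts(vy, vp))
    hist[[e]] <- data.frame(epoch = e, train_acc = acc_sum / n,
                            train_loss = loss_sum / n,
                            val_acc = val_acc, val_loss = val_loss,
                            lr = lr_epoch)
    if (verbose)
      message(sprintf(
        "epoch %3d  acc %.4f loss %.4f | val acc %.4f loss %.4f | lr %.2e",
        e, acc_sum / n, loss_sum / n, val_acc, val_loss, lr_epoch))
    schedule <- step_on_plateau(schedule, val_loss)
  }
  structure(list(model = model, history = do.call(rbind, hist),
                 schedule = schedule, seed = seed),
            class = "drnet_fit")
}

#' Evaluate a model on a labeled test set
#'
#' Probabilities are thresholded at 0.5 into a confusion table; returns the
#' resulting accuracy and the mean cross-entropy of the raw probabilities.
#'
#' @param model a `drnet` or `drnet_fit`.
#' @param x test images (any format accepted by [predict.drnet()]).
#' @param y 0/1 labels.
#' @return list with `accuracy`, `loss` and `counts`.
#' @export
evaluate <- function(model, x, y) {
  if (inherits(model, "drnet_fit")) model <- model$model
  if (length(y) == 0L) stop("empty test set", call. = FALSE)
  p <- predict.drnet(model, x)
  counts <- confusion_counts(y, p)
  list(accuracy = accuracy(counts), loss = cross_entropy(y, p),
       counts = counts)
}

#' @export
predict.drnet_fit <- function(object, newdata, ...) {
  predict.drnet(object$model, newdata, ...)
}

#' @export
print.drnet_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat("Fitted DR classifier:", nrow(h), "epochs\n")
  cat(sprintf("  final train acc %.4f / loss %.4f\n",
              last$train_acc, last$train_loss))
  cat(sprintf("  final val   acc %.4f / loss %.4f (lr %.3e)\n",
              last$val_acc, last$val_loss, last$lr))
  invisible(x)
}

#' @export
summary.drnet_fit <- function(object, ...) {
  h <- object$history
  best <- h[which.max(h$val_acc), ]
  cat("Training history (", nrow(h), " epochs)\n", sep = "")
  print(h, row.names = FALSE)
  cat(sprintf("\nBest validation accuracy %.4f at epoch %d\n",
              best$val_acc, best$epoch))
  cat("Generalization gap (train - val accuracy, final epoch): ",
      sprintf("%.4f\n", h$train_acc[nrow(h)] - h$val_acc[nrow(h)]))
  invisible(object)
}

#' @export
coef.drnet_fit <- function(object, ...) {
  head <- object$model$net$head
  c(setNames(head$w, paste0("feature_", seq_along(head$w))),
    bias = head$b)
}

#' @export
plot.drnet_fit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss")
  invisible(x)
}

#' Desk-scale end-to-end learning benchmark on synthetic data
#'
#' Generates a balanced synthetic fundus set (lesion task), runs the
#' preprocessing SOP, trains a width-0.25 side-64 revised model with
#' multiplication fusion for 10 epochs, and reports the final validation
#' accuracy. This is the package's standing check that the full stack
#' (generator, SOP, network, schedule) learns.
#'
#' @param seed master seed (data, weights and shuffling all derive from it).
#' @param n_per_class images per class (default 100, i.e. a 200-image set).
#' @param val_fraction fraction held out for validation (default 0.2).
#' @param epochs training epochs (default 10).
#' @param input_side,width network geometry (defaults 64 and 0.25).
#' @param merge_op fusion operator (default multiplication).
#' @param verbose print per-epoch progress.
#' @return list with `fit` (the `drnet_fit`), `val_accuracy` and
#'   `val_loss` from the last epoch.
#' @export
run_synthetic_benchmark <- function(seed = 1L, n_per_class = 100L,
                                    val_fraction = 0.2, epochs = 10L,
                                    input_side = 64L, width = 0.25,
                                    merge_op = "multiplication",
                                    verbose = FALSE) {
  seeds <- derive_seeds(seed, 3L)
  spec <- synthetic_spec()
  n <- 2L * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  img_seeds <- derive_seeds(seeds[1L], n)
  cfg <- sop_config(output_side = input_side, quality = NULL)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_fundus(spec, labels[i], "good", seed = img_seeds[i])
    images[[i]] <- run_sop(s$image, cfg)$image
  }
  x <- stack_images(images, input_side)
  n_val <- round(n * val_fraction)
  # balanced validation split: alternate classes
  val_idx <- c(seq_len(n_val / 2), n_per_class + seq_len(n_val / 2))
  tr_idx <- setdiff(seq_len(n), val_idx)
  model <- drnet(model_config(input_side, width, init_seed = seeds[2L]),
                 revised = TRUE, fusion = fusion_spec(merge_op))
  fit <- fit_drnet(model,
                   x[, , , tr_idx, drop = FALSE], labels[tr_idx],
                   validation = list(x = x[, , , val_idx, drop = FALSE],
                                     y = labels[val_idx]),
                   epochs = epochs, batch_size = 32L,
                   seed = seeds[3L], verbose = verbose)
  h <- fit$history
  list(fit = fit, val_accuracy = h$val_acc[nrow(h)],
       val_loss = h$val_loss[nrow(h)])
}
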