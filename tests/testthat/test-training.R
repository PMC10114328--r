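test_that("accuracy matches its closed form and rejects empty tables", {
  expect_equal(accuracy(list(TP = 3, TN = 2, FP = 0, FN = 0)), 1.0)
  expect_equal(accuracy(list(TP = 0, TN = 0, FP = 2, FN = 3)), 0.0)
  expect_equal(accuracy(list(TP = 2, TN = 3, FP = 1, FN = 2)), 0.625)
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("confusion counts use the >= 0.5 decision rule", {
  y <- c(1, 0, 1, 0, 1)
  p <- c(0.9, 0.4, 0.5, 0.6, 0.1)
  cc <- confusion_counts(y, p)
  expect_equal(cc, list(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(accuracy(cc), 0.6)
  # threshold boundary: probability exactly 0.5 is called positive
  expect_equal(confusion_counts(1, 0.5)$TP, 1L)
  expect_error(confusion_counts(c(0, 2), c(0.1, 0.2)))
})

test_that("cross-entropy matches hand values and clips", {
  expect_equal(cross_entropy(c(0, 1), c(0.5, 0.5)), log(2))
  expect_equal(cross_entropy(1, 0.25), -log(0.25))
  expect_lte(cross_entropy(c(1, 0), c(1, 0)), 1e-6)   # clipped at 1e-7
  expect_equal(cross_entropy(1, 0), -log(1e-7))
  expect_error(cross_entropy(c(0, 1), 0.5), "2 vs 1")
})

test_that("metrics agree with independent elementwise recomputation", {
  set.seed(500)
  y <- rbinom(50, 1, 0.5)
  p <- runif(50)
  cc <- confusion_counts(y, p)
  acc_brute <- 0
  ce_brute <- 0
  for (i in seq_along(y)) {
    pred <- if (p[i] >= 0.5) 1 else 0
    if (pred == y[i]) acc_brute <- acc_brute + 1
    pi <- min(max(p[i], 1e-7), 1 - 1e-7)
    ce_brute <- ce_brute - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  expect_equal(accuracy(cc), acc_brute / 50)
  expect_equal(cross_entropy(y, p), ce_brute / 50)
})

test_that("plateau schedule cuts by the factor after patience stagnation", {
  st <- schedule_state()
  expect_equal(st$lr, 0.01)
  expect_equal(st$factor, 0.5)
  st <- step_on_plateau(st, 1.0)     # first observation: baseline
  expect_equal(st$lr, 0.01)
  st <- step_on_plateau(st, 0.5)     # improvement
  expect_equal(st$lr, 0.01)
  st <- step_on_plateau(st, 0.5)     # stagnant 1
  st <- step_on_plateau(st, 0.5001)  # stagnant 2 -> cut
  expect_equal(st$lr, 0.005)
  expect_equal(st$cuts, 1L)
  # an improvement smaller than min_delta does not reset stagnation
  st2 <- schedule_state(min_delta = 1e-2)
  st2 <- step_on_plateau(st2, 1.0)
  st2 <- step_on_plateau(st2, 1.0 - 5e-3)
  st2 <- step_on_plateau(st2, 1.0 - 9e-3)
  expect_equal(st2$lr, 0.005)
  expect_error(step_on_plateau(schedule_state(), NaN), "finite")
  expect_error(schedule_state(floor = 0))
})

test_that("a sustained plateau walks the rate down to the floor", {
  # closed form: with patience 2 the first epoch sets the baseline and then
  # every 2 stagnant epochs cut once -> cuts(E) = floor((E - 1) / 2)
  tr <- simulate_plateau(61)
  expect_equal(tr$lr[61], 0.01 * 0.5^30)
  expect_equal(tr$lr[61], 9.3132e-12, tolerance = 1e-4)
  expect_lte(tr$lr[61], 1e-11)
  for (e in c(1, 2, 3, 10, 25, 61))
    expect_equal(tr$lr[e], max(0.01 * 0.5^floor((e - 1) / 2), 1e-12))
  expect_true(all(diff(tr$lr) <= 0))
  # the floor is binding eventually
  tr2 <- simulate_plateau(200)
  expect_equal(tr2$lr[200], 1e-12)
})

test_that("fitting runs, records history, and is bit-reproducible", {
  m <- tiny_model(seed = 30L)
  w_before <- fundusdr:::drnet_weights(m)
  set.seed(301)
  n <- 8
  x <- array(runif(32 * 32 * 3 * n, 0, 255), dim = c(32, 32, 3, n))
  y <- rep(c(0, 1), n / 2)
  vx <- x[, , , 1:4, drop = FALSE]
  vy <- y[1:4]
  fit <- fit_drnet(m, x, y, validation = list(x = vx, y = vy),
                   epochs = 2, batch_size = 4, seed = 11)
  expect_s3_class(fit, "drnet_fit")
  h <- fit$history
  expect_equal(nrow(h), 2)
  expect_named(h, c("epoch", "train_acc", "train_loss", "val_acc",
                    "val_loss", "lr"))
  expect_true(all(h$train_acc >= 0 & h$train_acc <= 1))
  expect_true(all(is.finite(h$train_loss)))
  expect_true(all(diff(h$lr) <= 0))
  # the input model is untouched
  expect_identical(fundusdr:::drnet_weights(m), w_before)
  # bit-reproducible
  fit2 <- fit_drnet(m, x, y, validation = list(x = vx, y = vy),
                    epochs = 2, batch_size = 4, seed = 11)
  expect_identical(fundusdr:::drnet_weights(fit$model),
                   fundusdr:::drnet_weights(fit2$model))
  expect_identical(fit$history, fit2$history)
  # a different shuffling seed changes the outcome
  fit3 <- fit_drnet(m, x, y, validation = list(x = vx, y = vy),
                    epochs = 2, batch_size = 4, seed = 12)
  expect_false(identical(fit$history, fit3$history))

  expect_error(fit_drnet(m, x, numeric(0), validation = list(x = vx, y = vy)),
               "empty training")
  expect_error(fit_drnet(m, x, y, validation = list(x = vx, y = numeric(0))),
               "empty validation")
})

test_that("fitting a revised model leaves the unused stage-5 block intact", {
  m <- tiny_model(seed = 33L)
  set.seed(304)
  x <- array(runif(32 * 32 * 3 * 4, 0, 255), dim = c(32, 32, 3, 4))
  y <- c(0, 1, 0, 1)
  fit <- fit_drnet(m, x, y, validation = list(x = x, y = y),
                   epochs = 1, batch_size = 4, seed = 6)
  b3_before <- m$net$stages[[4]][[3]]$conv1$W
  b3_after <- fit$model$net$stages[[4]][[3]]$conv1$W
  expect_identical(b3_after, b3_before)
  # and the full forward (visualization path) still works after training
  act <- layer_activation(fit, x[, , , 1], "conv5_block3_out")
  expect_equal(dim(act), c(1, 1, 128))
})

test_that("evaluate reports accuracy and loss consistent with predict", {
  m <- tiny_model(seed = 31L)
  set.seed(302)
  x <- array(runif(32 * 32 * 3 * 6, 0, 255), dim = c(32, 32, 3, 6))
  y <- c(0, 1, 0, 1, 0, 1)
  ev <- evaluate(m, x, y)
  p <- predict(m, x)
  expect_equal(ev$accuracy, mean((p >= 0.5) == (y == 1)))
  expect_equal(ev$loss, cross_entropy(y, p))
  expect_equal(ev$counts, confusion_counts(y, p))
  expect_error(evaluate(m, x, numeric(0)), "empty test")
})

test_that("fit methods print, summarize, plot and expose coefficients", {
  m <- tiny_model(seed = 32L)
  set.seed(303)
  x <- array(runif(32 * 32 * 3 * 4, 0, 255), dim = c(32, 32, 3, 4))
  y <- c(0, 1, 0, 1)
  fit <- fit_drnet(m, x, y, validation = list(x = x, y = y),
                   epochs = 1, batch_size = 4, seed = 2)
  expect_output(print(fit), "1 epochs")
  expect_output(summary(fit), "Best validation accuracy")
  co <- coef(fit)
  expect_length(co, 129)          # 128 features + bias
  expect_named(co[129], "bias")
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
  expect_equal(predict(fit, x), predict(fit$model, x))
})
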