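test_that("configuration objects validate their inputs", {
  expect_error(model_config(input_side = 100), "divisible by 32.*100")
  expect_error(model_config(width_multiplier = 0), "\\(0, 1\\]")
  expect_error(model_config(width_multiplier = 1.5), "\\(0, 1\\]")
  expect_error(fusion_spec("concat"), "unknown merge_op")
  expect_error(fusion_spec(layer_a = "conv5_block3_out"), "taps")
  expect_error(regularizer_spec(kernel_l2 = -1), "non-negative")
  expect_s3_class(model_config(64, 0.25), "model_config")
})

test_that("merge operators match their closed forms", {
  a <- c(1, 2, 3); b <- c(2, -2, 4)
  expect_equal(merge_features(a, b, "addition"), c(3, 0, 7))
  expect_equal(merge_features(a, b, "subtraction"), c(-1, 4, -1))
  expect_equal(merge_features(a, b, "multiplication"), c(2, -4, 12))
  expect_equal(merge_features(a, b, "average"), c(1.5, 0, 3.5))
  expect_equal(merge_features(a, b, "maximum"), c(2, 2, 4))
  # matrix shape preserved
  A <- matrix(1:4, 2); B <- matrix(c(2, 0, 1, 3), 2)
  expect_equal(merge_features(A, B, "multiplication"),
               matrix(c(2, 0, 3, 12), 2))
  expect_error(merge_features(matrix(0, 2, 3), matrix(0, 3, 2), "addition"),
               "\\[2x3\\].*\\[3x2\\]")
  expect_error(merge_features(a, b, "division"), "unknown merge op")
  # algebraic relations among the operators
  expect_equal(merge_features(a, b, "average"),
               merge_features(a, b, "addition") / 2)
  expect_equal(merge_features(a, b, "subtraction"),
               -merge_features(b, a, "subtraction"))
  expect_equal(merge_features(a, b, "maximum"), merge_features(b, a, "maximum"))
})

test_that("penalty matches kernel-L2 plus activity-L1", {
  r1 <- regularizer_spec(kernel_l2 = 1, activity_l1 = 1)
  expect_equal(penalty(c(3, 4), numeric(0), r1), 25)
  expect_equal(penalty(numeric(0), c(-1, 0.5), r1), 1.5)
  expect_equal(penalty(c(3, 4), c(-1, 0.5), r1), 26.5)
  expect_equal(penalty(c(3, 4), c(-1, 0.5), regularizer_spec()),
               1e-4 * 25 + 1e-5 * 1.5)
  expect_equal(penalty(c(3, 4), c(-1, 0.5),
                       regularizer_spec(kernel_l2 = 0, activity_l1 = 0)), 0)
  expect_error(penalty(c(3, NA), 1, r1))
})

test_that("builds are seed-reproducible and seed-sensitive", {
  m1 <- drnet(model_config(32, 0.0625, init_seed = 5))
  m2 <- drnet(model_config(32, 0.0625, init_seed = 5))
  m3 <- drnet(model_config(32, 0.0625, init_seed = 6))
  expect_identical(drnet_weights(m1), drnet_weights(m2))
  expect_false(identical(m1$net$stem$conv$W, m3$net$stem$conv$W))
  expect_identical(predict(m1, random_raster(32, 1)),
                   predict(m2, random_raster(32, 1)))
})

test_that("forward pass has the documented geometry", {
  m <- tiny_model()           # side 32, width 0.0625
  x <- array(stats::runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  fw <- fundusdr:::model_fwd(m, x)
  # stage-5 spatial side is input / 32; channels are 2048 * width
  expect_equal(dim(fw$named$conv5_block1_out), c(1, 1, 128, 2))
  expect_equal(dim(fw$named$conv5_block2_out), c(1, 1, 128, 2))
  expect_equal(fw$feat_dim, c(1, 1, 128, 2))
  expect_length(fw$prob, 2)
  # sigmoid output; saturation to exactly 0/1 in double precision is allowed
  expect_true(all(is.finite(fw$prob) & fw$prob >= 0 & fw$prob <= 1))
  # revised forward skips block 3 unless asked for it
  expect_null(fw$named$conv5_block3_out)
  fw3 <- fundusdr:::model_fwd(m, x, collect = "conv5_block3_out")
  expect_equal(dim(fw3$named$conv5_block3_out), c(1, 1, 128, 2))

  m64 <- tiny_model(side = 64L, width = 0.25)
  x64 <- array(stats::runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  fw64 <- fundusdr:::model_fwd(m64, x64)
  expect_equal(dim(fw64$named$conv5_block1_out), c(2, 2, 512, 1))
})

test_that("full-width network produces the canonical 7x7x2048 stage-5 maps", {
  m <- drnet(model_config(224, 1, init_seed = 3))
  x <- array(stats::runif(224 * 224 * 3), dim = c(224, 224, 3, 1))
  fw <- fundusdr:::model_fwd(m, x)
  expect_equal(dim(fw$named$conv5_block1_out), c(7, 7, 2048, 1))
  expect_equal(dim(fw$named$conv5_block2_out), c(7, 7, 2048, 1))
  expect_equal(fw$feat_dim, c(7, 7, 2048, 1))
})

test_that("fusion algebra shows through the head", {
  x <- array(stats::runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  # multiplication is commutative in the taps
  ms <- drnet(model_config(32, 0.0625, init_seed = 9),
              fusion = fusion_spec("multiplication",
                                   layer_a = "conv5_block2_out",
                                   layer_b = "conv5_block1_out"))
  mo <- drnet(model_config(32, 0.0625, init_seed = 9),
              fusion = fusion_spec("multiplication"))
  expect_equal(fundusdr:::model_fwd(ms, x)$prob,
               fundusdr:::model_fwd(mo, x)$prob)
  # subtracting a tap from itself leaves only the head bias
  md <- drnet(model_config(32, 0.0625, init_seed = 9),
              fusion = fusion_spec("subtraction",
                                   layer_a = "conv5_block1_out",
                                   layer_b = "conv5_block1_out"))
  fw <- fundusdr:::model_fwd(md, x)
  expect_equal(fw$z, rep(md$net$head$b, 2))
  # original structure ignores the fusion taps
  morig <- build_backbone(model_config(32, 0.0625, init_seed = 9))
  fworig <- fundusdr:::model_fwd(morig, x)
  expect_equal(dim(fworig$named$conv5_block3_out), c(1, 1, 128, 2))
  expect_false(isTRUE(all.equal(fworig$prob, fw$prob)))
})

test_that("predict handles the documented input formats", {
  m <- tiny_model()
  img <- random_raster(32, 13)
  p1 <- predict(m, img)
  expect_length(p1, 1)
  p2 <- predict(m, list(img, img))
  expect_equal(p2, rep(p1, 2), tolerance = 1e-10)
  cls <- predict(m, list(img, img), type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
  x4 <- array(stats::runif(32 * 32 * 3 * 3), dim = c(32, 32, 3, 3))
  expect_length(predict(m, x4), 3)
  expect_error(predict(m, array(0, dim = c(16, 16, 3, 1))), "32x32")
  expect_output(print(m), "revised")
})

test_that("analytic gradients agree with central differences", {
  m <- drnet(model_config(32, 0.0625, init_seed = 21),
             reg = regularizer_spec(kernel_l2 = 1e-3, activity_l1 = 1e-3))
  # tame the random head so the sigmoid is unsaturated and the loss surface
  # is locally smooth (large steps would cross ReLU kinks downstream)
  m$net$head$w <- m$net$head$w * 0.02
  set.seed(77)
  x <- array(stats::runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  y <- c(0, 1)
  loss_now <- function() {
    p <- fundusdr:::model_fwd(m, x, training = TRUE)$prob
    cross_entropy(y, p) + penalty(m$net$head$w, p, m$reg)
  }
  fw <- fundusdr:::model_fwd(m, x, training = TRUE)
  p <- fw$prob
  dz <- (p - y) / 2 + m$reg$activity_l1 * p * (1 - p)
  fundusdr:::model_bwd(m, x, fw, dz)
  eps <- 1e-6
  num_grad <- function(env, field, idx) {
    w0 <- env[[field]][idx]
    env[[field]][idx] <- w0 + eps; up <- loss_now()
    env[[field]][idx] <- w0 - eps; dn <- loss_now()
    env[[field]][idx] <- w0
    (up - dn) / (2 * eps)
  }
  checks <- list(
    list(env = m$net$head, a = "gw", w = "w", idx = 3L),
    list(env = m$net$stages[[4]][[2]]$conv3, a = "gW", w = "W", idx = 5L),
    list(env = m$net$stages[[2]][[1]]$conv2, a = "gW", w = "W", idx = 2L),
    list(env = m$net$stages[[4]][[1]]$bn2, a = "ggamma", w = "gamma", idx = 1L),
    list(env = m$net$stages[[3]][[4]]$bn3, a = "gbeta", w = "beta", idx = 2L))
  for (ck in checks) {
    ana <- ck$env[[ck$a]][ck$idx]
    num <- num_grad(ck$env, ck$w, ck$idx)
    expect_equal(ana, num, tolerance = 1e-3)
  }
  # head bias
  b0 <- m$net$head$b
  m$net$head$b <- b0 + eps; up <- loss_now()
  m$net$head$b <- b0 - eps; dn <- loss_now()
  m$net$head$b <- b0
  expect_equal(m$net$head$gb, (up - dn) / (2 * eps), tolerance = 1e-3)
})
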