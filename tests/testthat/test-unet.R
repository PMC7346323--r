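tiny_cfg <- network_config(input_size = 16L, channels = c(4L, 6L),
                           batch_size = 2L, seed = 3L)

test_that("network shapes, ranges and parameter accounting", {
  cfg4 <- network_config(input_size = 256L,
                         channels = c(8L, 16L, 32L, 64L))
  # 4 levels = 3 poolings; deepest grid is input / 2^3
  expect_equal(256 / 2^(length(cfg4$channels) - 1), 32)
  expect_error(network_config(input_size = 100L,
                              channels = c(8L, 16L, 32L, 64L)),
               "divisible")

  m <- build_unet(tiny_cfg)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  fw <- fundoscreen:::unet_forward(m, x, train = TRUE)
  expect_equal(dim(fw$probs), c(16, 16, 2, 2))
  expect_true(all(fw$probs > 0 & fw$probs < 1))

  # removing the concatenating path shrinks deep encoder inputs by the
  # image channel count: 3 channels x (3x3 kernel) x out-width weights
  m_cp <- build_unet(tiny_cfg, concat_path = TRUE)
  m_plain <- build_unet(tiny_cfg, concat_path = FALSE)
  expect_equal(count_parameters(m_cp) - count_parameters(m_plain),
               3 * 9 * tiny_cfg$channels[2])
})

test_that("analytic gradients match numeric differentiation", {
  set.seed(5)
  m <- build_unet(tiny_cfg)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  q <- array(rbinom(16 * 16 * 2 * 2, 1, 0.3), c(16, 16, 2, 2))
  fw <- fundoscreen:::unet_forward(m, x, train = TRUE)
  fl <- fundoscreen:::fusion_loss_batch(fw$probs, q, tiny_cfg)
  gr <- fundoscreen:::unet_backward(m, fw$cache, fl$gz)
  loss_at <- function(model) {
    f <- fundoscreen:::unet_forward(model, x, train = TRUE)
    fundoscreen:::fusion_loss_batch(f$probs, q, tiny_cfg)$loss
  }
  h <- 1e-6
  for (nm in c("enc1_c1", "enc2_c2", "dec1_up", "dec1_c2", "head")) {
    for (idx in c(1, 5)) {
      m2 <- m
      m2$layers[[nm]]$w[idx] <- m2$layers[[nm]]$w[idx] + h
      expect_equal(gr[[nm]]$w[idx], (loss_at(m2) - fl$loss) / h,
                   tolerance = 1e-3)
    }
  }
  m2 <- m
  m2$layers[["enc1_b1"]]$gamma[2] <- m2$layers[["enc1_b1"]]$gamma[2] + h
  expect_equal(gr[["enc1_b1"]]$gamma[2], (loss_at(m2) - fl$loss) / h,
               tolerance = 1e-3)
})

test_that("a few steps of training reduce the loss, deterministically", {
  set.seed(8)
  train_set <- lapply(1:6, function(i) {
    od <- render_ellipse_mask(ellipse_params(c(8, 8), 5, 4, 0), c(16, 16))
    oc <- render_ellipse_mask(ellipse_params(c(8, 8), 2, 2, 0), c(16, 16))
    img <- array(0.2 + 0.02 * i, c(16, 16, 3))
    for (ch in 1:3) img[, , ch] <- img[, , ch] + 0.5 * od + 0.2 * oc
    list(image = img, od_mask = od, oc_mask = oc)
  })
  cfg <- network_config(input_size = 16L, channels = c(4L, 6L),
                        batch_size = 3L, learning_rate = 1e-2, seed = 9L)
  m1 <- train_unet(build_unet(cfg), train_set, epochs = 8)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])

  m2 <- train_unet(build_unet(cfg), train_set, epochs = 8)
  expect_identical(m1$history$train_loss, m2$history$train_loss)

  pr1 <- predict_unet(m1, train_set[[1]]$image)
  pr2 <- predict_unet(m1, train_set[[1]]$image)
  expect_identical(pr1, pr2)
  expect_true(all(pr1$od_prob >= 0 & pr1$od_prob <= 1))
  expect_error(train_unet(build_unet(cfg), list()), "empty")
  expect_error(predict_unet(m1, array(0, c(8, 8, 3))), "expects")
})

test_that("binarisation is per-channel, >= at ties, monotone in threshold", {
  probs <- list(od_prob = matrix(0.6, 4, 4), oc_prob = matrix(0.5, 4, 4))
  b <- binarize_probs(probs, 0.5)
  expect_true(all(b$od_mask == 1))
  expect_true(all(b$oc_mask == 1))  # ties are set
  set.seed(2)
  probs <- list(od_prob = matrix(runif(64), 8, 8),
                oc_prob = matrix(runif(64), 8, 8))
  lo <- binarize_probs(probs, 0.3); hi <- binarize_probs(probs, 0.7)
  expect_true(all(hi$od_mask <= lo$od_mask))
  expect_true(all(hi$oc_mask <= lo$oc_mask))
})

test_that("augmentation keeps image and masks geometrically consistent", {
  s <- fixture_samples("non-glaucoma", 4)
  roi <- crop_roi(s$image, s$od_center, 96)
  rows <- roi$origin[1]:(roi$origin[1] + roi$side - 1)
  cols <- roi$origin[2]:(roi$origin[2] + roi$side - 1)
  prep <- prepare_roi(roi$image_crop, s$od_mask[rows, cols],
                      s$oc_mask[rows, cols], size = 64L)
  for (seed in 1:5) {
    aug <- augment(prep$image, prep$od_mask, prep$oc_mask, seed = seed)
    expect_identical(sort(unique(as.vector(aug$od_mask))),
                     sort(unique(c(0L, 1L))))
    # area approximately preserved under flip/rotate/small affine
    expect_lt(abs(sum(aug$od_mask) - sum(prep$od_mask)) / sum(prep$od_mask),
              0.15)
    # the augmented cup stays inside the augmented disc (same transform)
    expect_gt(mean(aug$od_mask[aug$oc_mask == 1]), 0.98)
    expect_identical(aug, augment(prep$image, prep$od_mask, prep$oc_mask,
                                  seed = seed))
  }
})
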