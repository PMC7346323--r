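#' Segmentation network configuration
#'
#' Encoder-decoder network with a concatenating path: each encoder level
#' below the first receives the raw input, average-pooled to that level's
#' resolution, concatenated with the previous level's pooled features
#' (multi-scale inputs). The decoder mirrors the encoder with
#' nearest-neighbour up-convolutions and skip connections; the final 1x1
#' convolution emits two sigmoid channels (disc, cup) as independent
#' multi-label outputs.
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `2^(length(channels) - 1)`.
#' @param channels feature widths per level, shallow to deep.
#' @param lambda1,lambda2 fusion-loss weights for the disc and cup terms.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param class_weight positive-class weight in the cross-entropy term.
#' @param eps numerical floor for logarithms and the Dice denominator.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping; `Inf` (default) trains for the full schedule.
#' @param seed integer seed for initialisation and shuffling.
#' @return an object of class `network_config`.
#' @export
network_config <- function(input_size = 256L,
                           channels = c(32L, 64L, 128L, 256L),
                           lambda1 = 0.5, lambda2 = 0.5,
                           learning_rate = 1e-4, epochs = 500L,
                           batch_size = 8L, class_weight = 1,
                           eps = 1e-7, early_stop_patience = Inf,
                           seed = 1L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, length(channels) >= 2)
  poolings <- length(channels) - 1
  if (input_size %% 2^poolings != 0) {
    stop_fs("input_size %d not divisible by 2^%d", input_size, poolings)
  }
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 lambda1 = lambda1, lambda2 = lambda2,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weight = class_weight, eps = eps,
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "network_config")
}

# He-normal initialised convolution parameters.
init_conv <- function(cin, cout, k) {
  list(w = matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = rep(0, cout), k = k)
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

#' Build the segmentation network
#'
#' @param config a [network_config()].
#' @param in_channels input image channels (3 for RGB).
#' @param concat_path include the concatenating path (default `TRUE`);
#'   disabling it reproduces a plain U-shape encoder for comparisons.
#' @return an object of class `unet_model` holding parameters and batch
#'   normalisation state.
#' @export
build_unet <- function(config, in_channels = 3L, concat_path = TRUE) {
  L <- length(config$channels)
  ch <- config$channels
  with_seed(config$seed, {
    layers <- list()
    prev <- in_channels
    for (i in seq_len(L)) {          # encoder (level L = bottleneck)
      cin <- if (i == 1) prev else ch[i - 1] + (if (concat_path) in_channels else 0)
      layers[[paste0("enc", i, "_c1")]] <- init_conv(cin, ch[i], 3)
      layers[[paste0("enc", i, "_b1")]] <- init_bn(ch[i])
      layers[[paste0("enc", i, "_c2")]] <- init_conv(ch[i], ch[i], 3)
      layers[[paste0("enc", i, "_b2")]] <- init_bn(ch[i])
    }
    for (i in rev(seq_len(L - 1))) { # decoder
      layers[[paste0("dec", i, "_up")]] <- init_conv(ch[i + 1], ch[i], 3)
      layers[[paste0("dec", i, "_bu")]] <- init_bn(ch[i])
      layers[[paste0("dec", i, "_c1")]] <- init_conv(2 * ch[i], ch[i], 3)
      layers[[paste0("dec", i, "_b1")]] <- init_bn(ch[i])
      layers[[paste0("dec", i, "_c2")]] <- init_conv(ch[i], ch[i], 3)
      layers[[paste0("dec", i, "_b2")]] <- init_bn(ch[i])
    }
    layers[["head"]] <- init_conv(ch[1], 2L, 1)
    structure(list(layers = layers, config = config,
                   in_channels = in_channels, concat_path = concat_path),
              class = "unet_model")
  })
}

#' Number of trainable parameters
#' @param model a `unet_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (!is.null(l$w)) length(l$w) + length(l$b)
    else length(l$gamma) + length(l$beta)
  }, 0))
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

relu_fwd <- function(x) x * (x > 0)

# Forward pass. x: (H, W, C, N) array. In training mode BN uses batch
# statistics and the cache needed for backprop is stored.
unet_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  L <- length(cfg$channels)
  cache <- list(inputs = list())
  run <- function(name, a) {
    l <- model$layers[[name]]
    if (!is.null(l$w)) {
      cache$inputs[[name]] <<- a
      conv_fwd(a, l$w, l$b, l$k)
    } else {
      if (train) {
        r <- bn_fwd(a, l$gamma, l$beta, 1e-5)
        cache$inputs[[name]] <<- list(x = a, mean = r$mean, var = r$var)
        r$y
      } else {
        bn_infer(a, l$gamma, l$beta, l$run_mean, l$run_var, 1e-5)
      }
    }
  }
  block <- function(tag, a) {
    a <- run(paste0(tag, "_c1"), a); a <- run(paste0(tag, "_b1"), a)
    cache$inputs[[paste0(tag, "_r1")]] <<- a <- relu_fwd(a)
    a <- run(paste0(tag, "_c2"), a); a <- run(paste0(tag, "_b2"), a)
    cache$inputs[[paste0(tag, "_r2")]] <<- a <- relu_fwd(a)
    a
  }
  skips <- list(); pool_idx <- list(); scaled_input <- x
  a <- x
  for (i in seq_len(L)) {
    if (i > 1) {
      p <- maxpool2_fwd(a)
      pool_idx[[i]] <- list(idx = p$idx, dim = dim(a))
      scaled_input <- avgpool2_fwd(scaled_input)
      a <- if (model$concat_path) concat4(p$y, scaled_input) else p$y
      cache$enc_in_ch[[i]] <- dim(p$y)[3]
    }
    a <- block(paste0("enc", i), a)
    if (i < L) skips[[i]] <- a
  }
  for (i in rev(seq_len(L - 1))) {
    a <- upsample2_fwd(a)
    a <- run(paste0("dec", i, "_up"), a); a <- run(paste0("dec", i, "_bu"), a)
    cache$inputs[[paste0("dec", i, "_ru")]] <- a <- relu_fwd(a)
    a <- concat4(a, skips[[i]])
    a <- block(paste0("dec", i), a)
  }
  z <- run("head", a)
  probs <- 1 / (1 + exp(-z))
  cache$pool_idx <- pool_idx
  list(probs = probs, z = z, cache = cache)
}

# Backward pass from the gradient w.r.t. the pre-sigmoid logits.
unet_backward <- function(model, cache, gz) {
  cfg <- model$config
  L <- length(cfg$channels)
  grads <- list()
  back <- function(name, g) {
    l <- model$layers[[name]]
    if (!is.null(l$w)) {
      r <- conv_bwd(cache$inputs[[name]], l$w, g, l$k)
      grads[[name]] <<- list(w = r$gw, b = r$gb)
      r$gx
    } else {
      s <- cache$inputs[[name]]
      r <- bn_bwd(s$x, g, l$gamma, s$mean, s$var, 1e-5)
      grads[[name]] <<- list(gamma = r$ggamma, beta = r$gbeta)
      r$gx
    }
  }
  block_bwd <- function(tag, g) {
    g <- g * (cache$inputs[[paste0(tag, "_r2")]] > 0)
    g <- back(paste0(tag, "_b2"), g); g <- back(paste0(tag, "_c2"), g)
    g <- g * (cache$inputs[[paste0(tag, "_r1")]] > 0)
    g <- back(paste0(tag, "_b1"), g); g <- back(paste0(tag, "_c1"), g)
    g
  }
  g <- back("head", gz)
  gskips <- list()
  for (i in seq_len(L - 1)) {        # decoder in reverse build order
    g <- block_bwd(paste0("dec", i), g)
    nup <- dim(cache$inputs[[paste0("dec", i, "_ru")]])[3]
    gskips[[i]] <- g[, , (nup + 1):(dim(g)[3]), , drop = FALSE]
    g <- g[, , seq_len(nup), , drop = FALSE]
    g <- g * (cache$inputs[[paste0("dec", i, "_ru")]] > 0)
    g <- back(paste0("dec", i, "_bu"), g); g <- back(paste0("dec", i, "_up"), g)
    g <- upsample2_bwd(g)
  }
  for (i in rev(seq_len(L))) {       # encoder in reverse
    g <- block_bwd(paste0("enc", i), g)
    if (i == 1) break
    if (model$concat_path) {
      nf <- cache$enc_in_ch[[i]]
      g <- g[, , seq_len(nf), , drop = FALSE]   # drop scaled-input channels
    }
    g <- maxpool2_bwd(g, cache$pool_idx[[i]]$idx, cache$pool_idx[[i]]$dim)
    g <- g + gskips[[i - 1]]
  }
  grads
}

# Fusion-loss value and logit gradient for a batch. probs/q: (H,W,2,N).
fusion_loss_batch <- function(probs, q, cfg) {
  eps <- cfg$eps
  n <- dim(probs)[4]
  lam <- c(cfg$lambda1, cfg$lambda2)
  w <- cfg$class_weight
  loss <- 0
  gz <- array(0, dim(probs))
  for (ch in 1:2) {
    for (i in seq_len(n)) {
      p <- probs[, , ch, i]; qq <- q[, , ch, i]
      m <- length(p)
      pc <- pmin(pmax(p, eps), 1 - eps)
      ce <- -mean(w * qq * log(pc) + (1 - qq) * log(1 - pc))
      dce_dp <- (-w * qq / pc + (1 - qq) / (1 - pc)) / m
      den <- sum(p^2) + sum(qq^2) + eps
      num <- 2 * sum(p * qq)
      dice <- -num / den
      ddice_dp <- (-2 * qq * den + num * 2 * p) / den^2
      loss <- loss + lam[ch] * (ce + dice) / n
      gz[, , ch, i] <- lam[ch] * (dce_dp + ddice_dp) * p * (1 - p) / n
    }
  }
  list(loss = loss, gz = gz)
}

#' Binary cross-entropy loss of a probability mask
#'
#' Two-term binary cross-entropy averaged over pixels, with an optional
#' positive-class weight; probabilities are clipped away from 0 and 1.
#'
#' @param prob probability matrix in `[0, 1]`.
#' @param truth binary matrix of the same size.
#' @param class_weight weight on the positive term, default 1.
#' @param eps clipping floor.
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(prob, truth, class_weight = 1, eps = 1e-7) {
  if (!identical(dim(prob), dim(truth))) stop_fs("grids differ")
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(class_weight * truth * log(p) + (1 - truth) * log(1 - p))
}

#' Soft Dice loss of a probability mask
#'
#' `-(2 sum(p q)) / (sum(p^2) + sum(q^2) + eps)`: -1 at perfect overlap,
#' 0 for disjoint masks.
#'
#' @inheritParams cross_entropy_loss
#' @return scalar in `(-1, 0]`.
#' @export
dice_loss <- function(prob, truth, eps = 1e-7) {
  if (!identical(dim(prob), dim(truth))) stop_fs("grids differ")
  -(2 * sum(prob * truth)) / (sum(prob^2) + sum(truth^2) + eps)
}

#' Multi-label fusion loss
#'
#' `L = lambda1 (L_CE^disc + L_dice^disc) + lambda2 (L_CE^cup + L_dice^cup)`,
#' the training objective combining weighted binary cross-entropy and soft
#' Dice over the two output channels.
#'
#' @param od_prob,oc_prob predicted probability matrices.
#' @param od_truth,oc_truth binary ground-truth masks.
#' @param lambda1,lambda2 channel weights, default 0.5 each.
#' @param class_weight,eps see [cross_entropy_loss()].
#' @return scalar; bounded below by `-(lambda1 + lambda2)`.
#' @export
fusion_loss <- function(od_prob, oc_prob, od_truth, oc_truth,
                        lambda1 = 0.5, lambda2 = 0.5, class_weight = 1,
                        eps = 1e-7) {
  lambda1 * (cross_entropy_loss(od_prob, od_truth, class_weight, eps) +
               dice_loss(od_prob, od_truth, eps)) +
    lambda2 * (cross_entropy_loss(oc_prob, oc_truth, class_weight, eps) +
                 dice_loss(oc_prob, oc_truth, eps))
}

# Stack a list of samples (image, od_mask, oc_mask) into batch arrays.
stack_batch <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], 3, n))
  q <- array(0, c(d[1], d[2], 2, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    q[, , 1, i] <- samples[[i]]$od_mask
    q[, , 2, i] <- samples[[i]]$oc_mask
  }
  list(x = x, q = q)
}

#' Resize a sample to the network input grid
#'
#' Bilinear for the image, nearest-neighbour for the masks so they stay
#' binary.
#'
#' @param image H x W x 3 array.
#' @param od_mask,oc_mask binary matrices (optional).
#' @param size target side.
#' @return list with `image` and, when given, `od_mask`, `oc_mask`.
#' @export
prepare_roi <- function(image, od_mask = NULL, oc_mask = NULL, size) {
  rs_img <- function(m) from_ebimage(EBImage::resize(as_ebimage(m), w = size,
                                                     h = size))
  rs_mask <- function(m) {
    r <- from_ebimage(EBImage::resize(as_ebimage(m * 1.0), w = size, h = size,
                                      filter = "none"))
    matrix(as.integer(r > 0.5), size, size)
  }
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- rs_img(image[, , ch])
  out <- list(image = img)
  if (!is.null(od_mask)) out$od_mask <- rs_mask(od_mask)
  if (!is.null(oc_mask)) out$oc_mask <- rs_mask(oc_mask)
  out
}

#' Seeded augmentation of an ROI/mask pair
#'
#' Random horizontal/vertical flips, rotation, brightness/contrast/
#' saturation jitter (image only) and a small random affine
#' translation+scale. The identical geometric transform is applied to the
#' image and both masks; masks are resampled nearest-neighbour so they
#' stay binary.
#'
#' @param image H x W x 3 array.
#' @param od_mask,oc_mask binary matrices.
#' @param seed integer seed.
#' @param max_rotation maximum absolute rotation in degrees.
#' @return list with augmented `image`, `od_mask`, `oc_mask`.
#' @export
augment <- function(image, od_mask, oc_mask, seed, max_rotation = 15) {
  with_seed(seed, {
    H <- nrow(od_mask); W <- ncol(od_mask)
    hflip <- runif(1) < 0.5; vflip <- runif(1) < 0.5
    ang <- runif(1, -max_rotation, max_rotation)
    shift <- runif(2, -0.05, 0.05) * c(H, W)
    scale <- runif(1, 0.95, 1.05)
    bright <- runif(1, -0.08, 0.08); contr <- runif(1, 0.9, 1.1)
    satur <- runif(1, 0.9, 1.1)
    geom <- function(m, mask) {
      im <- as_ebimage(m * 1.0)
      if (hflip) im <- EBImage::flop(im)   # mirror columns
      if (vflip) im <- EBImage::flip(im)   # mirror rows
      flt <- if (mask) "none" else "bilinear"
      im <- EBImage::rotate(im, ang, output.dim = c(W, H), filter = flt,
                            bg.col = 0)
      ctr <- c((W + 1) / 2, (H + 1) / 2)   # EBImage (x, y)
      mtx <- rbind(c(scale, 0), c(0, scale),
                   c(ctr[1] * (1 - scale) + shift[2],
                     ctr[2] * (1 - scale) + shift[1]))
      im <- EBImage::affine(im, mtx, filter = flt, bg.col = 0,
                            output.dim = c(W, H))
      from_ebimage(im)
    }
    out_img <- array(0, c(H, W, 3))
    for (ch in 1:3) out_img[, , ch] <- geom(image[, , ch], mask = FALSE)
    lum <- (rgb_to_gray(out_img) - 0.5) * contr + 0.5 + bright
    for (ch in 1:3) {
      pl <- (out_img[, , ch] - 0.5) * contr + 0.5 + bright
      out_img[, , ch] <- clip01(lum + satur * (pl - lum))
    }
    list(image = out_img,
         od_mask = matrix(as.integer(geom(od_mask, TRUE) > 0.5), H, W),
         oc_mask = matrix(as.integer(geom(oc_mask, TRUE) > 0.5), H, W))
  })
}

#' Train the segmentation network
#'
#' Adam optimisation of the fusion loss, with seeded shuffling and optional
#' per-epoch augmentation and early stopping on the validation loss.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param train_set list of samples: each a list with `image`
#'   (H x W x 3 at the configured input size), `od_mask`, `oc_mask`.
#' @param val_set optional validation list in the same format.
#' @param epochs override of the configured epoch count.
#' @param augment_data apply [augment()] with a fresh seed each epoch.
#' @param verbose print a line per `verbose` epochs (0 = silent).
#' @return the trained model, with a `history` data frame attached.
#' @export
train_unet <- function(model, train_set, val_set = NULL, epochs = NULL,
                       augment_data = FALSE, verbose = 0) {
  cfg <- model$config
  if (length(train_set) == 0) stop_fs("empty training set")
  if (is.null(epochs)) epochs <- cfg$epochs
  opt <- adam_init(model)
  momentum <- 0.1
  history <- NULL
  best_val <- Inf; wait <- 0; best_layers <- NULL
  val_batch <- if (!is.null(val_set)) stack_batch(val_set)
  step <- 0
  for (ep in seq_len(epochs)) {
    ord <- with_seed(cfg$seed + ep, sample(length(train_set)))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      batch_samples <- train_set[idx]
      if (augment_data) {
        batch_samples <- lapply(seq_along(idx), function(j) {
          s <- batch_samples[[j]]
          augment(s$image, s$od_mask, s$oc_mask,
                  seed = cfg$seed + ep * 10000L + idx[j])
        })
      }
      b <- stack_batch(batch_samples)
      fw <- unet_forward(model, b$x, train = TRUE)
      # update BN running stats
      for (nm in names(model$layers)) {
        if (!is.null(model$layers[[nm]]$gamma)) {
          s <- fw$cache$inputs[[nm]]
          model$layers[[nm]]$run_mean <-
            (1 - momentum) * model$layers[[nm]]$run_mean + momentum * s$mean
          model$layers[[nm]]$run_var <-
            (1 - momentum) * model$layers[[nm]]$run_var + momentum * s$var
        }
      }
      fl <- fusion_loss_batch(fw$probs, b$q, cfg)
      grads <- unet_backward(model, fw$cache, fl$gz)
      step <- step + 1
      model <- adam_step(model, grads, opt, step, cfg$learning_rate)
      ep_loss <- ep_loss + fl$loss; nb <- nb + 1
    }
    val_loss <- NA_real_
    if (!is.null(val_set)) {
      vf <- unet_forward(model, val_batch$x, train = FALSE)
      val_loss <- fusion_loss_batch(vf$probs, val_batch$q, cfg)$loss
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; wait <- 0
        if (is.finite(cfg$early_stop_patience)) best_layers <- model$layers
      } else wait <- wait + 1
    }
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = ep_loss / nb,
                                         val_loss = val_loss))
    if (verbose > 0 && ep %% verbose == 0) {
      message(sprintf("epoch %d: train %.4f val %.4f", ep,
                      ep_loss / nb, val_loss))
    }
    if (is.finite(cfg$early_stop_patience) && wait >= cfg$early_stop_patience) {
      if (!is.null(best_layers)) model$layers <- best_layers
      break
    }
  }
  model$history <- history
  model
}

adam_init <- function(model) {
  e <- new.env()
  e$m <- list(); e$v <- list()
  e
}

adam_step <- function(model, grads, opt, step, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (p in names(grads[[nm]])) {
      key <- paste0(nm, ".", p)
      tgt <- if (p %in% c("w", "b")) p else p   # gamma/beta named directly
      g <- grads[[nm]][[p]]
      if (is.null(opt$m[[key]])) { opt$m[[key]] <- g * 0; opt$v[[key]] <- g * 0 }
      opt$m[[key]] <- beta1 * opt$m[[key]] + (1 - beta1) * g
      opt$v[[key]] <- beta2 * opt$v[[key]] + (1 - beta2) * g^2
      mh <- opt$m[[key]] / (1 - beta1^step)
      vh <- opt$v[[key]] / (1 - beta2^step)
      model$layers[[nm]][[tgt]] <- model$layers[[nm]][[tgt]] -
        lr * mh / (sqrt(vh) + eps)
    }
  }
  model
}

#' Segment an ROI with a trained network
#'
#' Single deterministic forward pass in inference mode (batch-norm running
#' statistics).
#'
#' @param model trained `unet_model`.
#' @param roi H x W x 3 array at the configured input size.
#' @return list with `od_prob` and `oc_prob` matrices in `[0, 1]`.
#' @export
predict_unet <- function(model, roi) {
  size <- model$config$input_size
  if (!all(dim(roi)[1:2] == size)) {
    stop_fs("ROI is %dx%d but the network expects %dx%d",
            dim(roi)[1], dim(roi)[2], size, size)
  }
  x <- array(roi, c(size, size, 3, 1))
  fw <- unet_forward(model, x, train = FALSE)
  list(od_prob = fw$probs[, , 1, 1], oc_prob = fw$probs[, , 2, 1])
}

#' Threshold probability masks into binary masks
#'
#' Channels are thresholded independently (multi-label outputs); a pixel
#' exactly at the threshold is set (>= rule).
#'
#' @param probs list with `od_prob`, `oc_prob`.
#' @param threshold in (0, 1), default 0.5.
#' @return list with `od_mask`, `oc_mask` 0/1 matrices.
#' @export
binarize_probs <- function(probs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  list(od_mask = matrix(as.integer(probs$od_prob >= threshold),
                        nrow(probs$od_prob), ncol(probs$od_prob)),
       oc_mask = matrix(as.integer(probs$oc_prob >= threshold),
                        nrow(probs$oc_prob), ncol(probs$oc_prob)))
}
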