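make_noise_table <- function(n = 60, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rbinom(n, 1, 0.5)
  list(x = x, y = y)
}

test_that("variance filter drops constants and keeps spread features", {
  set.seed(4)
  x <- cbind(const = rep(1, 100), bern = rbinom(100, 1, 0.5),
             unif = runif(100))
  keep <- variance_filter(x, threshold = 0.01)
  expect_false("const" %in% keep)
  expect_true("bern" %in% keep)   # scaled variance 0.25 > 0.01
  keep0 <- variance_filter(x, threshold = 0)
  expect_setequal(keep0, c("const", "bern", "unif"))  # threshold 0 keeps all
  expect_error(variance_filter(cbind(a = rep(2, 5)), 0.01), "every feature")
})

test_that("correlation filter drops one member of redundant pairs", {
  tb <- make_noise_table(200, 4, seed = 2)
  x <- cbind(tb$x, dup = tb$x[, 1], neg = -tb$x[, 2])
  y <- as.integer(tb$x[, 1] > 0)
  keep <- correlation_filter(x, y, threshold = 0.95)
  expect_equal(sum(c("f1", "dup") %in% keep), 1)
  expect_equal(sum(c("f2", "neg") %in% keep), 1)
  # independent features survive a high threshold at large n
  keep2 <- correlation_filter(tb$x, tb$y, threshold = 0.95)
  expect_setequal(keep2, colnames(tb$x))
})

test_that("forest ranking finds the informative feature and is seeded", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed + 100)
    n <- 80
    y <- rbinom(n, 1, 0.5)
    x <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    x[, 7] <- y * 2 + rnorm(n, 0, 0.3)   # the informative column
    rk <- rank_features_rf(x, y, seed = seed)
    hits <- hits + (rk$feature[1] == "f7")
  }
  expect_gte(hits, 19)

  tb <- make_noise_table(seed = 9)
  r1 <- rank_features_rf(tb$x, tb$y, seed = 5)
  r2 <- rank_features_rf(tb$x, tb$y, seed = 5)
  expect_identical(r1, r2)
  expect_equal(sum(r1$importance), 1, tolerance = 1e-12)
  expect_error(rank_features_rf(tb$x, rep(1, nrow(tb$x))), "both classes")

  expect_length(select_top_k(r1, 3), 3)
  expect_identical(select_top_k(r1, nrow(r1)), r1$feature)
  expect_warning(sel <- select_top_k(r1, 99), "survive")
  expect_length(sel, nrow(r1))
})

test_that("SMOTE balances counts with convex minority combinations", {
  set.seed(6)
  x <- rbind(matrix(rnorm(30 * 3, 5), 30, 3), matrix(rnorm(70 * 3), 70, 3))
  colnames(x) <- c("a", "b", "c")
  y <- c(rep(1, 30), rep(0, 70))
  sm <- smote_resample(x, y, seed = 4)
  expect_equal(as.integer(table(sm$labels)), c(70L, 70L))
  expect_identical(sm$x[1:100, ], x)    # originals preserved
  # each synthetic point lies on a segment between two minority originals
  minority <- x[y == 1, ]
  for (i in which(sm$synthetic)) {
    p <- sm$x[i, ]
    on_segment <- any(vapply(seq_len(nrow(minority)), function(a) {
      da <- p - minority[a, ]
      any(vapply(seq_len(nrow(minority)), function(b) {
        if (a == b) return(FALSE)
        ab <- minority[b, ] - minority[a, ]
        t <- sum(da * ab) / sum(ab * ab)
        t >= -1e-9 && t <= 1 + 1e-9 && sqrt(sum((da - t * ab)^2)) < 1e-8
      }, TRUE))
    }, TRUE))
    expect_true(on_segment)
  }
  # balanced input is returned unchanged
  bal <- smote_resample(x[c(1:30, 31:60), ], y[c(1:30, 31:60)], seed = 1)
  expect_identical(bal$x, x[c(1:30, 31:60), ])
  expect_error(smote_resample(x[c(1:4, 31:70), ], y[c(1:4, 31:70)],
                              k_neighbors = 5), "reduce k")
})

test_that("boosted trees separate separable data and serialise exactly", {
  set.seed(7)
  n <- 80
  x <- cbind(u = c(rnorm(n / 2, 3), rnorm(n / 2, -3)), v = rnorm(n))
  y <- rep(c(1, 0), each = n / 2)
  b <- train_gdbt(x, y, seed = 2)
  pr <- predict_risk(b, x)
  expect_equal(mean((pr$probability >= 0.5) == y), 1)
  expect_identical(predict_risk(train_gdbt(x, y, seed = 2), x)$probability,
                   pr$probability)
  expect_error(predict_risk(b, cbind(u = 1)), "missing features: v")
  # threshold tie goes to glaucoma
  b2 <- b; b2$threshold <- pr$probability[1]
  expect_equal(predict_risk(b2, x[1, , drop = FALSE])$risk_class, "glaucoma")

  dir <- withr::local_tempdir()
  save_bundle(b, dir)
  b3 <- load_bundle(dir)
  expect_identical(predict_risk(b3, x)$probability, pr$probability)
  expect_identical(b3$selected_features, b$selected_features)
})

test_that("cross-validation is stratified, leak-free and calibrated", {
  set.seed(10)
  n <- 100
  x <- cbind(sig = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
             n3 = rnorm(n), n4 = rnorm(n))
  y <- as.integer(x[, "sig"] + rnorm(n, 0, 0.3) > 0)
  cv <- cross_validate(x, y, folds = 10, k_features = 2, seed = 3)
  expect_equal(nrow(cv$per_fold), 10)
  expect_gt(cv$mean[["auc"]], 0.85)

  # label permutation drives held-out AUC to chance: selection and SMOTE
  # fitted on training folds only cannot memorise the permuted labels
  yp <- local({ set.seed(99); sample(y) })
  cvp <- cross_validate(x, yp, folds = 10, k_features = 2, seed = 3)
  expect_gt(cvp$pooled$auc, 0.35)
  expect_lt(cvp$pooled$auc, 0.65)
  expect_error(cross_validate(x[1:5, ], y[1:5], folds = 10), "nrow")
})
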