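test_that("morphological cleanup removes specks and is idempotent", {
  blob <- render_ellipse_mask(ellipse_params(c(32, 32), 13, 13, 0),
                              c(64, 64))
  m <- blob; m[5, 5] <- 1L
  cleaned <- morphological_clean(m, radius = 3)
  expect_equal(cleaned[5, 5], 0L)
  expect_lt(abs(sum(cleaned) - sum(blob)) / sum(blob), 0.1)
  expect_identical(morphological_clean(cleaned, 3), cleaned)
  empty <- matrix(0L, 8, 8)
  expect_identical(morphological_clean(empty, 2), empty)
})

test_that("ellipse fit recovers rendered parameters", {
  e <- ellipse_params(c(64, 60), 40, 25, 0)
  f <- fit_ellipse(render_ellipse_mask(e, c(128, 128)))
  expect_lt(max(abs(f$center - e$center)), 1)
  expect_lt(abs(f$semi_major - 40), 1)
  expect_lt(abs(f$semi_minor - 25), 1)
  expect_lt(rotation_distance(f$rotation, 0), 0.05)

  circ <- fit_ellipse(render_ellipse_mask(
    ellipse_params(c(64, 64), 30, 30, 0), c(128, 128)))
  expect_lt(abs(circ$semi_major - 30), 1)
  expect_lt(abs(circ$semi_minor - 30), 1)

  tiny <- matrix(0L, 16, 16); tiny[8, 8:9] <- 1L; tiny[9, 8:9] <- 1L
  expect_error(fit_ellipse(tiny), "contour")
})

test_that("rendered masks hit the analytic area and round-trip the fit", {
  set.seed(21)
  for (i in 1:20) {
    a <- runif(1, 15, 40); b <- runif(1, 10, a)
    e <- ellipse_params(c(runif(1, 45, 55), runif(1, 45, 55)), a, b,
                        runif(1, 0, pi))
    m <- render_ellipse_mask(e, c(100, 100))
    expect_lt(abs(sum(m) - pi * a * b) / (pi * a * b), 0.02)
  }
  expect_warning(render_ellipse_mask(ellipse_params(c(500, 500), 5, 4, 0),
                                     c(64, 64)), "empty")
})

test_that("pair post-processing enforces cup-in-disc and denoises", {
  s <- fixture_samples("non-glaucoma", 5)
  post <- postprocess_pair(s$od_mask, s$oc_mask)
  expect_lt(max(abs(post$od_ellipse$center - s$od_ellipse$center)), 1)
  expect_lt(abs(post$od_ellipse$semi_major - s$od_ellipse$semi_major), 1)
  expect_lt(abs(post$oc_ellipse$semi_major - s$oc_ellipse$semi_major), 1)

  # salt noise: post-processing restores overlap with the clean truth
  set.seed(31)
  noisy_od <- s$od_mask
  flips <- sample(length(noisy_od), round(0.05 * length(noisy_od)))
  noisy_od[flips] <- 1L - noisy_od[flips]
  noisy_oc <- s$oc_mask
  flips2 <- sample(length(noisy_oc), round(0.05 * length(noisy_oc)))
  noisy_oc[flips2] <- 1L - noisy_oc[flips2]
  sm <- postprocess_pair(noisy_od, noisy_oc)
  expect_gt(overlap_score(s$od_mask, sm$od_mask),
            overlap_score(s$od_mask, noisy_od))
  expect_true(all(sm$od_mask[sm$oc_mask == 1] == 1))

  # a cup leaking outside the disc is clipped back inside
  leak_oc <- render_ellipse_mask(
    ellipse_params(s$oc_ellipse$center + c(0, 30),
                   s$oc_ellipse$semi_major, s$oc_ellipse$semi_minor,
                   s$oc_ellipse$rotation), dim(s$od_mask))
  clipped <- postprocess_pair(s$od_mask, leak_oc)
  expect_true(all(clipped$od_mask[clipped$oc_mask == 1] == 1))

  expect_error(postprocess_pair(matrix(0L, 32, 32), matrix(0L, 32, 32)),
               "empty")
})
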