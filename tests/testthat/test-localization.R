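test_that("enhancement lifts bright objects and fixes flat images", {
  flat <- matrix(0.5, 64, 64)
  expect_equal(enhance_image(flat, radius = 10), flat)

  # single bright dot on a flat background gains contrast (dot is smaller
  # than the element, so the top-hat adds its full height back)
  toy <- matrix(0.2, 32, 32); toy[16, 16] <- 0.6
  enh <- enhance_image(toy, radius = 4)
  expect_gt(enh[16, 16] - median(enh), 0.6 - 0.2)

  s <- fixture_samples("non-glaucoma", 1)
  gray <- rgb_to_gray(s$image)
  enh <- enhance_image(s$image)
  expect_gt(mean(enh[s$od_mask == 1]), mean(gray[s$od_mask == 1]))
  expect_error(enhance_image(flat, radius = 60), "larger than image")
})

test_that("brightest-region extraction selects the top of the range", {
  flat <- matrix(0.7, 8, 8)
  expect_true(all(extract_brightest_region(flat) == 1))

  ramp <- matrix(0:255 / 255, 16, 16)
  sel <- extract_brightest_region(ramp, fraction = 0.065)
  expect_setequal(which(sel == 1), which(ramp >= 0.935 * 1))
  expect_gte(sum(sel), 1)

  s <- fixture_samples("non-glaucoma", 1)
  cand <- extract_brightest_region(enhance_image(s$image))
  expect_gt(sum(cand * s$od_mask) / sum(cand), 0.5)
})

test_that("vessel extraction recovers strokes, best in the green channel", {
  flat <- array(0.5, c(64, 64, 3))
  expect_equal(sum(extract_vessels(flat)), 0)

  recall_on <- function(s, chan) {
    vm <- if (is.null(chan)) extract_vessels(s$image) else
      extract_vessels(s$image[, , chan])
    dil <- EBImage::dilate(EBImage::Image(t(vm * 1.0)),
                           EBImage::makeBrush(5, "disc"))
    dil <- t(EBImage::imageData(dil))
    sum(dil[s$vessel_mask == 1] > 0) / sum(s$vessel_mask)
  }
  rec <- vapply(1:5, function(seed) {
    recall_on(fixture_samples(if (seed %% 2) "non-glaucoma" else "glaucoma",
                              seed), NULL)
  }, 0)
  expect_true(all(rec >= 0.6))

  s <- fixture_samples("non-glaucoma", 1)
  expect_gt(recall_on(s, 2), recall_on(s, 1))
  expect_gt(recall_on(s, 2), recall_on(s, 3))
})

test_that("window confidence normalises per map and averages", {
  # one window: degenerate min-max -> all scores 0
  maps <- list(intensity_map = matrix(1, 8, 8),
               vessel_map = matrix(0.5, 8, 8),
               fusion_map = matrix(0.75, 8, 8))
  w1 <- window_confidence(maps, window_side = 8, stride = 1)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$s, 0)

  # two windows with raw sums {10, 20} on every map -> s = {0, 1}
  m <- matrix(0, 4, 8)
  m[, 1:4] <- 10 / 16; m[, 5:8] <- 20 / 16
  maps2 <- list(intensity_map = m, vessel_map = m, fusion_map = m)
  w2 <- window_confidence(maps2, window_side = 4, stride = 4)
  expect_equal(sort(w2$s), c(0, 1))

  # s invariant under common affine rescaling of a raw-score map
  maps3 <- list(intensity_map = matrix(runif(64), 8, 8),
                vessel_map = matrix(runif(64), 8, 8),
                fusion_map = matrix(runif(64), 8, 8))
  a <- window_confidence(maps3, 4, 2)
  maps3$intensity_map <- 0.2 + 3 * maps3$intensity_map
  b <- window_confidence(maps3, 4, 2)
  expect_equal(a$s, b$s, tolerance = 1e-12)
  expect_true(all(a$s >= 0 & a$s <= 1))
})

test_that("uniform images fall back to the tie-break window", {
  img <- array(0.5, c(96, 96, 3))
  loc <- localize_od(img, window_side = 32, stride = 8)
  expect_equal(unname(loc$center), c(16.5, 16.5))
})

test_that("ROI crop is 1.5x the disc diameter and border-safe", {
  img <- array(runif(200 * 200 * 3), c(200, 200, 3))
  roi <- crop_roi(img, c(100, 100), 100)
  expect_equal(roi$side, 150)
  expect_equal(unname(roi$origin), c(26, 26))
  expect_equal(dim(roi$image_crop)[1:2], c(150, 150))

  edge <- crop_roi(img, c(1, 1), 100)
  expect_equal(unname(edge$origin), c(1, 1))
  expect_equal(edge$side, 150)
  expect_error(crop_roi(img, c(100, 100), 150), "exceeds")

  # crop around the true centre contains the whole disc
  s <- fixture_samples("glaucoma", 2)
  r <- crop_roi(s$image, s$od_center, 96)
  inside <- s$od_mask[r$origin[1]:(r$origin[1] + r$side - 1),
                      r$origin[2]:(r$origin[2] + r$side - 1)]
  expect_equal(sum(inside), sum(s$od_mask))
})

test_that("localization lands near the disc and inside the image", {
  for (seed in 1:5) {
    s <- fixture_samples(if (seed %% 2) "non-glaucoma" else "glaucoma", seed)
    loc <- localize_od(s$image)
    d <- ellipse_extents(s$od_ellipse)["vertical"]
    err <- sqrt(sum((loc$center - s$od_center)^2))
    expect_lt(err, 0.25 * d)
    expect_true(all(loc$center >= 1 &
                      loc$center <= dim(s$image)[1:2]))
  }
})
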