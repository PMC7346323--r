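test_that("class-conditional CDR ranges and determinism hold", {
  s_normal <- generate_sample(default_cfg, "non-glaucoma", seed = 1)
  expect_gte(s_normal$true_cdr, default_cfg$cdr_normal_range[1])
  expect_lte(s_normal$true_cdr, default_cfg$cdr_normal_range[2])

  s_gl <- generate_sample(default_cfg, "glaucoma", seed = 2)
  expect_gte(s_gl$true_cdr, default_cfg$cdr_glaucoma_range[1])
  expect_lte(s_gl$true_cdr, default_cfg$cdr_glaucoma_range[2])

  again <- generate_sample(default_cfg, "non-glaucoma", seed = 1)
  expect_identical(s_normal$image, again$image)
  expect_identical(s_normal$od_mask, again$od_mask)

  # geometry-only generation matches the rendered sample at the same seed
  geo <- generate_sample(default_cfg, "non-glaucoma", seed = 1,
                         render = FALSE)
  expect_null(geo$image)
  expect_identical(geo$od_mask, s_normal$od_mask)
  expect_identical(geo$true_cdr, s_normal$true_cdr)
})

test_that("rendered masks reproduce the drawn CDR and intensity ordering", {
  for (seed in 1:6) {
    label <- if (seed %% 2 == 0) "glaucoma" else "non-glaucoma"
    s <- fixture_samples(label, seed)
    vd <- mask_vertical_extent(s$od_mask)
    vc <- mask_vertical_extent(s$oc_mask)
    expect_lt(abs(vc / vd - s$true_cdr), 1 / vd + 0.01)
    # cup strictly inside disc
    expect_true(all(s$od_mask[s$oc_mask == 1] == 1))
    expect_lt(sum(s$oc_mask), sum(s$od_mask))
    g <- rgb_to_gray(s$image)
    expect_gt(mean(g[s$od_mask == 1]), mean(g[s$od_mask == 0]))
    expect_gt(mean(g[s$oc_mask == 1]),
              mean(g[s$od_mask == 1 & s$oc_mask == 0]))
    # vessels darker than their surroundings in the green channel
    green <- s$image[, , 2]
    expect_lt(mean(green[s$vessel_mask == 1]),
              mean(green[s$vessel_mask == 0 & s$od_mask == 0]))
    expect_gte(sum(s$vessel_mask) > 0, default_cfg$vessel_count_range[1] > 0)
  }
})

test_that("dataset composition follows the glaucoma fraction", {
  ds <- generate_dataset(default_cfg, 10, 0.3, seed = 0, render = FALSE)
  expect_equal(sum(ds$manifest$label == "glaucoma"), 3)
  expect_equal(nrow(ds$manifest), 10)

  ds1 <- generate_dataset(default_cfg, 1, 0.0, seed = 1, render = FALSE)
  expect_equal(ds1$manifest$label, "non-glaucoma")

  big <- generate_dataset(default_cfg, 60, 0.5, seed = 7, render = FALSE)
  cdr_gl <- big$manifest$true_cdr[big$manifest$label == "glaucoma"]
  cdr_no <- big$manifest$true_cdr[big$manifest$label == "non-glaucoma"]
  expect_gt(mean(cdr_gl), mean(cdr_no))
  expect_gt(min(cdr_gl), max(cdr_no))  # ranges are disjoint by construction
})

test_that("samples round-trip losslessly through PNG + JSON", {
  s <- fixture_samples("non-glaucoma", 1)
  dir <- withr::local_tempdir()
  write_sample(s, dir)
  back <- read_sample(dir, s$id)
  expect_identical(back$image, s$image)
  expect_identical(back$od_mask, s$od_mask)
  expect_identical(back$oc_mask, s$oc_mask)
  expect_equal(back$true_cdr, s$true_cdr, tolerance = 1e-14)
  expect_identical(back$label, s$label)
  expect_identical(back$eye, s$eye)
  expect_equal(back$od_ellipse$semi_major, s$od_ellipse$semi_major,
               tolerance = 1e-14)
  # mask PNG holds only {0, 255}
  raw <- png::readPNG(file.path(dir, paste0(s$id, "_od_mask.png")))
  expect_setequal(unique(as.vector(raw)) * 255, c(0, 255))
})

test_that("impossible configurations are rejected", {
  expect_error(synth_config(od_diameter_range = c(200, 260)), "cannot fit")
  expect_error(synth_config(cdr_normal_range = c(0.3, 0.7),
                            cdr_glaucoma_range = c(0.6, 0.9)),
               "strictly above")
  expect_error(synth_config(cdr_normal_range = c(0, 0.4)), "inside")
})
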