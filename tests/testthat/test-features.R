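annulus <- function(r_in = 20, r_out = 40, ctr = c(64, 64), dim = c(128, 128)) {
  list(od = render_ellipse_mask(ellipse_params(ctr, r_out, r_out, 0), dim),
       oc = render_ellipse_mask(ellipse_params(ctr, r_in, r_in, 0), dim))
}

test_that("CDR features follow ellipse arithmetic", {
  od <- ellipse_params(c(0, 0), 50, 45, pi / 2)   # vertical diameter 100
  oc <- ellipse_params(c(0, 0), 20, 18, pi / 2)   # vertical diameter 40
  f <- compute_cdr_features(od, oc)
  expect_equal(f$vertical_cdr, 0.4, tolerance = 1e-12)
  expect_equal(f$od_area, pi * 50 * 45)
  expect_equal(f$cd_area_ratio, (20 * 18) / (50 * 45), tolerance = 1e-12)

  same <- compute_cdr_features(od, od)
  expect_equal(same$vertical_cdr, 1)
  expect_equal(same$cd_area_ratio, 1)

  # common rotation leaves the area ratio unchanged
  rot <- function(e, th) ellipse_params(e$center, e$semi_major,
                                        e$semi_minor, e$rotation + th)
  f2 <- compute_cdr_features(rot(od, 0.7), rot(oc, 0.7))
  expect_equal(f2$cd_area_ratio, f$cd_area_ratio, tolerance = 1e-12)
})

test_that("rim sectors partition the annulus into equal quadrants", {
  an <- annulus()
  sec <- split_nrr_sectors(an$od, an$oc, "right")
  areas <- vapply(sec[c("inr", "snr", "nnr", "tnr")], sum, 0)
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
  total <- sec$inr + sec$snr + sec$nnr + sec$tnr
  rim <- an$od * (1 - an$oc)
  expect_true(all(total == rim))        # disjoint and exhaustive
  expect_lte(max(total), 1L)

  # a thickened top half makes the superior sector dominate
  top_heavy <- an$od
  extra <- render_ellipse_mask(ellipse_params(c(54, 64), 44, 44, 0),
                               c(128, 128))
  top_heavy[1:64, ] <- pmax(top_heavy[1:64, ], extra[1:64, ])
  sec2 <- split_nrr_sectors(top_heavy, an$oc, "right")
  expect_gt(sum(sec2$snr), sum(sec2$inr))

  # laterality swaps the nasal/temporal masks exactly
  left <- split_nrr_sectors(an$od, an$oc, "left")
  expect_identical(left$nnr, sec$tnr)
  expect_identical(left$tnr, sec$nnr)
  expect_error(split_nrr_sectors(an$od, an$oc, "unknown"), "laterality")
})

test_that("sector thickness matches annulus geometry and scaling laws", {
  an <- annulus(20, 40)
  sec <- split_nrr_sectors(an$od, an$oc, "right")
  isnt <- compute_isnt_features(sec, an$od, an$oc)
  th <- unlist(isnt[grep("thickness", names(isnt))])
  expect_true(all(abs(th - 20) <= 1))
  areas <- unlist(isnt[grep("_area", names(isnt))])
  expect_equal(sum(areas), sum(an$od * (1 - an$oc)))

  # doubling the scale doubles thickness and quadruples area
  an2 <- annulus(40, 80, ctr = c(128, 128), dim = c(256, 256))
  sec2 <- split_nrr_sectors(an2$od, an2$oc, "right")
  isnt2 <- compute_isnt_features(sec2, an2$od, an2$oc)
  expect_equal(isnt2$inr_thickness / isnt$inr_thickness, 2, tolerance = 0.05)
  expect_equal(isnt2$inr_area / isnt$inr_area, 4, tolerance = 0.05)
})

test_that("the ISNT rule check orders thicknesses with ties allowed", {
  mk <- function(i, s, n, t) list(inr_thickness = i, snr_thickness = s,
                                  nnr_thickness = n, tnr_thickness = t)
  r <- check_isnt_rule(mk(40, 35, 30, 25))
  expect_equal(r$flag, 1L); expect_equal(r$margin, 5)
  r2 <- check_isnt_rule(mk(30, 35, 30, 25))
  expect_equal(r2$flag, 0L); expect_equal(r2$margin, -5)
  r3 <- check_isnt_rule(mk(20, 20, 20, 20))
  expect_equal(r3$flag, 1L); expect_equal(r3$margin, 0)
})

test_that("the 25-feature vector reproduces generator ground truth", {
  expect_length(clinical_feature_names(), 25)
  for (seed in 1:4) {
    lab <- if (seed %% 2 == 0) "glaucoma" else "non-glaucoma"
    s <- fixture_samples(lab, seed)
    fv <- extract_feature_vector(s$od_ellipse, s$oc_ellipse, s$od_mask,
                                 s$oc_mask, s$eye)
    expect_length(fv, 25)
    expect_identical(names(fv), clinical_feature_names())
    expect_lt(abs(fv[["vertical_cdr"]] - s$true_cdr), 0.02)
    expect_true(all(fv[c("inr_disc_ratio", "snr_disc_ratio",
                         "nnr_disc_ratio", "tnr_disc_ratio",
                         "cd_area_ratio", "rim_disc_ratio")] >= 0))
  }
  ds <- generate_dataset(default_cfg, 30, 0.5, seed = 17, render = FALSE)
  ft <- extract_features_dataset(ds$samples)
  gl <- ft$x[ft$labels == "glaucoma", "vertical_cdr"]
  no <- ft$x[ft$labels == "non-glaucoma", "vertical_cdr"]
  expect_gt(mean(gl), mean(no))
  # ISNT realism: healthy rims usually satisfy the rule, glaucomatous not
  expect_gt(mean(ft$x[ft$labels == "non-glaucoma", "isnt_rule"]), 0.8)
  expect_lt(mean(ft$x[ft$labels == "glaucoma", "isnt_rule"]), 0.2)
})

test_that("features are translation invariant", {
  an <- annulus(15, 30, ctr = c(50, 50), dim = c(128, 128))
  an_shift <- annulus(15, 30, ctr = c(70, 60), dim = c(128, 128))
  s1 <- compute_isnt_features(split_nrr_sectors(an$od, an$oc, "right"),
                              an$od, an$oc)
  s2 <- compute_isnt_features(split_nrr_sectors(an_shift$od, an_shift$oc,
                                                "right"),
                              an_shift$od, an_shift$oc)
  expect_equal(s1$inr_thickness, s2$inr_thickness, tolerance = 0.05)
  expect_equal(s1$snr_area, s2$snr_area, tolerance = 0.02 * s1$snr_area)
})
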