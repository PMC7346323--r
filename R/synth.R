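#' Configuration for the synthetic fundus generator
#'
#' The generator emulates ORIGA-style retinal photographs at the level the
#' screening pipeline consumes: a reddish-orange fundus background behind a
#' circular camera aperture, multiplicative vignetting, a bright elliptical
#' optic disc (OD) containing a brighter elliptical optic cup (OC) whose
#' cup-to-disc ratio (CDR) is drawn from a class-conditional range, and dark
#' curvilinear vessels radiating out of the disc. Paired ground-truth masks
#' and the glaucoma label are returned with every image.
#'
#' @param image_size integer `(H, W)` in pixels.
#' @param od_diameter_range vertical OD diameter range in pixels.
#' @param cdr_normal_range CDR range for non-glaucoma eyes; strictly below
#'   `cdr_glaucoma_range` so synthetic ground truth is unambiguous.
#' @param cdr_glaucoma_range CDR range for glaucoma eyes.
#' @param vessel_count_range integer range of rendered vessels.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#'   (intensity units on the `[0, 1]` scale).
#' @param vignette_strength strength in `[0, 1]` of the radial multiplicative
#'   vignette.
#' @param isnt_realism if `TRUE` (default) the cup is offset so that healthy
#'   rims follow the ISNT thickness ordering while glaucomatous rims thin
#'   superiorly/temporally and violate it.
#' @param seed default integer seed used by [generate_dataset()].
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(image_size = c(256L, 256L),
                         od_diameter_range = c(64, 96),
                         cdr_normal_range = c(0.25, 0.45),
                         cdr_glaucoma_range = c(0.60, 0.85),
                         vessel_count_range = c(6L, 12L),
                         noise_sigma = 0.012,
                         vignette_strength = 0.35,
                         isnt_realism = TRUE,
                         seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              od_diameter_range = od_diameter_range,
              cdr_normal_range = cdr_normal_range,
              cdr_glaucoma_range = cdr_glaucoma_range,
              vessel_count_range = as.integer(vessel_count_range),
              noise_sigma = noise_sigma,
              vignette_strength = vignette_strength,
              isnt_realism = isTRUE(isnt_realism),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng_ok(cfg$cdr_normal_range) || !rng_ok(cfg$cdr_glaucoma_range) ||
      any(c(cfg$cdr_normal_range, cfg$cdr_glaucoma_range) <= 0) ||
      any(c(cfg$cdr_normal_range, cfg$cdr_glaucoma_range) >= 1)) {
    stop_fs("CDR ranges must lie strictly inside (0, 1)")
  }
  if (cfg$cdr_glaucoma_range[1] <= cfg$cdr_normal_range[2]) {
    stop_fs("cdr_glaucoma_range must lie strictly above cdr_normal_range")
  }
  if (!rng_ok(cfg$od_diameter_range) || cfg$od_diameter_range[1] <= 0) {
    stop_fs("invalid od_diameter_range")
  }
  aperture <- 0.48 * min(cfg$image_size)
  if (1.15 * cfg$od_diameter_range[2] / 2 + 8 >= aperture) {
    stop_fs("OD of diameter %g cannot fit inside a %dx%d frame",
            cfg$od_diameter_range[2], cfg$image_size[1], cfg$image_size[2])
  }
  if (cfg$vignette_strength < 0 || cfg$vignette_strength > 1) {
    stop_fs("vignette_strength must be in [0, 1]")
  }
  invisible(cfg)
}

# Fixed scene palette (RGB in [0,1]); per-sample brightness jitter multiplies
# these. A single hue keeps the generator simple while still exercising the
# bright-object enhancement and the green-channel vessel contrast.
synth_palette <- function() {
  # The red channel is kept bright and low-contrast against the dark-red
  # vessels (as in real fundus photographs, where red is near saturation)
  # so the green channel carries the best vessel/background contrast.
  list(background = c(0.72, 0.34, 0.10),
       od = c(0.97, 0.80, 0.42),
       oc = c(1.00, 0.87, 0.52),
       vessel = c(0.55, 0.07, 0.05))
}

#' Generate one synthetic fundus sample
#'
#' Deterministic given `(config, label, seed)`: the same call returns
#' bit-identical pixel arrays. The true CDR is drawn from the label's range;
#' the rendered masks reproduce it as the ratio of vertical mask extents to
#' within a pixel of quantisation.
#'
#' @param config a [synth_config()].
#' @param label `"glaucoma"` or `"non-glaucoma"`.
#' @param seed integer seed for this sample.
#' @param render if `FALSE`, skip the (relatively expensive) image
#'   composition and return `image = NULL`; geometry, masks and labels are
#'   identical to the rendered sample at the same seed. Useful when only
#'   the ground-truth geometry is needed, e.g. for large feature tables.
#' @return an object of class `fundus_sample`: a list with `image`
#'   (H x W x 3 array in `[0, 1]`, 8-bit quantised), `od_mask`, `oc_mask`,
#'   `vessel_mask` (0/1 matrices), `label`, `true_cdr`, `od_center`
#'   (`(row, col)`), `eye`, `od_ellipse`, `oc_ellipse`, `id`.
#' @export
generate_sample <- function(config = synth_config(),
                            label = c("non-glaucoma", "glaucoma"),
                            seed = config$seed, render = TRUE) {
  label <- match.arg(label)
  validate_synth_config(config)
  with_seed(seed, {
    H <- config$image_size[1]; W <- config$image_size[2]
    pal <- synth_palette()
    eye <- sample(c("left", "right"), 1)

    # --- disc / cup geometry -------------------------------------------
    d_v <- runif(1, config$od_diameter_range[1], config$od_diameter_range[2])
    A_v <- d_v / 2                      # OD vertical semi-axis
    A_h <- A_v * runif(1, 0.84, 0.96)   # vertically elongated disc
    tilt <- runif(1, -0.10, 0.10)
    cdr_rng <- if (label == "glaucoma") config$cdr_glaucoma_range else
      config$cdr_normal_range
    cdr <- runif(1, cdr_rng[1], cdr_rng[2])

    ctr_img <- c((H + 1) / 2, (W + 1) / 2)
    aperture <- 0.48 * min(H, W)
    r_max <- aperture - 1.15 * A_v - 8
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * min(r_max, 0.30 * min(H, W))
    od_center <- ctr_img + rad * c(sin(ang), cos(ang))

    t_v <- A_v * (1 - cdr)              # vertical rim semi-thickness
    a_v <- cdr * A_v                    # OC vertical semi-axis (exact CDR)
    a_h <- max(0.3 * a_v, A_h - 0.5 * t_v)  # horizontal rim clearly thinner
                                            # than vertical, so I/S > N/T
    # Cup offset: towards superior (thins S), towards temporal (thins T).
    up_frac <- if (config$isnt_realism) {
      if (label == "glaucoma") runif(1, 0.40, 0.55) else runif(1, 0.10, 0.20)
    } else 0
    temp_frac <- if (config$isnt_realism) runif(1, 0.10, 0.20) else 0
    t_h <- A_h - a_h
    temporal_sign <- if (eye == "right") -1 else 1   # right eye: temporal = image-left
    oc_center <- od_center + c(-up_frac * t_v, temporal_sign * temp_frac * t_h)

    od_ell <- ellipse_from_axes(od_center, A_v, A_h, tilt)
    oc_ell <- ellipse_from_axes(oc_center, a_v, a_h, tilt)
    od_mask <- render_ellipse_mask(od_ell, c(H, W))
    oc_mask <- render_ellipse_mask(oc_ell, c(H, W))
    oc_mask <- oc_mask * od_mask        # numeric safety: cup inside disc

    # --- vessels: cubic Bezier strokes converging into the disc --------
    bright <- runif(1, 0.9, 1.1)
    n_vessels <- sample(seq(config$vessel_count_range[1],
                            config$vessel_count_range[2]), 1)
    vessel_mask <- matrix(0L, H, W)
    for (v in seq_len(n_vessels)) {
      stroke <- vessel_stroke(od_center, A_v, c(H, W), cdr)
      vessel_mask[stroke] <- 1L
    }
    noise <- matrix(rnorm(H * W, 0, config$noise_sigma), H, W)

    # --- scene composition, vignette, aperture, blur, noise ------------
    img <- NULL
    if (render) {
      img <- array(0, c(H, W, 3))
      dr <- matrix(seq_len(H) - ctr_img[1], H, W)
      dc <- matrix(seq_len(W) - ctr_img[2], H, W, byrow = TRUE)
      rr <- sqrt(dr^2 + dc^2)
      vig <- 1 - config$vignette_strength * (rr / (0.5 * min(H, W)))^2
      ap <- ifelse(rr <= aperture, 1, 0.03)
      for (ch in 1:3) {
        pl <- matrix(pal$background[ch] * bright, H, W)
        pl[od_mask == 1] <- pal$od[ch] * bright
        pl[oc_mask == 1] <- pal$oc[ch] * bright
        pl[vessel_mask == 1] <- pal$vessel[ch] * bright
        pl <- pl * vig * ap
        pl <- from_ebimage(EBImage::gblur(as_ebimage(pl), sigma = 0.8))
        img[, , ch] <- clip01(pl + noise)
      }
      img <- round(img * 255) / 255     # 8-bit grid so PNG round-trips exactly
    }

    structure(
      list(image = img, od_mask = od_mask, oc_mask = oc_mask,
           vessel_mask = vessel_mask, label = label, true_cdr = cdr,
           od_center = od_center, eye = eye,
           od_ellipse = od_ell, oc_ellipse = oc_ell,
           id = sprintf("synth_%s_%d", gsub("-", "", label), seed)),
      class = "fundus_sample"
    )
  })
}

# One vessel: cubic Bezier arcing from just outside the cup to the
# periphery, so vessels converge into the disc (their density peaks there,
# as in real fundus photographs) without crossing the brighter cup.
# Stamped with a disc of random width 2-5 px; returns a logical index matrix.
vessel_stroke <- function(od_center, od_radius, dim, cdr) {
  H <- dim[1]; W <- dim[2]
  theta <- runif(1, 0, 2 * pi)
  u <- c(sin(theta), cos(theta))
  perp <- c(u[2], -u[1])
  start_frac <- min(0.97, cdr + runif(1, 0.06, 0.18))
  p0 <- od_center + start_frac * od_radius * u
  # reach decays the vessel density away from the disc, like real arcades
  reach <- runif(1, 0.30, 0.90) * 0.5 * min(H, W)
  p3 <- od_center + reach * u + runif(1, -0.25, 0.25) * reach * perp
  p1 <- p0 + 0.33 * (p3 - p0) + runif(1, -0.12, 0.12) * reach * perp
  p2 <- p0 + 0.66 * (p3 - p0) + runif(1, -0.12, 0.12) * reach * perp
  tt <- seq(0, 1, length.out = 160)
  bez <- function(i) (1 - tt)^3 * p0[i] + 3 * (1 - tt)^2 * tt * p1[i] +
    3 * (1 - tt) * tt^2 * p2[i] + tt^3 * p3[i]
  pr <- bez(1); pc <- bez(2)
  # vessels are thickest at the disc and taper towards the periphery
  half0 <- runif(1, 1.6, 2.5)           # width 3-5 px at the disc
  half <- pmax(half0 * (1 - 0.65 * tt), 0.95)   # taper, floor at ~2 px
  off <- expand.grid(dr = -3:3, dc = -3:3)
  idx <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(off))) {
    d2 <- off$dr[k]^2 + off$dc[k]^2
    sel <- d2 <= half^2
    if (!any(sel)) next
    rows <- round(pr[sel]) + off$dr[k]
    cols <- round(pc[sel]) + off$dc[k]
    keep <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
    idx[cbind(rows[keep], cols[keep])] <- TRUE
  }
  idx
}

#' Generate a labelled synthetic dataset
#'
#' @param config a [synth_config()].
#' @param n number of samples.
#' @param glaucoma_fraction fraction of glaucoma samples in `[0, 1]`;
#'   `round(n * glaucoma_fraction)` samples receive the glaucoma label.
#' @param seed integer seed; per-sample seeds are drawn from it.
#' @param render see [generate_sample()].
#' @return list with `samples` (list of `fundus_sample`) and `manifest`
#'   (data frame: id, label, true_cdr, eye, od centre and vertical diameter).
#' @export
generate_dataset <- function(config = synth_config(), n, glaucoma_fraction,
                             seed = config$seed, render = TRUE) {
  stopifnot(n >= 1, glaucoma_fraction >= 0, glaucoma_fraction <= 1)
  n_gl <- round(n * glaucoma_fraction)
  labels <- c(rep("glaucoma", n_gl), rep("non-glaucoma", n - n_gl))
  sample_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_sample(config, labels[i], sample_seeds[i], render = render)
    s$id <- sprintf("s%04d", i)
    samples[[i]] <- s
  }
  manifest <- data.frame(
    id = vapply(samples, `[[`, "", "id"),
    label = labels,
    true_cdr = vapply(samples, `[[`, 0, "true_cdr"),
    eye = vapply(samples, `[[`, "", "eye"),
    od_row = vapply(samples, function(s) s$od_center[1], 0),
    od_col = vapply(samples, function(s) s$od_center[2], 0),
    od_vertical_diameter = vapply(
      samples, function(s) unname(ellipse_extents(s$od_ellipse)["vertical"]), 0),
    stringsAsFactors = FALSE
  )
  list(samples = samples, manifest = manifest)
}

#' Write a synthetic sample to disk
#'
#' Image as 8-bit RGB PNG, masks as single-channel PNG with values
#' `{0, 255}`, metadata (label, true CDR, eye, geometry) as JSON. The files
#' round-trip losslessly through [read_sample()].
#'
#' @param sample a `fundus_sample`.
#' @param directory output directory (created if missing).
#' @return invisibly, the named character vector of file paths.
#' @export
write_sample <- function(sample, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  stem <- file.path(directory, sample$id)
  paths <- c(image = paste0(stem, "_image.png"),
             od_mask = paste0(stem, "_od_mask.png"),
             oc_mask = paste0(stem, "_oc_mask.png"),
             vessel_mask = paste0(stem, "_vessel_mask.png"),
             meta = paste0(stem, "_meta.json"))
  ok <- tryCatch({
    png::writePNG(sample$image, paths["image"])
    png::writePNG(sample$od_mask * 1.0, paths["od_mask"])
    png::writePNG(sample$oc_mask * 1.0, paths["oc_mask"])
    png::writePNG(sample$vessel_mask * 1.0, paths["vessel_mask"])
    meta <- list(id = sample$id, label = sample$label,
                 true_cdr = sample$true_cdr, eye = sample$eye,
                 od_center = sample$od_center,
                 od_ellipse = unclass(sample$od_ellipse),
                 oc_ellipse = unclass(sample$oc_ellipse))
    jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = I(17))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_fs("failed to write sample to %s: %s",
                           directory, conditionMessage(ok))
  invisible(paths)
}

#' Read a synthetic sample written by [write_sample()]
#'
#' @param directory directory holding the files.
#' @param id sample id (file stem).
#' @return a `fundus_sample`.
#' @export
read_sample <- function(directory, id) {
  stem <- file.path(directory, id)
  need <- paste0(stem, c("_image.png", "_od_mask.png", "_oc_mask.png",
                         "_vessel_mask.png", "_meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop_fs("missing sample files: %s",
                               paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(need[5], simplifyVector = TRUE)
  as_mask <- function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  }
  structure(
    list(image = png::readPNG(need[1]),
         od_mask = as_mask(need[2]), oc_mask = as_mask(need[3]),
         vessel_mask = as_mask(need[4]),
         label = meta$label, true_cdr = meta$true_cdr,
         od_center = meta$od_center, eye = meta$eye,
         od_ellipse = do.call(ellipse_params, meta$od_ellipse[
           c("center", "semi_major", "semi_minor", "rotation")]),
         oc_ellipse = do.call(ellipse_params, meta$oc_ellipse[
           c("center", "semi_major", "semi_minor", "rotation")]),
         id = meta$id),
    class = "fundus_sample"
  )
}

#' Write a dataset (samples + CSV manifest) to a directory
#'
#' @param dataset result of [generate_dataset()].
#' @param directory output directory.
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (s in dataset$samples) write_sample(s, directory)
  mp <- file.path(directory, "manifest.csv")
  write.csv(dataset$manifest, mp, row.names = FALSE)
  invisible(mp)
}
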