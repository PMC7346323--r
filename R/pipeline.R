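#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the screening pipeline. The maximum
#' OD diameter used for the 1.5x ROI crop is a dataset statistic (computed
#' from training masks when available), not estimated per image.
#'
#' @param max_od_diameter maximum OD diameter in pixels.
#' @param input_size segmentation input side.
#' @param window_side,stride localization scan parameters (`NULL` =
#'   resolution-scaled defaults).
#' @param clean_radius post-processing opening radius.
#' @param threshold classifier decision threshold.
#' @param exposure_bounds mean-intensity range outside which an exposure
#'   warning (not a rejection) is attached to the report.
#' @param seed integer seed recorded in reports.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_od_diameter = 96, input_size = 128L,
                            window_side = NULL, stride = NULL,
                            clean_radius = 3, threshold = 0.5,
                            exposure_bounds = c(0.1, 0.9), seed = 1L) {
  structure(list(max_od_diameter = max_od_diameter,
                 input_size = as.integer(input_size),
                 window_side = window_side, stride = stride,
                 clean_radius = clean_radius, threshold = threshold,
                 exposure_bounds = exposure_bounds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate that an image looks like a fundus photograph
#'
#' Heuristic screen applied before any analysis: a fundus photograph is
#' dominated by warm red/orange hues (R > G > B over most illuminated
#' pixels) and shows the dark border of the camera aperture. Non-fundus
#' uploads (documents, scenery, solid colours) fail one of the two tests.
#'
#' @param image H x W x 3 array in `[0, 1]`, or a path to a PNG/JPEG file.
#' @return list with `ok` (logical), `reason` (`NULL` or `"non-fundus
#'   image"` with detail), and the decoded `image`.
#' @export
validate_input <- function(image) {
  if (is.character(image)) {
    if (!file.exists(image)) stop_fs("cannot read image file: %s", image)
    image <- load_fundus_image(image)
  }
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    return(list(ok = FALSE, reason = "non-fundus image: not 3-channel",
                image = image))
  }
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  lit <- r + g + b > 0.15
  warm <- mean((r > g & g >= b)[lit])
  border <- border_darkness(image)
  ok <- isTRUE(warm > 0.5) && border < 0.25
  reason <- if (!ok) {
    sprintf("non-fundus image (warm-hue fraction %.2f, border intensity %.2f)",
            warm, border)
  }
  list(ok = ok, reason = reason, image = image)
}

# Mean intensity of the image corners, which the circular aperture leaves
# dark in a real fundus photograph.
border_darkness <- function(image) {
  gray <- rgb_to_gray(image)
  H <- nrow(gray); W <- ncol(gray)
  m <- round(0.08 * min(H, W))
  mean(c(gray[1:m, 1:m], gray[1:m, (W - m + 1):W],
         gray[(H - m + 1):H, 1:m], gray[(H - m + 1):H, (W - m + 1):W]))
}

#' Read a fundus image file
#' @param path PNG or JPEG file.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
load_fundus_image <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(EBImage::imageData(im))
  if (length(d) == 2) stop_fs("%s is a grayscale image, expected RGB", path)
  arr <- EBImage::imageData(im)
  out <- array(0, c(d[2], d[1], 3))
  for (ch in 1:3) out[, , ch] <- t(arr[, , ch])
  out
}

#' Screen a single fundus image end to end
#'
#' Runs the full diagnosis chain: input validation, OD localization, ROI
#' crop, disc/cup segmentation, ellipse post-processing, clinical feature
#' extraction and glaucoma risk prediction. Any stage failure yields a
#' structured report with the failing stage and reason rather than a
#' partial result.
#'
#' @param image array or file path.
#' @param model trained `unet_model`.
#' @param bundle trained `classifier_bundle`.
#' @param config a [pipeline_config()].
#' @param eye eye laterality (`"left"`/`"right"`); required for the
#'   nasal/temporal assignment.
#' @param source_id identifier echoed into the report.
#' @return list of class `screening_report`.
#' @export
run_screening <- function(image, model, bundle, config = pipeline_config(),
                          eye = "right", source_id = "image") {
  warnings <- character(0)
  fail <- function(stage, reason) {
    structure(list(source_id = source_id, ok = FALSE, stage = stage,
                   reason = reason, warnings = warnings,
                   seed = config$seed), class = "screening_report")
  }
  val <- validate_input(image)
  if (!val$ok) return(fail("validate", val$reason))
  img <- val$image
  mi <- mean(rgb_to_gray(img))
  if (mi < config$exposure_bounds[1]) {
    warnings <- c(warnings, "possible underexposure")
  }
  if (mi > config$exposure_bounds[2]) {
    warnings <- c(warnings, "possible overexposure")
  }
  res <- tryCatch({
    loc <- localize_od(img, window_side = config$window_side,
                       stride = config$stride)
    roi <- crop_roi(img, loc$center, config$max_od_diameter)
    prep <- prepare_roi(roi$image_crop, size = config$input_size)
    probs <- predict_unet(model, prep$image)
    masks <- binarize_probs(probs, config$threshold)
    post <- postprocess_pair(masks$od_mask, masks$oc_mask,
                             clean_radius = config$clean_radius)
    # map ellipses back to full-image pixel units
    scale <- roi$side / config$input_size
    rescale <- function(e) {
      ellipse_params(e$center * scale + roi$origin - scale / 2 - 0.5,
                     e$semi_major * scale, e$semi_minor * scale, e$rotation)
    }
    feats <- extract_feature_vector(post$od_ellipse, post$oc_ellipse,
                                    post$od_mask, post$oc_mask, eye)
    risk <- predict_risk(bundle, feats)
    isnt_names <- c("inr_thickness", "snr_thickness", "nnr_thickness",
                    "tnr_thickness")
    structure(list(
      source_id = source_id, ok = TRUE,
      od_center = as.numeric(loc$center),
      roi = list(origin = as.numeric(roi$origin), side = roi$side),
      od_ellipse = unclass(rescale(post$od_ellipse)),
      oc_ellipse = unclass(rescale(post$oc_ellipse)),
      vertical_cdr = unname(feats["vertical_cdr"]),
      horizontal_cdr = unname(feats["horizontal_cdr"]),
      isnt = list(thicknesses = as.list(feats[isnt_names]),
                  rule_satisfied = unname(feats["isnt_rule"]),
                  margin = unname(feats["isnt_margin"])),
      features = as.list(feats),
      risk_probability = risk$probability[1],
      risk_class = risk$risk_class[1],
      eye = eye, warnings = warnings, seed = config$seed),
      class = "screening_report")
  }, error = function(e) fail("pipeline", conditionMessage(e)))
  res
}

#' Serialise / restore a screening report
#'
#' @param report a `screening_report`.
#' @param path JSON file path.
#' @return `write_report`: invisibly, `path`; `read_report`: the restored
#'   report (lossless round trip).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat(sprintf("screening of %s FAILED at stage %s: %s\n",
                x$source_id, x$stage, x$reason))
    return(invisible(x))
  }
  cat(sprintf("screening report for %s (%s eye)\n", x$source_id, x$eye))
  cat(sprintf("  OD centre: (%.1f, %.1f)  vertical CDR: %.3f  horizontal CDR: %.3f\n",
              x$od_center[1], x$od_center[2], x$vertical_cdr,
              x$horizontal_cdr))
  cat(sprintf("  ISNT rule: %s (margin %.2f px)\n",
              if (x$isnt$rule_satisfied > 0) "satisfied" else "violated",
              x$isnt$margin))
  cat(sprintf("  glaucoma risk: %.3f -> %s\n", x$risk_probability,
              x$risk_class))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Batch evaluation of the pipeline over a labelled dataset
#'
#' Screens every sample, compares risk classes with the labels into a
#' contingency report, and (when ground-truth masks are present) aggregates
#' segmentation overlap scores and the CDR error.
#'
#' @param samples list of `fundus_sample` objects.
#' @param model,bundle trained models.
#' @param config a [pipeline_config()].
#' @return list with `contingency` (see [contingency_report()]),
#'   `segmentation` (mean `s_disc`, `s_cup`, `acc_disc`, `acc_cup`,
#'   `delta_cdr`), `reports`, and `failures`.
#' @export
batch_evaluate <- function(samples, model, bundle,
                           config = pipeline_config()) {
  if (length(samples) == 0) stop_fs("empty sample list")
  n <- length(samples)
  pred <- character(n); seg <- NULL
  reports <- vector("list", n); failures <- 0L
  for (i in seq_len(n)) {
    s <- samples[[i]]
    rep <- run_screening(s$image, model, bundle, config, eye = s$eye,
                         source_id = s$id)
    reports[[i]] <- rep
    if (!isTRUE(rep$ok)) {
      failures <- failures + 1L
      pred[i] <- NA_character_
      next
    }
    pred[i] <- rep$risk_class
    if (!is.null(s$od_mask)) {
      sm <- report_masks(rep, dim(s$od_mask))
      seg <- rbind(seg, data.frame(
        s_disc = overlap_score(s$od_mask, sm$od),
        s_cup = overlap_score(s$oc_mask, sm$oc),
        acc_disc = mask_accuracy(s$od_mask, sm$od)[["balanced_accuracy"]],
        acc_cup = mask_accuracy(s$oc_mask, sm$oc)[["balanced_accuracy"]],
        delta_cdr = cdr_error(s$true_cdr, rep$vertical_cdr)))
    }
  }
  labels <- vapply(samples, `[[`, "", "label")
  okmask <- !is.na(pred)
  classes <- c("glaucoma", "non-glaucoma")
  counts <- vapply(classes, function(cl) sum(labels == cl), 0L)
  correct <- vapply(classes, function(cl) {
    sum(labels == cl & okmask & pred == cl)
  }, 0L)
  list(contingency = contingency_report(counts, correct),
       segmentation = if (!is.null(seg)) colMeans(seg),
       reports = reports, failures = failures)
}

# Re-render the report's full-resolution ellipses as masks.
report_masks <- function(report, dim) {
  odp <- report$od_ellipse; ocp <- report$oc_ellipse
  od <- render_ellipse_mask(ellipse_params(odp$center, odp$semi_major,
                                           odp$semi_minor, odp$rotation), dim)
  oc <- render_ellipse_mask(ellipse_params(ocp$center, ocp$semi_major,
                                           ocp$semi_minor, ocp$rotation), dim)
  list(od = od, oc = oc * od)
}
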