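#' Build a segmentation training set of ROI crops
#'
#' Generates synthetic samples and crops each to the square ROI around the
#' ground-truth disc centre (side 1.5x the configured maximum OD diameter,
#' as for training-mask-derived crops), resizing image and masks to the
#' network input grid.
#'
#' @param config a [synth_config()].
#' @param n number of samples.
#' @param glaucoma_fraction class balance.
#' @param seed integer seed.
#' @param input_size network input side.
#' @param max_od_diameter ROI statistic in pixels.
#' @return list of samples (`image`, `od_mask`, `oc_mask`) ready for
#'   [train_unet()], with the source manifest attached as an attribute.
#' @export
make_roi_dataset <- function(config = synth_config(), n, glaucoma_fraction,
                             seed, input_size = 128L, max_od_diameter = 96) {
  ds <- generate_dataset(config, n, glaucoma_fraction, seed)
  out <- lapply(ds$samples, function(s) {
    roi <- crop_roi(s$image, s$od_center, max_od_diameter)
    o <- roi$origin; side <- roi$side
    rows <- o[1]:(o[1] + side - 1); cols <- o[2]:(o[2] + side - 1)
    prepare_roi(roi$image_crop, s$od_mask[rows, cols],
                s$oc_mask[rows, cols], size = input_size)
  })
  attr(out, "manifest") <- ds$manifest
  out
}

#' Extract the clinical feature table of a sample list
#'
#' Features are computed from each sample's ground-truth geometry (fitted
#' ellipses and masks), yielding the table used to train and
#' cross-validate the glaucoma classifier.
#'
#' @param samples list of `fundus_sample` objects.
#' @return list with `x` (n x 25 matrix) and `labels` (character vector).
#' @export
extract_features_dataset <- function(samples) {
  x <- t(vapply(samples, function(s) {
    extract_feature_vector(s$od_ellipse, s$oc_ellipse, s$od_mask,
                           s$oc_mask, s$eye)
  }, numeric(25)))
  list(x = x, labels = vapply(samples, `[[`, "", "label"))
}

#' Train the desk-scale screening models
#'
#' One-call training of both pipeline models on synthetic data at desk
#' scale: the segmentation network on `n_train` 128 x 128 ROI crops
#' (validation on `n_val`), and the SMOTE + gradient-boosted-trees
#' classifier on a feature table extracted from ground-truth geometry of
#' `n_features` samples (imbalanced 30/70, as screening cohorts are).
#'
#' @param seed master seed.
#' @param n_train,n_val,n_features problem sizes.
#' @param epochs segmentation training epochs.
#' @param channels encoder widths.
#' @param learning_rate Adam step size.
#' @param synth synthetic-data configuration.
#' @param verbose print training progress.
#' @return list with `model` (trained `unet_model`), `bundle`
#'   (`classifier_bundle`), `selection` (feature-selection report) and
#'   `config` (matching [pipeline_config()]).
#' @export
train_screening_models <- function(seed = 1L, n_train = 40L, n_val = 10L,
                                   n_features = 200L, epochs = 30L,
                                   channels = c(16L, 32L, 64L),
                                   learning_rate = 1e-3,
                                   synth = synth_config(),
                                   verbose = 0) {
  train_set <- make_roi_dataset(synth, n_train, 0.5, seed = seed + 1L)
  val_set <- make_roi_dataset(synth, n_val, 0.5, seed = seed + 2L)
  ncfg <- network_config(input_size = 128L, channels = channels,
                         learning_rate = learning_rate,
                         batch_size = 8L, seed = seed)
  model <- build_unet(ncfg)
  model <- train_unet(model, train_set, val_set, epochs = epochs,
                      verbose = verbose)
  feat_samples <- generate_dataset(synth, n_features, 0.3,
                                   seed = seed + 3L, render = FALSE)$samples
  ft <- extract_features_dataset(feat_samples)
  sel <- select_features(ft$x, ft$labels, seed = seed)
  bal <- smote_resample(ft$x[, sel$selected, drop = FALSE], ft$labels,
                        seed = seed)
  bundle <- train_gdbt(bal$x, bal$labels,
                       selected_features = sel$selected, seed = seed)
  list(model = model, bundle = bundle, selection = sel,
       config = pipeline_config(max_od_diameter = 96, input_size = 128L,
                                seed = seed))
}

#' Save / load a trained segmentation model
#'
#' Native R serialisation of the parameter list plus a JSON sidecar with
#' the network configuration.
#'
#' @param model a `unet_model`.
#' @param path file path (`.rds`).
#' @return `save_unet`: invisibly, `path`; `load_unet`: the model.
#' @export
save_unet <- function(model, path) {
  saveRDS(model, path)
  sidecar <- sub("\\.rds$", ".json", path)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, sidecar, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) readRDS(path)
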