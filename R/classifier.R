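#' Drop near-constant features
#'
#' Features are min-max scaled to `[0, 1]` column-wise and those whose
#' scaled variance falls below `threshold` are dropped (a constant feature
#' is always dropped for any positive threshold).
#'
#' @param x numeric feature matrix or data frame (rows = eyes).
#' @param threshold scaled-variance cutoff, default 0.005.
#' @return character vector of surviving feature names.
#' @export
variance_filter <- function(x, threshold = 0.005) {
  x <- as.matrix(x)
  stopifnot(nrow(x) > 0)
  v <- apply(x, 2, function(col) {
    r <- range(col)
    if (diff(r) == 0) return(0)
    var((col - r[1]) / diff(r))
  })
  keep <- names(v)[v >= threshold]
  if (length(keep) == 0) stop_fs("variance filter dropped every feature")
  keep
}

#' Drop one member of each highly correlated feature pair
#'
#' Pairs with `|Pearson r| > threshold` are processed greedily in
#' descending `|r|`; the member with the weaker point-biserial correlation
#' to the class label is dropped (ties drop the feature later in canonical
#' column order).
#'
#' @param x numeric feature matrix or data frame.
#' @param labels class labels (see [classification_metrics()] coding).
#' @param threshold absolute-correlation cutoff, default 0.95.
#' @return character vector of surviving feature names.
#' @export
correlation_filter <- function(x, labels, threshold = 0.95) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  y <- as_binary_label(labels)
  sds <- apply(x, 2, sd)
  cm <- suppressWarnings(cor(x))
  cm[!is.finite(cm)] <- 0
  relevance <- suppressWarnings(abs(cor(x, y)))
  relevance[!is.finite(relevance)] <- 0
  dropped <- character(0)
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    ord <- order(-abs(cm[pairs]))
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      ni <- colnames(x)[i]; nj <- colnames(x)[j]
      if (ni %in% dropped || nj %in% dropped) next
      # drop the less label-relevant member; tie -> the later column
      dropped <- c(dropped,
                   if (relevance[i] > relevance[j]) nj
                   else if (relevance[j] > relevance[i]) ni
                   else nj)
    }
  }
  setdiff(colnames(x), dropped)
}

#' Rank features by random-forest Gini importance
#'
#' Fits a small random forest (default 10 trees) and ranks features by the
#' mean decrease in Gini impurity, normalised to sum to 1.
#'
#' @param x numeric feature matrix or data frame.
#' @param labels class labels.
#' @param n_trees number of trees, default 10.
#' @param seed integer seed.
#' @return data frame with `feature` and `importance`, in descending
#'   importance.
#' @export
rank_features_rf <- function(x, labels, n_trees = 10, seed = 1) {
  y <- factor(as_binary_label(labels), levels = c(0, 1))
  if (length(unique(y)) < 2) stop_fs("feature ranking needs both classes")
  fit <- with_seed(seed, randomForest::randomForest(
    x = as.data.frame(x), y = y, ntree = n_trees))
  imp <- fit$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  ord <- order(-imp)
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Select the top-k ranked features
#'
#' @param ranking data frame from [rank_features_rf()].
#' @param k number of features, default 8.
#' @return character vector of feature names.
#' @export
select_top_k <- function(ranking, k = 8) {
  if (nrow(ranking) < k) {
    warning(sprintf("only %d features survive selection; using all",
                    nrow(ranking)))
    k <- nrow(ranking)
  }
  ranking$feature[seq_len(k)]
}

#' Run the full feature-selection chain
#'
#' Variance filter, correlation filter, random-forest Gini ranking, top-k,
#' returning a selection report.
#'
#' @param x feature matrix or data frame.
#' @param labels class labels.
#' @param variance_threshold,correlation_threshold,k,n_trees,seed
#'   stage parameters.
#' @return list with `dropped_low_variance`, `dropped_correlated`,
#'   `ranking`, `selected`.
#' @export
select_features <- function(x, labels, variance_threshold = 0.005,
                            correlation_threshold = 0.95, k = 8,
                            n_trees = 10, seed = 1) {
  x <- as.matrix(x)
  keep_v <- variance_filter(x, variance_threshold)
  keep_c <- if (length(keep_v) >= 2) {
    correlation_filter(x[, keep_v, drop = FALSE], labels,
                       correlation_threshold)
  } else keep_v
  ranking <- rank_features_rf(x[, keep_c, drop = FALSE], labels,
                              n_trees = n_trees, seed = seed)
  list(dropped_low_variance = setdiff(colnames(x), keep_v),
       dropped_correlated = setdiff(keep_v, keep_c),
       ranking = ranking,
       selected = select_top_k(ranking, k))
}

#' SMOTE oversampling of the minority class
#'
#' Synthesises minority-class points by linear interpolation between a
#' minority sample and one of its k nearest minority neighbours (Euclidean
#' metric) until the class counts are equal. Originals are preserved;
#' every synthetic point is a convex combination of two minority
#' originals.
#'
#' @param x numeric feature matrix.
#' @param labels class labels.
#' @param k_neighbors number of nearest neighbours, default 5.
#' @param seed integer seed.
#' @return list with `x` (stacked matrix), `labels` (0/1 integer vector)
#'   and `synthetic` (logical marker for the new rows).
#' @export
smote_resample <- function(x, labels, k_neighbors = 5, seed = 1) {
  x <- as.matrix(x)
  y <- as_binary_label(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) {
    return(list(x = x, labels = y, synthetic = rep(FALSE, nrow(x))))
  }
  minority <- if (n1 < n0) 1L else 0L
  xm <- x[y == minority, , drop = FALSE]
  n_min <- nrow(xm); n_new <- abs(n0 - n1)
  if (n_min <= k_neighbors) {
    stop_fs("minority class has %d samples <= k_neighbors = %d; reduce k",
            n_min, k_neighbors)
  }
  d <- as.matrix(dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    gap <- runif(n_new)
    xm[base, , drop = FALSE] + gap * (xm[pick, , drop = FALSE] -
                                        xm[base, , drop = FALSE])
  })
  list(x = rbind(x, synth),
       labels = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)))
}

#' Train the gradient-boosted decision-tree classifier
#'
#' Fits gradient-boosted trees on the selected features and wraps them
#' with the selection and decision threshold into a classifier bundle.
#'
#' @param x feature matrix (balanced, e.g. after [smote_resample()]).
#' @param labels 0/1 labels.
#' @param selected_features feature names used by the model, in order.
#' @param n_rounds,max_depth,eta boosting hyper-parameters
#'   (default 100 trees of depth 3, learning rate 0.1).
#' @param threshold decision threshold on the glaucoma probability.
#' @param seed integer seed.
#' @return list of class `classifier_bundle`.
#' @export
train_gdbt <- function(x, labels, selected_features = colnames(x),
                       n_rounds = 100, max_depth = 3, eta = 0.1,
                       threshold = 0.5, seed = 1) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) stop_fs("training needs both classes")
  xs <- as.matrix(x)[, selected_features, drop = FALSE]
  dtrain <- xgboost::xgb.DMatrix(xs, label = y, nthread = 1)
  model <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = n_rounds, verbose = 0))
  structure(list(model_raw = xgboost::xgb.save.raw(model),
                 selected_features = selected_features,
                 threshold = threshold, seed = seed,
                 hyperparams = list(n_rounds = n_rounds,
                                    max_depth = max_depth, eta = eta)),
            class = "classifier_bundle")
}

bundle_model <- function(bundle) xgboost::xgb.load.raw(bundle$model_raw)

#' Predict glaucoma risk for one or more feature vectors
#'
#' @param bundle a `classifier_bundle`.
#' @param features named numeric vector, matrix or data frame containing
#'   (at least) the bundle's selected features.
#' @return data frame with `probability` and `risk_class`.
#' @export
predict_risk <- function(bundle, features) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.matrix(features)
  missing <- setdiff(bundle$selected_features, colnames(features))
  if (length(missing)) {
    stop_fs("missing features: %s", paste(missing, collapse = ", "))
  }
  xs <- features[, bundle$selected_features, drop = FALSE]
  p <- predict(bundle_model(bundle), xgboost::xgb.DMatrix(xs, nthread = 1))
  data.frame(probability = p,
             risk_class = ifelse(p >= bundle$threshold,
                                 "glaucoma", "non-glaucoma"),
             stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the screening classifier
#'
#' Feature selection and SMOTE statistics are fitted inside each training
#' fold only (no information leakage); the held-out fold is scored with
#' the fold's own model.
#'
#' @param x feature matrix or data frame.
#' @param labels class labels.
#' @param folds number of folds, default 10.
#' @param k_features number of selected features, default 8.
#' @param k_neighbors SMOTE neighbours.
#' @param seed governs fold assignment, SMOTE and tree randomness.
#' @param ... passed to [train_gdbt()].
#' @return list with `per_fold` (data frame of Sensitivity, Specificity,
#'   ACC, AUC) and `mean` (named vector), plus pooled out-of-fold scores.
#' @export
cross_validate <- function(x, labels, folds = 10, k_features = 8,
                           k_neighbors = 5, seed = 1, ...) {
  x <- as.matrix(x)
  y <- as_binary_label(labels)
  stopifnot(nrow(x) >= folds)
  fold_id <- with_seed(seed, stratified_folds(y, folds))
  per <- NULL
  pooled <- data.frame(idx = seq_along(y), score = NA_real_)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      stop_fs("fold %d lost a class; use fewer folds or more data", f)
    }
    sel <- select_features(x[tr, , drop = FALSE], y[tr], k = k_features,
                           seed = seed + f)
    bal <- smote_resample(x[tr, sel$selected, drop = FALSE], y[tr],
                          k_neighbors = k_neighbors, seed = seed + f)
    bundle <- train_gdbt(bal$x, bal$labels,
                         selected_features = sel$selected,
                         seed = seed + f, ...)
    pr <- predict_risk(bundle, x[te, , drop = FALSE])
    m <- classification_metrics(y[te], pr$probability, bundle$threshold)
    per <- rbind(per, data.frame(fold = f, sensitivity = m$sensitivity,
                                 specificity = m$specificity,
                                 accuracy = m$accuracy, auc = m$auc))
    pooled$score[te] <- pr$probability
  }
  list(per_fold = per,
       mean = colMeans(per[, c("sensitivity", "specificity",
                               "accuracy", "auc")]),
       pooled = classification_metrics(y, pooled$score))
}

stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Save / load a classifier bundle
#'
#' The boosted model is stored in its native binary format beside a JSON
#' manifest with the selected features, threshold, seed and
#' hyper-parameters; predictions round-trip bit-exactly.
#'
#' @param bundle a `classifier_bundle`.
#' @param path directory to write into.
#' @return `save_bundle`: invisibly, the manifest path; `load_bundle`: the
#'   restored bundle.
#' @export
save_bundle <- function(bundle, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  writeBin(as.vector(bundle$model_raw), file.path(path, "model.xgb"))
  manifest <- bundle[c("selected_features", "threshold", "seed",
                       "hyperparams")]
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(file.path(path, "manifest.json"))
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  raw <- readBin(file.path(path, "model.xgb"), "raw",
                 file.size(file.path(path, "model.xgb")))
  structure(list(model_raw = raw,
                 selected_features = manifest$selected_features,
                 threshold = manifest$threshold, seed = manifest$seed,
                 hyperparams = manifest$hyperparams),
            class = "classifier_bundle")
}
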