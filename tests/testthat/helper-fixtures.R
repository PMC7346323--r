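# Shared fixtures, built in code at test time.

default_cfg <- synth_config()

# A handful of cached samples so independent tests do not regenerate them.
fixture_samples <- local({
  cache <- list()
  function(label = "non-glaucoma", seed = 1) {
    key <- paste(label, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_sample(default_cfg, label, seed)
    }
    cache[[key]]
  }
})

# Desk-scale trained models, trained once and shared by the segmentation
# and end-to-end acceptance tests (the dominant cost of the suite).
trained_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_screening_models(seed = 42L, n_train = 40L,
                                       n_val = 10L, n_features = 200L,
                                       epochs = 30L)
    }
    cache
  }
})

# Vertical extent (px) of a binary mask.
mask_vertical_extent <- function(m) {
  rows <- which(rowSums(m) > 0)
  if (length(rows) == 0) return(0)
  diff(range(rows)) + 1
}

# Angular distance between two rotations modulo pi.
rotation_distance <- function(a, b) {
  d <- abs(a - b) %% pi
  min(d, pi - d)
}
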