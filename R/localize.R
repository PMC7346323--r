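#' Morphological enhancement of the bright disc region
#'
#' Enhances the gray-level fundus image as `F' = F + G_T - G_B`, where `G_T`
#' and `G_B` are the white top-hat and black bottom-hat transforms with a
#' disc structuring element. With a structuring element larger than the
#' optic disc, the top-hat term lifts the disc above the background while
#' the bottom-hat term suppresses dark structures (vessels). The output is
#' clipped back to `[0, 1]`.
#'
#' @param image RGB array or gray matrix in `[0, 1]`.
#' @param radius structuring-element radius in pixels; the default scales
#'   with the image so the element just exceeds a typical disc.
#' @return enhanced gray-level matrix in `[0, 1]`.
#' @export
enhance_image <- function(image, radius = NULL) {
  gray <- if (length(dim(image)) == 3) rgb_to_gray(image) else image
  if (is.null(radius)) radius <- round(min(dim(gray)) / 5)
  if (2 * radius + 1 > min(dim(gray))) {
    stop_fs("structuring element (%d px) larger than image", 2 * radius + 1)
  }
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  im <- as_ebimage(gray)
  gt <- EBImage::whiteTopHat(im, kern)
  gb <- EBImage::blackTopHat(im, kern)
  clip01(gray + from_ebimage(gt) - from_ebimage(gb))
}

#' Extract the brightest candidate region
#'
#' Selects pixels in the top `fraction` of the dynamic range of the enhanced
#' image: value `>= (1 - fraction) * max`. The optic disc occupies the
#' brightest area of the fundus, so these pixels are disc candidates.
#'
#' @param enhanced gray matrix.
#' @param fraction top fraction of the dynamic range, default 0.065.
#' @return 0/1 matrix; always contains at least one pixel (the maximum).
#' @export
extract_brightest_region <- function(enhanced, fraction = 0.065) {
  stopifnot(fraction > 0, fraction < 1, length(enhanced) > 0)
  thr <- (1 - fraction) * max(enhanced)
  matrix(as.integer(enhanced >= thr), nrow(enhanced), ncol(enhanced))
}

#' Extract the retinal vessel map
#'
#' CLAHE-equalises the green channel (where vessel/background contrast is
#' strongest), computes the bottom-hat minus top-hat response
#' `F_vessel = G_B - G_T` with a disc element larger than a vessel width so
#' dark curvilinear structures respond positively, thresholds the positive
#' response by Otsu's method, and median-filters the binary map to remove
#' salt-and-pepper noise.
#'
#' The dark rim of the camera aperture itself responds strongly to the
#' bottom-hat, so the binary map is clipped to an eroded field-of-view mask
#' (the standard guard in retinal vessel extraction).
#'
#' @param image RGB array in `[0, 1]`, or a single-channel matrix which is
#'   used directly (for channel-comparison experiments).
#' @param radius structuring-element radius, default 15 px.
#' @param median_radius median filter radius (window `2r+1`), default 2.
#' @param clahe_limit CLAHE clip limit.
#' @return 0/1 vessel map.
#' @export
extract_vessels <- function(image, radius = 15, median_radius = 1,
                            clahe_limit = 2) {
  chan <- if (length(dim(image)) == 3) image[, , 2] else image
  im <- as_ebimage(chan)
  if (diff(range(chan)) > 0) {   # CLAHE is undefined on a constant image
    im <- EBImage::clahe(im, nx = 8, ny = 8, limit = clahe_limit,
                         keep.range = TRUE)
  }
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  resp <- from_ebimage(EBImage::blackTopHat(im, kern)) -
    from_ebimage(EBImage::whiteTopHat(im, kern))
  resp[resp < 0] <- 0
  thr <- otsu_threshold(resp[resp > 0])
  bin <- as_ebimage((resp > thr) * 1.0)
  bin <- EBImage::medianFilter(bin, size = median_radius)
  vmap <- matrix(as.integer(from_ebimage(bin) > 0.5), nrow(chan), ncol(chan))
  fov_chan <- if (length(dim(image)) == 3) {
    pmax(image[, , 1], image[, , 2], image[, , 3])
  } else image
  vmap * fov_mask(fov_chan, erode_radius = radius + 3)
}

# Field-of-view mask: illuminated pixels (brightest channel, so dark
# vessels do not punch holes), hole-filled and eroded so transitions at
# the aperture border cannot masquerade as dark vessels.
fov_mask <- function(chan, erode_radius = 18, threshold = 0.08) {
  fov <- (chan > threshold) * 1.0
  if (all(fov == 1)) return(matrix(1L, nrow(chan), ncol(chan)))
  im <- EBImage::fillHull(as_ebimage(fov))
  er <- EBImage::erode(im, EBImage::makeBrush(2 * erode_radius + 1, "disc"))
  matrix(as.integer(from_ebimage(er) > 0.5), nrow(chan), ncol(chan))
}

# Otsu threshold on a numeric vector (maximises between-class variance over
# a 256-bin histogram). Applied to the nonzero vessel response only, so the
# dominant zero background does not swamp the histogram.
otsu_threshold <- function(x, bins = 256) {
  if (length(x) == 0) return(Inf)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(bins, 1L + floor((x - rng[1]) / diff(rng) * bins)), bins)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(bins) - 0.5) / bins * diff(rng)
  w0 <- cumsum(w); mu <- cumsum(w * mids); mu_t <- mu[bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Sliding-window confidence scores over the three feature maps
#'
#' Scans a square window over the intensity-candidate, vessel and fusion
#' maps. Each window's raw score on a map is the sum of map values inside
#' the window; per map, raw scores are min-max normalised to `[0, 1]`
#' across all windows (a degenerate map whose scores are all equal
#' normalises to 0); the final window score `s` is the mean of the three
#' normalised scores.
#'
#' @param maps list with `intensity_map`, `vessel_map`, `fusion_map`
#'   matrices on a common grid.
#' @param window_side window side in pixels.
#' @param stride scan stride in pixels.
#' @return data frame of window centres and scores: `row`, `col`,
#'   `f_i`, `f_bv`, `f_ibv`, `s`.
#' @export
window_confidence <- function(maps, window_side, stride) {
  H <- nrow(maps$intensity_map); W <- ncol(maps$intensity_map)
  stopifnot(window_side <= min(H, W), stride >= 1)
  tops <- unique(c(seq(1, H - window_side + 1, by = stride), H - window_side + 1))
  lefts <- unique(c(seq(1, W - window_side + 1, by = stride), W - window_side + 1))
  grid <- expand.grid(top = tops, left = lefts)
  raw <- function(m) window_sums(m, grid$top, grid$left, window_side)
  f <- lapply(maps[c("intensity_map", "vessel_map", "fusion_map")], raw)
  norm <- lapply(f, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  })
  data.frame(row = grid$top + (window_side - 1) / 2,
             col = grid$left + (window_side - 1) / 2,
             f_i = norm[[1]], f_bv = norm[[2]], f_ibv = norm[[3]],
             s = (norm[[1]] + norm[[2]] + norm[[3]]) / 3)
}

# Box sums via a zero-padded integral image.
window_sums <- function(m, tops, lefts, side) {
  ii <- rbind(0, cbind(0, apply(apply(m, 2, cumsum), 1, cumsum)))
  # ii is (W+1) x (H+1) after the double apply (transposed); index carefully
  ii <- t(ii)
  b <- tops + side; r <- lefts + side
  ii[cbind(b, r)] - ii[cbind(tops, r)] - ii[cbind(b, lefts)] + ii[cbind(tops, lefts)]
}

#' Localize the optic disc centre
#'
#' Full localization chain: morphological enhancement, brightest-region
#' extraction, vessel extraction, pixelwise-mean fusion of the candidate and
#' vessel maps, and sliding-window confidence scoring. The centre of the
#' window with the maximum score is returned; ties break towards the
#' smallest row, then smallest column.
#'
#' @param image RGB fundus array in `[0, 1]`.
#' @param window_side scan window side; defaults to the middle of the
#'   expected OD diameter range (0.28 of the smaller image dimension).
#'   When the candidate blob and the window differ in size, every window
#'   fully containing (or contained in) the blob ties on the intensity
#'   map and the tie-break corner can sit half the size mismatch away from
#'   the true centre; a window near the mid-range diameter minimises that
#'   worst-case offset across disc sizes.
#' @param stride scan stride, default `window_side / 8` (at least 1).
#' @param enhance_radius,vessel_radius structuring-element radii passed to
#'   [enhance_image()] and [extract_vessels()].
#' @param fraction brightest-region fraction, default 0.065.
#' @return list with `center` (`(row, col)`), `score`, `windows` (the full
#'   score table) and the three feature `maps`.
#' @export
localize_od <- function(image, window_side = NULL, stride = NULL,
                        enhance_radius = NULL, vessel_radius = 15,
                        fraction = 0.065) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(window_side)) window_side <- round(0.28 * min(H, W))
  if (is.null(stride)) stride <- max(1L, round(window_side / 8))
  enhanced <- enhance_image(image, radius = enhance_radius)
  bright <- extract_brightest_region(enhanced, fraction)
  vessels <- extract_vessels(image, radius = vessel_radius)
  maps <- list(intensity_map = bright + 0,
               vessel_map = vessels + 0,
               fusion_map = (bright + vessels) / 2)
  win <- window_confidence(maps, window_side, stride)
  best <- win[order(-win$s, win$row, win$col)[1], ]
  list(center = c(row = best$row, col = best$col), score = best$s,
       windows = win, maps = maps)
}

#' Crop the square region of interest around the disc
#'
#' Square crop of side `round(1.5 * max_od_diameter)` centred on the
#' localized disc; at image borders the crop is shifted (never shrunk or
#' padded) so it stays inside the image.
#'
#' @param image RGB array or gray matrix.
#' @param center `(row, col)` disc centre.
#' @param max_od_diameter maximum OD diameter in pixels (a dataset/config
#'   statistic, not estimated from the image).
#' @return list of class `roi_region` with `image_crop`, `origin`
#'   (`(row, col)` of the crop's top-left pixel in the parent) and `side`.
#' @export
crop_roi <- function(image, center, max_od_diameter) {
  stopifnot(max_od_diameter > 0)
  H <- dim(image)[1]; W <- dim(image)[2]
  side <- round(1.5 * max_od_diameter)
  if (side > min(H, W)) {
    stop_fs("ROI side %d exceeds image extent %d", side, min(H, W))
  }
  top <- round(center[1] - (side - 1) / 2)
  left <- round(center[2] - (side - 1) / 2)
  top <- min(max(top, 1), H - side + 1)
  left <- min(max(left, 1), W - side + 1)
  crop <- if (length(dim(image)) == 3) {
    image[top:(top + side - 1), left:(left + side - 1), , drop = FALSE]
  } else {
    image[top:(top + side - 1), left:(left + side - 1), drop = FALSE]
  }
  structure(list(image_crop = crop, origin = c(row = top, col = left),
                 side = side),
            class = "roi_region")
}
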