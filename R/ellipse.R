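#' Morphological cleanup of a binary mask
#'
#' Opening (erosion then dilation) with a disc structuring element; isolated
#' specks smaller than the disc vanish while large blobs keep their area.
#' Opening is idempotent.
#'
#' @param mask 0/1 matrix.
#' @param radius disc radius in pixels (>= 1).
#' @return cleaned 0/1 matrix.
#' @export
morphological_clean <- function(mask, radius = 3) {
  stopifnot(radius >= 1)
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  out <- EBImage::opening(as_ebimage((mask > 0) * 1.0), kern)
  matrix(as.integer(from_ebimage(out) > 0.5), nrow(mask), ncol(mask))
}

#' Canny edge detection
#'
#' Sobel gradients, non-maximum suppression along the quantised gradient
#' direction, and two-threshold hysteresis. Thresholds default to fractions
#' of the strong-response level estimated from the nonzero gradient
#' magnitudes, so masks and smooth images need no manual tuning.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param low,high optional hysteresis thresholds on gradient magnitude.
#' @return 0/1 edge matrix.
#' @export
canny_edges <- function(img, low = NULL, high = NULL) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gy_k <- t(sx)  # gradient along rows
  gx <- from_ebimage(EBImage::filter2(as_ebimage(img), t(sx)))
  gy <- from_ebimage(EBImage::filter2(as_ebimage(img), t(gy_k)))
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) return(matrix(0L, nrow(img), ncol(img)))
  nz <- mag[mag > 1e-6]
  if (is.null(high)) high <- 0.4 * max(nz)
  if (is.null(low)) low <- 0.4 * high
  # non-maximum suppression over 4 quantised directions
  ang <- atan2(gy, gx) %% pi
  sector <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(0, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- mag
  sh <- function(dr, dc) pad[2:(H + 1) + dr, 2:(W + 1) + dc]
  n1 <- matrix(0, H, W); n2 <- n1
  # sector 0: horizontal gradient -> compare left/right neighbours
  m0 <- sector == 0; m1 <- sector == 1; m2 <- sector == 2; m3 <- sector == 3
  n1[m0] <- sh(0, -1)[m0]; n2[m0] <- sh(0, 1)[m0]
  n1[m1] <- sh(-1, -1)[m1]; n2[m1] <- sh(1, 1)[m1]
  n1[m2] <- sh(-1, 0)[m2]; n2[m2] <- sh(1, 0)[m2]
  n3 <- sh(-1, 1); n4 <- sh(1, -1)
  n1[m3] <- n3[m3]; n2[m3] <- n4[m3]
  nms <- mag * (mag >= n1 & mag >= n2)
  strong <- nms >= high
  weak <- nms >= low
  if (!any(strong)) return(matrix(0L, H, W))
  # hysteresis: keep weak components that touch a strong pixel
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(weak * 1.0)))
  keep <- unique(lab[strong])
  matrix(as.integer(weak & lab %in% keep[keep > 0]), H, W)
}

#' Direct least-squares ellipse fit to a mask boundary
#'
#' Extracts contour pixels with the Canny detector and fits the
#' general-conic least-squares ellipse (numerically stable formulation of
#' the direct ellipse-specific fit), returning geometric parameters.
#'
#' @param mask 0/1 matrix with a single filled blob.
#' @return an [ellipse_params()] object.
#' @export
fit_ellipse <- function(mask) {
  edges <- canny_edges((mask > 0) * 1.0)
  pts <- which(edges == 1, arr.ind = TRUE)
  if (nrow(pts) < 5) {
    stop_fs("ellipse fit needs >= 5 contour pixels, got %d", nrow(pts))
  }
  fit_ellipse_points(pts[, 1], pts[, 2])
}

# Halir-Flusser stable direct least-squares fit; rows/cols are pixel
# coordinates, internally x = col, y = row.
fit_ellipse_points <- function(rows, cols) {
  x <- cols - mean(cols); y <- rows - mean(rows)  # centre for conditioning
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0) stop_fs("degenerate fit: no ellipse solution")
  a1 <- evec[, idx[1]]
  conic <- c(a1, as.vector(Tm %*% a1))  # (A, B, C, D, E, F) in centred coords
  geom <- conic_to_ellipse(conic)
  geom$center <- geom$center + c(mean(rows), mean(cols))
  ellipse_params(geom$center, geom$semi_major, geom$semi_minor, geom$rotation)
}

conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; FF <- k[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop_fs("degenerate fit: conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + FF
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  if (Fc > 0) { lam <- -lam; Fc <- -Fc }  # normalise sign so lam > 0
  if (any(lam <= 0)) stop_fs("degenerate fit: non-positive axis")
  axes <- sqrt(-Fc / lam)                 # ordered with eigen(): lam[1] >= lam[2]
  # lam[1] >= lam[2] > 0 -> axes[1] <= axes[2]; major axis = eigvec of lam[2]
  vmaj <- eg$vectors[, 2]
  rot <- atan2(vmaj[2], vmaj[1]) %% pi    # (x, y) = (col, row) frame
  list(center = c(cy, cx), semi_major = axes[2], semi_minor = axes[1],
       rotation = rot)
}

#' Post-process a predicted disc/cup mask pair
#'
#' For each channel: keep the largest connected component, open it with a
#' disc element, fit an ellipse to its Canny contour, and re-render the
#' filled ellipse. The rendered cup is clipped by the rendered disc so the
#' anatomical containment OC inside OD always holds.
#'
#' @param od_mask,oc_mask predicted binary masks on a common grid.
#' @param clean_radius opening radius, default 3.
#' @return list with `od_mask`, `oc_mask` (smoothed masks), `od_ellipse`,
#'   `oc_ellipse`.
#' @export
postprocess_pair <- function(od_mask, oc_mask, clean_radius = 3) {
  smooth_one <- function(m, what) {
    blob <- largest_component(m, what)
    # fill interior (pepper) holes before opening, otherwise the erosion
    # eats the blob from every hole; then open to shed boundary noise
    filled <- EBImage::fillHull(as_ebimage(blob * 1.0))
    blob <- matrix(as.integer(from_ebimage(filled) > 0.5), nrow(m), ncol(m))
    cleaned <- morphological_clean(blob, clean_radius)
    if (!any(cleaned > 0)) {
      stop_fs("segmentation failed: %s mask empty after cleanup", what)
    }
    ell <- fit_ellipse(cleaned)
    list(mask = render_ellipse_mask(ell, dim(m)), ellipse = ell)
  }
  od <- smooth_one(od_mask, "disc")
  oc <- smooth_one(oc_mask, "cup")
  list(od_mask = od$mask, oc_mask = oc$mask * od$mask,
       od_ellipse = od$ellipse, oc_ellipse = oc$ellipse)
}

largest_component <- function(mask, what = "mask") {
  if (!any(mask > 0)) stop_fs("segmentation failed: %s mask is empty", what)
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage((mask > 0) * 1.0)))
  tab <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(tab)), nrow(mask), ncol(mask))
}
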