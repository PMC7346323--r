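#' CDR-related features from fitted disc and cup ellipses
#'
#' Vertical CDR is the ratio of the vertical cup extent (VCD) to the
#' vertical disc extent (VDD); horizontal CDR is the analogous column-axis
#' ratio. Areas come from the ellipse area `pi * a * b`.
#'
#' @param od,oc [ellipse_params()] for disc and cup.
#' @return named list: `vertical_cdr`, `horizontal_cdr`, `vdd`, `vcd`,
#'   `od_area`, `oc_area`, `cd_area_ratio`, `od_eccentricity`,
#'   `oc_eccentricity`.
#' @export
compute_cdr_features <- function(od, oc) {
  od_ext <- ellipse_extents(od); oc_ext <- ellipse_extents(oc)
  if (od_ext["vertical"] <= 0) stop_fs("zero vertical disc extent")
  list(
    vertical_cdr = unname(oc_ext["vertical"] / od_ext["vertical"]),
    horizontal_cdr = unname(oc_ext["horizontal"] / od_ext["horizontal"]),
    vdd = unname(od_ext["vertical"]),
    vcd = unname(oc_ext["vertical"]),
    od_area = ellipse_area(od),
    oc_area = ellipse_area(oc),
    cd_area_ratio = ellipse_area(oc) / ellipse_area(od),
    od_eccentricity = ellipse_eccentricity(od),
    oc_eccentricity = ellipse_eccentricity(oc)
  )
}

#' Split the neuro-retinal rim into ISNT quadrants
#'
#' The rim (disc minus cup) is partitioned by the angle of each pixel's
#' vector from the cup centre into four 90-degree sectors centred on the
#' image axes: superior = up, inferior = down, and nasal/temporal assigned
#' by eye laterality (right eye: temporal = image-left). Sector boundaries
#' sit at 45 degrees from the axes.
#'
#' @param od_mask,oc_mask binary masks, cup inside disc.
#' @param eye `"left"` or `"right"`.
#' @return list of 0/1 matrices `inr`, `snr`, `nnr`, `tnr` plus the cup
#'   centre used (`center`).
#' @export
split_nrr_sectors <- function(od_mask, oc_mask, eye = c("right", "left")) {
  if (length(eye) != 1 || !eye %in% c("left", "right")) {
    stop_fs("eye laterality must be \"left\" or \"right\"; set it on the sample")
  }
  rim <- (od_mask > 0) & !(oc_mask > 0)
  ctr <- mask_centroid(oc_mask)
  H <- nrow(od_mask); W <- ncol(od_mask)
  dr <- matrix(seq_len(H) - ctr[1], H, W)
  dc <- matrix(seq_len(W) - ctr[2], H, W, byrow = TRUE)
  ang <- atan2(-dr, dc)  # 0 = image-right, pi/2 = image-up
  within <- function(lo, hi) {
    a <- (ang - lo) %% (2 * pi)
    rim & a < ((hi - lo) %% (2 * pi))
  }
  up <- within(pi / 4, 3 * pi / 4)
  down <- within(5 * pi / 4, 7 * pi / 4)
  left <- within(3 * pi / 4, 5 * pi / 4)
  right <- within(-pi / 4, pi / 4)
  temporal <- if (eye == "right") left else right
  nasal <- if (eye == "right") right else left
  as_m <- function(m) matrix(as.integer(m), H, W)
  iv_left <- c(3 * pi / 4, 5 * pi / 4); iv_right <- c(-pi / 4, pi / 4)
  list(inr = as_m(down), snr = as_m(up), nnr = as_m(nasal),
       tnr = as_m(temporal), center = ctr,
       intervals = list(inr = c(5 * pi / 4, 7 * pi / 4),
                        snr = c(pi / 4, 3 * pi / 4),
                        nnr = if (eye == "right") iv_right else iv_left,
                        tnr = if (eye == "right") iv_left else iv_right))
}

mask_centroid <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_fs("cannot take centroid of an empty mask")
  colMeans(idx)
}

#' ISNT-related scalar features from rim sectors
#'
#' Per-sector area, mean radial thickness (mean over sector angles of the
#' rim extent along the ray from the cup centre), and sector-to-disc area
#' ratios.
#'
#' @param sectors result of [split_nrr_sectors()].
#' @param od_mask,oc_mask binary masks used to trace the rays.
#' @param n_rays number of rays across the full circle.
#' @return named list of `*_area`, `*_thickness`, `*_disc_ratio` for
#'   inr/snr/nnr/tnr.
#' @export
compute_isnt_features <- function(sectors, od_mask, oc_mask, n_rays = 180) {
  rim_px <- sum((od_mask > 0) & !(oc_mask > 0))
  if (rim_px == 0) {
    warning("empty rim; ISNT features set to 0")
    z <- as.list(rep(0, 12))
    names(z) <- paste0(rep(c("inr", "snr", "nnr", "tnr"), each = 3),
                       c("_area", "_thickness", "_disc_ratio"))
    return(z)
  }
  ctr <- sectors$center
  disc_area <- sum(od_mask > 0)
  thick <- ray_thickness(od_mask, oc_mask, ctr, n_rays)
  out <- list()
  for (nm in c("inr", "snr", "nnr", "tnr")) {
    sec <- sectors[[nm]]
    iv <- sectors$intervals[[nm]]
    in_iv <- ((thick[, "angle"] - iv[1]) %% (2 * pi)) < ((iv[2] - iv[1]) %% (2 * pi))
    out[[paste0(nm, "_area")]] <- sum(sec)
    out[[paste0(nm, "_disc_ratio")]] <- sum(sec) / disc_area
    out[[paste0(nm, "_thickness")]] <- if (any(in_iv)) {
      mean(thick[in_iv, "thickness"])
    } else 0
  }
  out
}

# Rim extent along rays from the cup centre: for each angle, the outermost
# disc radius minus the outermost cup radius.
ray_thickness <- function(od_mask, oc_mask, ctr, n_rays) {
  H <- nrow(od_mask); W <- ncol(od_mask)
  angles <- (seq_len(n_rays) - 1) / n_rays * 2 * pi
  rmax <- ceiling(sqrt(H^2 + W^2))
  rr <- seq(0.5, rmax, by = 0.5)
  t(vapply(angles, function(a) {
    r_pts <- round(ctr[1] - rr * sin(a))
    c_pts <- round(ctr[2] + rr * cos(a))
    ok <- r_pts >= 1 & r_pts <= H & c_pts >= 1 & c_pts <= W
    od_hit <- rr[ok][od_mask[cbind(r_pts[ok], c_pts[ok])] > 0]
    oc_hit <- rr[ok][oc_mask[cbind(r_pts[ok], c_pts[ok])] > 0]
    r_od <- if (length(od_hit)) max(od_hit) else 0
    r_oc <- if (length(oc_hit)) max(oc_hit) else 0
    c(angle = a, thickness = max(0, r_od - r_oc))
  }, c(angle = 0, thickness = 0)))
}

#' ISNT rule check
#'
#' Healthy rims satisfy inferior >= superior >= nasal >= temporal mean
#' thickness. The margin is the smallest of the three consecutive
#' differences; a violated rule has a negative margin.
#'
#' @param isnt result of [compute_isnt_features()] (or any list with
#'   `inr_thickness`, `snr_thickness`, `nnr_thickness`, `tnr_thickness`).
#' @return list with `flag` (1 if the rule holds, ties allowed) and
#'   `margin`.
#' @export
check_isnt_rule <- function(isnt) {
  i <- isnt$inr_thickness; s <- isnt$snr_thickness
  n <- isnt$nnr_thickness; t <- isnt$tnr_thickness
  margin <- min(i - s, s - n, n - t)
  list(flag = as.integer(margin >= 0), margin = margin)
}

#' Canonical 25-feature roster
#' @return character vector of the 25 feature names in canonical order.
#' @export
clinical_feature_names <- function() {
  c("vertical_cdr", "horizontal_cdr", "vdd", "vcd", "od_area", "oc_area",
    "cd_area_ratio", "od_eccentricity", "oc_eccentricity", "nrr_area",
    "inr_area", "snr_area", "nnr_area", "tnr_area",
    "inr_thickness", "snr_thickness", "nnr_thickness", "tnr_thickness",
    "inr_disc_ratio", "snr_disc_ratio", "nnr_disc_ratio", "tnr_disc_ratio",
    "isnt_rule", "isnt_margin", "rim_disc_ratio")
}

#' Extract the full 25-feature clinical vector
#'
#' Combines the CDR-related ellipse features, the ISNT quadrant features
#' and the rule check into the canonical named vector (see
#' [clinical_feature_names()] for the order).
#'
#' @param od,oc fitted [ellipse_params()].
#' @param od_mask,oc_mask binary masks consistent with the ellipses.
#' @param eye `"left"` or `"right"`.
#' @return named numeric vector of length 25.
#' @export
extract_feature_vector <- function(od, oc, od_mask, oc_mask, eye) {
  cdrf <- compute_cdr_features(od, oc)
  sectors <- split_nrr_sectors(od_mask, oc_mask, eye)
  isnt <- compute_isnt_features(sectors, od_mask, oc_mask)
  rule <- check_isnt_rule(isnt)
  rim_area <- sum((od_mask > 0) & !(oc_mask > 0))
  disc_area <- sum(od_mask > 0)
  v <- c(cdrf$vertical_cdr, cdrf$horizontal_cdr, cdrf$vdd, cdrf$vcd,
         cdrf$od_area, cdrf$oc_area, cdrf$cd_area_ratio,
         cdrf$od_eccentricity, cdrf$oc_eccentricity, rim_area,
         isnt$inr_area, isnt$snr_area, isnt$nnr_area, isnt$tnr_area,
         isnt$inr_thickness, isnt$snr_thickness, isnt$nnr_thickness,
         isnt$tnr_thickness,
         isnt$inr_disc_ratio, isnt$snr_disc_ratio, isnt$nnr_disc_ratio,
         isnt$tnr_disc_ratio,
         rule$flag, rule$margin, rim_area / disc_area)
  names(v) <- clinical_feature_names()
  v
}
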