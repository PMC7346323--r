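#' @useDynLib fundoscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var cor runif rnorm predict quantile median sd
#' @importFrom utils head write.csv read.csv
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded generation
#' never disturbs the caller's RNG stream. All randomness in the package
#' goes through this helper, which pins the generator kinds so that a given
#' seed yields the same stream across R versions.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

#' Round half away from zero
#'
#' Display rounding used in accuracy tables: 0.78605 -> 0.7861 at 4 digits,
#' unlike base `round()` which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert an RGB array to a gray-level image
#'
#' Standard luminance weighting 0.299 R + 0.587 G + 0.114 B.
#'
#' @param img H x W x 3 numeric array in `[0, 1]`.
#' @return H x W numeric matrix in `[0, 1]`.
#' @export
rgb_to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Clip values into [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Matrix (H x W, row/col convention) <-> EBImage Image (x = col, y = row).
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(im) t(EBImage::imageData(im))

stop_fs <- function(...) stop(sprintf(...), call. = FALSE)
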