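#' @include AllClasses.R utils.R
NULL

#' Normalize image intensities to zero mean, unit variance
#'
#' `(image - mean) / SD`, with population statistics computed over the
#' whole image or, when a mask is given, over the masked pixels only.
#' The statistics are attached as attributes so the transform can be
#' audited (histogram checks) or inverted.
#'
#' @param image numeric matrix; must not be constant.
#' @param mask optional logical matrix restricting the statistics.
#' @return the normalized matrix with attributes `norm_mean`, `norm_sd`.
#' @examples
#' x <- normalizeIntensity(matrix(rnorm(64, 5, 3), 8))
#' c(mean(x), popSD = sqrt(mean((x - mean(x))^2)))
#' @export
normalizeIntensity <- function(image, mask = NULL) {
  vals <- if (is.null(mask)) image else image[mask]
  s <- popSD(vals)
  assertThat(s > 0, "cannot normalize a constant image")
  out <- (image - mean(vals)) / s
  attr(out, "norm_mean") <- mean(vals)
  attr(out, "norm_sd") <- s
  out
}

# Keys cubic-convolution kernel (a = -0.5), the classic bicubic weight.
cubicWeight <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Resample one axis by cubic convolution; returns the index/weight scheme.
cubicScheme <- function(nIn, nOut) {
  # centre-aligned mapping in 0-based coordinates
  pos <- ((0:(nOut - 1)) + 0.5) * nIn / nOut - 0.5
  base <- floor(pos)
  idx <- sapply(-1:2, function(o) pmin(pmax(base + o, 0), nIn - 1)) + 1
  w <- sapply(-1:2, function(o) cubicWeight(pos - (base + o)))
  w <- w / rowSums(w)
  list(idx = matrix(idx, nOut), w = matrix(w, nOut))
}

#' Resample an image to a target pixel spacing
#'
#' Separable bicubic (Keys cubic-convolution, a = -0.5) interpolation onto
#' a grid of `round(size * original/target)` pixels; edge samples are
#' clamped.  The radiomic pipeline's working resolution is 0.1 mm.
#'
#' @param image numeric matrix.
#' @param originalSpacing,targetSpacing mm per pixel (> 0).
#' @return resampled matrix with attributes `spacing` (target) and
#'   `original_spacing`; the identity (within floating point) when the
#'   spacings are equal.
#' @examples
#' dim(resampleImage(matrix(0, 100, 100), 0.2, 0.1))  # 200 x 200
#' @export
resampleImage <- function(image, originalSpacing, targetSpacing = 0.1) {
  assertThat(originalSpacing > 0 && targetSpacing > 0,
             "spacings must be > 0")
  factor <- originalSpacing / targetSpacing
  if (factor > 20)
    warning("upsampling factor above 20; expect interpolation artefacts")
  nrOut <- max(1L, as.integer(round(nrow(image) * factor)))
  ncOut <- max(1L, as.integer(round(ncol(image) * factor)))
  out <- image
  if (nrOut != nrow(image) || factor != 1) {
    sc <- cubicScheme(nrow(image), nrOut)
    out <- sc$w[, 1] * out[sc$idx[, 1], , drop = FALSE] +
      sc$w[, 2] * out[sc$idx[, 2], , drop = FALSE] +
      sc$w[, 3] * out[sc$idx[, 3], , drop = FALSE] +
      sc$w[, 4] * out[sc$idx[, 4], , drop = FALSE]
  }
  if (ncOut != ncol(image) || factor != 1) {
    sc <- cubicScheme(ncol(image), ncOut)
    out <- t(sc$w[, 1] * t(out)[sc$idx[, 1], , drop = FALSE] +
               sc$w[, 2] * t(out)[sc$idx[, 2], , drop = FALSE] +
               sc$w[, 3] * t(out)[sc$idx[, 3], , drop = FALSE] +
               sc$w[, 4] * t(out)[sc$idx[, 4], , drop = FALSE])
  }
  attr(out, "spacing") <- targetSpacing
  attr(out, "original_spacing") <- originalSpacing
  out
}

#' Extract a rectangular ROI
#'
#' Sub-array copy of the inclusive 0-based bounding box
#' `(x_min, y_min, x_max, y_max)`; x indexes columns, y rows.  When the
#' image was resampled, rescale the box by (original spacing / target
#' spacing) before extraction.
#'
#' @param image numeric matrix.
#' @param bbox numeric c(x_min, y_min, x_max, y_max), inside the image.
#' @param scaleFactor optional coordinate scale applied to the box (e.g.
#'   original/target spacing after resampling; default 1).
#' @return the ROI matrix with attribute `bbox` (the used pixel box).
#' @export
extractROI <- function(image, bbox, scaleFactor = 1) {
  bbox <- unname(bbox)
  bb <- if (scaleFactor == 1) round(bbox) else
    c(round(bbox[1:2] * scaleFactor),
      round((bbox[3:4] + 1) * scaleFactor) - 1)  # inclusive upper bound
  assertThat(bb[1] >= 0 && bb[2] >= 0 && bb[3] < ncol(image) &&
               bb[4] < nrow(image) && bb[1] <= bb[3] && bb[2] <= bb[4],
             "bbox must lie inside the image")
  out <- image[(bb[2] + 1):(bb[4] + 1), (bb[1] + 1):(bb[3] + 1),
               drop = FALSE]
  attr(out, "bbox") <- bb
  out
}

#' Quantize an ROI to L grey levels
#'
#' Clips the ROI to mean +/- 3 SD, then bins the clipped range into L
#' equal-width levels 0..L-1.  A constant ROI quantizes to all zeros with a
#' warning.  All matrix-based texture families (GLCM, GLRLM, NGTDM, SFM)
#' operate on this representation.
#'
#' @param roi numeric matrix (non-empty).
#' @param levels number of grey levels L (default 64).
#' @return integer matrix in 0..L-1 with attributes `levels` and
#'   `bin_edges`.
#' @export
quantizeROI <- function(roi, levels = 64L) {
  assertThat(length(roi) > 0, "ROI must be non-empty")
  m <- mean(roi); s <- popSD(roi)
  if (s == 0) {
    warning("constant ROI; all levels are zero")
    out <- matrix(0L, nrow(roi), ncol(roi))
    attr(out, "levels") <- as.integer(levels)
    attr(out, "bin_edges") <- c(m, m)
    return(out)
  }
  lo <- m - 3 * s; hi <- m + 3 * s
  x <- pmin(pmax(roi, lo), hi)
  edges <- seq(lo, hi, length.out = levels + 1)
  out <- matrix(findInterval(x, edges, rightmost.closed = TRUE,
                             all.inside = TRUE) - 1L,
                nrow(roi), ncol(roi))
  storage.mode(out) <- "integer"
  attr(out, "levels") <- as.integer(levels)
  attr(out, "bin_edges") <- edges
  out
}
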