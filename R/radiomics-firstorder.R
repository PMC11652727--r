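#' @include AllClasses.R utils.R
NULL

#' First-order (histogram) features
#'
#' 28 statistics of the raw ROI intensity distribution.  Moments are
#' population moments; quantiles use linear interpolation (type 7);
#' histogram-based statistics (entropy, uniformity, mode) use a 64-bin
#' equal-width histogram over the observed range.  A constant ROI returns
#' zero skewness/kurtosis/entropy/CoV and uniformity 1.
#'
#' @param roi numeric matrix or vector (non-empty).
#' @return named numeric vector of length 28 (prefix `fo_`).
#' @examples
#' f <- firstOrderFeatures(c(1, 2, 3, 4))
#' f[c("fo_mean", "fo_variance", "fo_min", "fo_max")]  # 2.5 1.25 1 4
#' @export
firstOrderFeatures <- function(roi) {
  x <- as.numeric(roi)
  assertThat(length(x) > 0, "ROI must be non-empty")
  m <- mean(x); s <- popSD(x)
  q <- quantile(x, c(0.05, 0.10, 0.25, 0.5, 0.75, 0.90, 0.95),
                names = FALSE, type = 7)
  nb <- 64L
  if (diff(range(x)) > 0) {
    edges <- seq(min(x), max(x), length.out = nb + 1)
    cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), nb)
    p <- cnt / sum(cnt)
    modeVal <- (edges[which.max(cnt)] + edges[which.max(cnt) + 1]) / 2
  } else {
    p <- 1
    modeVal <- x[1]
  }
  c(fo_mean = m,
    fo_sd = s,
    fo_variance = popVar(x),
    fo_skewness = popSkew(x),
    fo_kurtosis = popKurt(x),
    fo_min = min(x),
    fo_max = max(x),
    fo_range = diff(range(x)),
    fo_median = q[4],
    fo_p05 = q[1], fo_p10 = q[2], fo_p25 = q[3],
    fo_p75 = q[5], fo_p90 = q[6], fo_p95 = q[7],
    fo_iqr = q[5] - q[3],
    fo_interdecile_range = q[6] - q[2],
    fo_energy = sum(x^2),
    fo_rms = sqrt(mean(x^2)),
    fo_entropy = shannonEntropy(p),
    fo_uniformity = sum(p^2),
    fo_mad = mean(abs(x - m)),
    fo_robust_mad = median(abs(x - median(x))),
    fo_cov = if (abs(m) > 1e-12) s / m else 0,
    fo_mode = modeVal,
    fo_smoothness = 1 - 1 / (1 + popVar(x)),
    fo_midrange = (min(x) + max(x)) / 2,
    fo_trimmed_mean = mean(x, trim = 0.1))
}

glcmFeatureNames <- c(
  "energy", "contrast", "correlation", "variance", "idm",
  "sum_average", "sum_variance", "sum_entropy", "entropy",
  "difference_variance", "difference_entropy", "imc1", "imc2",
  "autocorrelation", "cluster_shade", "cluster_prominence",
  "cluster_tendency", "dissimilarity", "maximum_probability",
  "inverse_difference", "idn", "idmn")

# Symmetric direction-summed co-occurrence counts for one offset.
# Directions: 0, 45, 90, 135 degrees; pairs counted in both orders.
glcmCounts <- function(q, L, d) {
  nr <- nrow(q); nc <- ncol(q)
  cnt <- matrix(0, L, L)
  dirs <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  for (dd in dirs) {
    dr <- dd[1]; dc <- dd[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    tab <- tabulate(as.integer(a) * L + as.integer(b) + 1L, L * L)
    cnt <- cnt + matrix(tab, L, L, byrow = TRUE)
  }
  cnt + t(cnt)
}

# The 22 co-occurrence features from a normalized symmetric matrix P.
glcmStatistics <- function(P) {
  L <- nrow(P)
  i <- matrix(rep(1:L, L), L)       # row level index (1-based)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sdx <- sqrt(sum(((1:L) - mux)^2 * px))
  sdy <- sqrt(sum(((1:L) - muy)^2 * py))
  # p_{x+y}(k), k = 2..2L ; p_{x-y}(k), k = 0..L-1
  sums <- as.integer(i + j); diffs <- as.integer(abs(i - j))
  pxy <- vapply(2:(2 * L), function(k) sum(P[sums == k]), numeric(1))
  pxmy <- vapply(0:(L - 1), function(k) sum(P[diffs == k]), numeric(1))
  kS <- 2:(2 * L); kD <- 0:(L - 1)
  sumAvg <- sum(kS * pxy)
  diffAvg <- sum(kD * pxmy)
  hxy <- shannonEntropy(as.numeric(P))
  hx <- shannonEntropy(px); hy <- shannonEntropy(py)
  eps <- .Machine$double.xmin
  hxy1 <- -sum(P * log(pmax(px[row(P)] * py[col(P)], eps)) * (P > 0))
  hxy2 <- -sum(px[row(P)] * py[col(P)] *
                 log(pmax(px[row(P)] * py[col(P)], eps)))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sdx > 0 && sdy > 0)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0
  mu <- sum(i * P)
  c(energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    variance = sum((i - mu)^2 * P),
    idm = sum(P / (1 + (i - j)^2)),
    sum_average = sumAvg,
    sum_variance = sum((kS - sumAvg)^2 * pxy),
    sum_entropy = shannonEntropy(pxy),
    entropy = hxy,
    difference_variance = sum((kD - diffAvg)^2 * pxmy),
    difference_entropy = shannonEntropy(pxmy),
    imc1 = imc1,
    imc2 = imc2,
    autocorrelation = sum(i * j * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    maximum_probability = max(P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    idn = sum(P / (1 + abs(i - j) / L)),
    idmn = sum(P / (1 + (i - j)^2 / L^2)))
}

#' Grey-level co-occurrence features
#'
#' For each pixel offset (1, 3, 5 and 9 by default), symmetric
#' co-occurrence counts are accumulated over the four principal directions
#' (0, 45, 90, 135 degrees), normalized into one direction-averaged
#' probability matrix, and summarized by 22 features (the 13 Haralick
#' statistics plus 9 extended ones).  An ROI thinner than an offset in both
#' dimensions yields zeros (flagged) for that offset.
#'
#' @param qroi quantized ROI from [quantizeROI()].
#' @param offsets integer pixel offsets (default c(1, 3, 5, 9)).
#' @return named numeric vector of length 22 x length(offsets)
#'   (`glcm_<name>_d<offset>`).
#' @export
glcmFeatures <- function(qroi, offsets = c(1L, 3L, 5L, 9L)) {
  L <- attr(qroi, "levels")
  if (is.null(L)) L <- max(qroi) + 1L
  out <- numeric(0)
  for (d in offsets) {
    if (nrow(qroi) <= d && ncol(qroi) <= d) {
      vals <- setNames(rep(0, 22), glcmFeatureNames)
      attr(out, "flagged") <- c(attr(out, "flagged"), paste0("d", d))
    } else {
      cnt <- glcmCounts(qroi, L, d)
      vals <- if (sum(cnt) > 0) glcmStatistics(cnt / sum(cnt)) else
        setNames(rep(0, 22), glcmFeatureNames)
    }
    flg <- attr(out, "flagged")
    out <- c(out, setNames(vals, paste0("glcm_", glcmFeatureNames,
                                        "_d", d)))
    attr(out, "flagged") <- flg
  }
  out
}
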