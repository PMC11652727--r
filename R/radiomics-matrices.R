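#' @include AllClasses.R utils.R
NULL

# Run-length table of one direction: list of runs (level, length).
# Directions: "0" rows, "90" columns, "45" anti-diagonals, "135" diagonals.
runsInDirection <- function(q, direction) {
  nr <- nrow(q); nc <- ncol(q)
  seqs <- switch(direction,
    "0" = split(as.integer(t(q)), rep(seq_len(nr), each = nc)),
    "90" = split(as.integer(q), rep(seq_len(nc), each = nr)),
    "45" = split(as.integer(q[, nc:1]), as.integer(row(q) - col(q))),
    "135" = split(as.integer(q), row(q) - col(q)),
    stop("unknown direction"))
  runs <- lapply(seqs, function(s) {
    r <- rle(s)
    cbind(level = r$values, length = r$lengths)
  })
  do.call(rbind, runs)
}

glrlmStatsFromRuns <- function(runs, nPixels) {
  l <- runs[, "length"]; g <- runs[, "level"]
  nr <- nrow(runs)
  c(glrlm_sre = sum(1 / l^2) / nr,
    glrlm_lre = sum(l^2) / nr,
    glrlm_grey_level_nonuniformity =
      sum(tapply(rep(1, nr), g, sum)^2) / nr,
    glrlm_run_length_nonuniformity =
      sum(tapply(rep(1, nr), l, sum)^2) / nr,
    glrlm_run_percentage = nr / nPixels,
    glrlm_lglre = sum(1 / (g + 1)^2) / nr)
}

#' Grey-level run-length features
#'
#' Runs of identical grey level are enumerated along the four principal
#' directions; the six statistics (short/long-run emphasis, grey-level and
#' run-length nonuniformity, run percentage, low-grey-level run emphasis)
#' are averaged over directions.  Levels are 0-based; the low-grey-level
#' emphasis weights by 1/(level+1)^2.
#'
#' @param qroi quantized ROI.
#' @return named numeric vector of length 6.
#' @export
glrlmFeatures <- function(qroi) {
  n <- length(qroi)
  per <- vapply(c("0", "45", "90", "135"), function(d)
    glrlmStatsFromRuns(runsInDirection(qroi, d), n), numeric(6))
  rowMeans(per)
}

gldsStats <- c("mean", "contrast", "energy", "entropy", "idm")

#' Grey-level difference statistics
#'
#' Absolute differences between each pixel and the mean of its local
#' neighbourhood (window sizes 3, 5 and 7), summarized by the mean,
#' contrast (mean squared difference), and the energy, entropy and inverse
#' difference moment of a 32-bin histogram of the differences.  An ROI
#' smaller than a window yields zeros for that window (flagged).
#'
#' @param roi numeric matrix (prepared intensities).
#' @return named numeric vector of length 15 (`glds_<stat>_w<size>`).
#' @export
gldsFeatures <- function(roi) {
  out <- numeric(0)
  for (w in c(3L, 5L, 7L)) {
    nm <- paste0("glds_", gldsStats, "_w", w)
    if (min(dim(roi)) < w) {
      out <- c(out, setNames(rep(0, 5), nm))
      next
    }
    local <- convolve2(roi, boxKernel(w))
    d <- abs(roi - local)
    mx <- max(d)
    if (mx == 0) {
      vals <- c(0, 0, 1, 0, 1)
    } else {
      nb <- 32L
      edges <- seq(0, mx, length.out = nb + 1)
      p <- tabulate(findInterval(d, edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), nb)
      p <- p / sum(p)
      centres <- (edges[-1] + edges[-(nb + 1)]) / 2
      vals <- c(mean(d), mean(d^2), sum(p^2), shannonEntropy(p),
                sum(p / (1 + centres^2)))
    }
    out <- c(out, setNames(vals, nm))
  }
  out
}

ngtdmStats <- c("coarseness", "contrast", "busyness", "complexity",
                "strength")

ngtdmAtRadius <- function(q, d) {
  nr <- nrow(q); nc <- ncol(q)
  nm <- paste0("ngtdm_", ngtdmStats, "_r", d)
  if (nr < 2 * d + 1 || nc < 2 * d + 1)
    return(setNames(c(1e6, 0, 0, 0, 0), nm))
  w <- 2L * d + 1L
  boxSum <- convolve2(q + 0, matrix(1, w, w))
  nbMean <- (boxSum - q) / (w * w - 1)
  rows <- (d + 1):(nr - d); cols <- (d + 1):(nc - d)
  g <- as.integer(q[rows, cols])
  dev <- abs(g - as.numeric(nbMean[rows, cols]))
  N <- length(g)
  levels <- sort(unique(g))
  s <- vapply(levels, function(gl) sum(dev[g == gl]), numeric(1))
  p <- vapply(levels, function(gl) sum(g == gl), numeric(1)) / N
  eps <- 1e-12
  coarse <- min(1 / (eps + sum(p * s)), 1e6)
  ng <- length(levels)
  if (ng < 2) return(setNames(c(coarse, 0, 0, 0, sum(s) * 0), nm))
  pi_ <- matrix(p, ng, ng); pj_ <- t(pi_)
  li <- matrix(levels, ng, ng); lj <- t(li)
  si <- matrix(s, ng, ng); sj <- t(si)
  contrast <- (sum(pi_ * pj_ * (li - lj)^2) / (ng * (ng - 1))) *
    (sum(dev) / N)
  busyDen <- sum(abs(li * pi_ - lj * pj_))
  busy <- if (busyDen > 0) sum(p * s) / busyDen else 0
  complexity <- sum(abs(li - lj) * (pi_ * si + pj_ * sj) /
                      (N * (pi_ + pj_)))
  strength <- sum((pi_ + pj_) * (li - lj)^2) / (eps + sum(s))
  setNames(c(coarse, contrast, busy, complexity, strength), nm)
}

#' Neighbourhood grey-tone difference features
#'
#' Amadasun-King coarseness, contrast, busyness, complexity and strength,
#' computed at neighbourhood radii 1, 2 and 3 on the quantized ROI.  A
#' constant ROI has zero contrast and saturated (capped) coarseness.
#'
#' @param qroi quantized ROI.
#' @return named numeric vector of length 15 (`ngtdm_<stat>_r<radius>`).
#' @export
ngtdmFeatures <- function(qroi) {
  unlist(lapply(c(1L, 2L, 3L), function(d) ngtdmAtRadius(qroi, d)))
}

#' Grey-level sharpness features
#'
#' Statistics of the central-difference gradient-magnitude map computed on
#' the ROI interior: mean, variance, skewness, kurtosis, energy (mean
#' squared magnitude) and the entropy of a 32-bin magnitude histogram.
#'
#' @param roi numeric matrix, at least 3 x 3.
#' @return named numeric vector of length 6 (prefix `glsm_`).
#' @export
glsmFeatures <- function(roi) {
  assertThat(nrow(roi) >= 3 && ncol(roi) >= 3, "ROI must be at least 3 x 3")
  nr <- nrow(roi); nc <- ncol(roi)
  gx <- (roi[2:(nr - 1), 3:nc] - roi[2:(nr - 1), 1:(nc - 2)]) / 2
  gy <- (roi[3:nr, 2:(nc - 1)] - roi[1:(nr - 2), 2:(nc - 1)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  ent <- if (mx > 0) {
    nb <- 32L
    edges <- seq(0, mx, length.out = nb + 1)
    p <- tabulate(findInterval(mag, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nb)
    shannonEntropy(p / sum(p))
  } else 0
  c(glsm_mean = mean(mag), glsm_variance = popVar(as.numeric(mag)),
    glsm_skewness = popSkew(as.numeric(mag)),
    glsm_kurtosis = popKurt(as.numeric(mag)),
    glsm_energy = mean(mag^2), glsm_entropy = ent)
}

sfmStats <- c("coarseness", "contrast", "periodicity", "roughness")

sfmAtSpacing <- function(x, L) {
  nm <- paste0("sfm_", sfmStats, "_L", L)
  nr <- nrow(x); nc <- ncol(x)
  if (min(nr, nc) <= L) return(setNames(rep(0, 4), nm))
  deltas <- rbind(cbind(0, 1:L),
                  do.call(rbind, lapply(1:L, function(dr)
                    cbind(dr, -L:L))))
  dis <- numeric(nrow(deltas)); con <- numeric(nrow(deltas))
  for (k in seq_len(nrow(deltas))) {
    dr <- deltas[k, 1]; dc <- deltas[k, 2]
    r1 <- 1:(nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    dd <- x[r1, c1, drop = FALSE] - x[r1 + dr, c1 + dc, drop = FALSE]
    dis[k] <- mean(abs(dd)); con[k] <- mean(dd^2)
  }
  unitIdx <- which((deltas[, 1] == 0 & deltas[, 2] == 1) |
                     (deltas[, 1] == 1 & abs(deltas[, 2]) <= 1))
  mdis <- mean(dis)
  coarse <- min(1 / (1e-12 + mdis), 1e6)
  contrast <- sqrt(mean(con[unitIdx]))
  periodicity <- if (mdis > 0) (mdis - min(dis)) / mdis else 0
  r <- sqrt(deltas[, 1]^2 + deltas[, 2]^2)
  rBin <- round(r)
  mr <- tapply(dis, rBin, mean)
  rv <- as.numeric(names(mr))
  ok <- rv >= 1 & mr > 0
  rough <- if (sum(ok) >= 2) {
    3 - unname(coef(stats::lm(log(mr[ok]) ~ log(rv[ok])))[2])
  } else 0
  setNames(c(coarse, contrast, periodicity, rough), nm)
}

#' Statistical feature matrix features
#'
#' Inter-pixel statistics over all displacements up to a maximum spacing:
#' coarseness (inverse mean absolute difference), contrast (RMS difference
#' at unit displacements), periodicity (relative dip of the dissimilarity
#' curve, near 1 for textures whose period falls inside the displacement
#' set) and roughness (3 minus the Hurst slope of dissimilarity versus
#' displacement length).  Computed at spacings 4 and 8.
#'
#' @param roi numeric matrix (the quantized or prepared ROI).
#' @return named numeric vector of length 8 (`sfm_<stat>_L<spacing>`).
#' @export
sfmFeatures <- function(roi) {
  x <- roi + 0  # strip integer storage
  c(sfmAtSpacing(x, 4L), sfmAtSpacing(x, 8L))
}

#' Differential box-counting fractal dimension
#'
#' Intensities are scaled to 0..255 and covered by boxes of side s in
#' {2, 4, 8, 16} (restricted to s <= min(dim)/2); the box count at each
#' scale sums ceil spans of the intensity surface, and the dimension is
#' the least-squares slope of log(count) versus log(1/s).  Fewer than two
#' usable scales yields 0 (flagged).
#'
#' @param roi numeric matrix; 32 x 32 or larger engages all four scales.
#' @return named numeric vector of length 1 (`fractal_dimension`).
#' @export
fractalDimension <- function(roi) {
  nr <- nrow(roi); nc <- ncol(roi)
  scales <- c(2L, 4L, 8L, 16L)
  scales <- scales[scales <= min(nr, nc) / 2]
  if (length(scales) < 2) return(c(fractal_dimension = 0))
  rng <- diff(range(roi))
  g <- if (rng > 0) (roi - min(roi)) / rng * 255 else matrix(0, nr, nc)
  counts <- vapply(scales, function(s) {
    h <- s * 256 / min(nr, nc)
    rIdx <- (seq_len(nr) - 1L) %/% s
    cIdx <- (seq_len(nc) - 1L) %/% s
    key <- interaction(rIdx[row(g)], cIdx[col(g)], drop = TRUE)
    mx <- tapply(g, key, max); mn <- tapply(g, key, min)
    sum(floor(mx / h) - floor(mn / h) + 1)
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(1 / scales))
  c(fractal_dimension = unname(coef(fit)[2]))
}
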