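#' @include AllClasses.R utils.R
NULL

lawsVectors <- list(
  L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
  S5 = c(-1, 0, 2, 0, -1), R5 = c(1, -4, 6, -4, 1))

lawsPairs <- list(
  c("L5", "E5"), c("L5", "S5"), c("L5", "R5"),
  c("E5", "S5"), c("E5", "R5"), c("S5", "R5"),
  c("E5", "E5"), c("S5", "S5"), c("R5", "R5"))

#' Laws texture energy features
#'
#' 5x5 kernels are formed as outer products of the level, edge, spot and
#' ripple vectors; each filtered map is converted to a texture-energy map
#' by a 15x15 moving average of absolute responses, symmetric kernel pairs
#' (e.g. L5E5/E5L5) are averaged, and each of the 9 resulting maps is
#' summarized by its mean and standard deviation.  A constant ROI has zero
#' energy everywhere because every kernel involving E5, S5 or R5 sums to
#' zero (the pure L5L5 map is not used).
#'
#' @param roi numeric matrix, ideally at least 15 x 15.
#' @return named numeric vector of length 18
#'   (`laws_<pair>_mean`, `laws_<pair>_sd`).
#' @export
lawsFeatures <- function(roi) {
  combos <- unique(unlist(lapply(lawsPairs, function(p)
    c(paste0(p[1], p[2]), paste0(p[2], p[1])))))
  kernels <- lapply(combos, function(nm)
    outer(lawsVectors[[substr(nm, 1, 2)]], lawsVectors[[substr(nm, 3, 4)]]))
  names(kernels) <- combos
  resp <- fftCorrelate(roi, kernels, 2L, cacheKey = "laws")
  energy <- function(nm)
    fftCorrelate(abs(resp[[nm]]), list(b = boxKernel(15L)), 7L,
                 cacheKey = "box15")[[1]]
  out <- numeric(0)
  for (p in lawsPairs) {
    e <- if (p[1] == p[2]) energy(paste0(p[1], p[2])) else
      (energy(paste0(p[1], p[2])) + energy(paste0(p[2], p[1]))) / 2
    nm <- paste0("laws_", p[1], p[2])
    out <- c(out, setNames(c(mean(e), popSD(as.numeric(e))),
                           paste0(nm, c("_mean", "_sd"))))
  }
  out
}

#' Build the even-symmetric Gabor bank
#'
#' Six DC-corrected cosine-phase Gabor kernels at a carrier wavelength of
#' 4 pixels/cycle and orientations 0, 30, 60, 90, 120 and 150 degrees.
#' The Gaussian envelope SD follows a one-octave bandwidth
#' (sigma ~ 0.56 lambda); aspect ratio 1.
#'
#' @param wavelength carrier wavelength in pixels/cycle (default 4).
#' @param orientations filter orientations in degrees.
#' @return named list of kernels (`theta<deg>`), each summing to zero.
#' @export
gaborBank <- function(wavelength = 4,
                      orientations = c(0, 30, 60, 90, 120, 150)) {
  sigma <- 0.56 * wavelength
  half <- ceiling(3 * sigma)
  ax <- seq(-half, half)
  xs <- matrix(rep(ax, each = length(ax)), length(ax))  # x = column offset
  ys <- matrix(rep(ax, length(ax)), length(ax))         # y = row offset
  kernels <- lapply(orientations, function(deg) {
    th <- deg * pi / 180
    u <- xs * cos(th) + ys * sin(th)
    env <- exp(-(xs^2 + ys^2) / (2 * sigma^2))
    g <- env * cos(2 * pi * u / wavelength)
    g - env * sum(g) / sum(env)  # DC correction preserving the envelope
  })
  names(kernels) <- paste0("theta", orientations)
  kernels
}

#' Gabor filter features
#'
#' Mean absolute response of the ROI to each of the six wavelength-4
#' even-symmetric Gabor filters.  A cosine grating at the carrier
#' wavelength maximizes the feature of the matching orientation.
#'
#' @param roi numeric matrix.
#' @param bank kernel list from [gaborBank()].
#' @return named numeric vector of length 6 (`gabor_theta<deg>`).
#' @export
gaborFeatures <- function(roi, bank = gaborBank()) {
  half <- nrow(bank[[1]]) %/% 2L
  resp <- fftCorrelate(roi, bank, half, cacheKey = "gabor")
  vapply(setNames(names(bank), paste0("gabor_", names(bank))),
         function(nm) mean(abs(resp[[nm]])), numeric(1))
}

# One oriented Gaussian-derivative kernel: first (edge) or second (bar)
# derivative across the elongation, elongated along the filter direction.
orientedDerivKernel <- function(sAcross, sAlong, thetaDeg, order, half = 24L) {
  ax <- seq(-half, half)
  xs <- matrix(rep(ax, each = length(ax)), length(ax))
  ys <- matrix(rep(ax, length(ax)), length(ax))
  th <- thetaDeg * pi / 180
  u <- xs * cos(th) + ys * sin(th)    # along the filter
  v <- -xs * sin(th) + ys * cos(th)   # across the filter
  gAlong <- exp(-u^2 / (2 * sAlong^2))
  gAcross <- exp(-v^2 / (2 * sAcross^2))
  k <- if (order == 1L) (-v / sAcross^2) * gAcross * gAlong else
    ((v^2 / sAcross^2 - 1) / sAcross^2) * gAcross * gAlong
  k <- k - mean(k)
  k / sum(abs(k))
}

#' Build the 38-filter root filter set
#'
#' A rotationally symmetric Gaussian and Laplacian-of-Gaussian (sigma 10
#' pixels) plus first-derivative (edge) and second-derivative (bar)
#' oriented Gaussian filters at scales (sigma across, sigma along) of
#' (1, 3), (2, 6) and (4, 12), each at orientations 0, 30, 60, 90, 120 and
#' 150 degrees: 2 + 2 x 3 x 6 = 38 kernels.  All kernels are L1-normalized
#' and, except the Gaussian, zero-mean.
#'
#' @return list with `kernels` (named list of 38 matrices) and `meta`
#'   (data.frame: name, type, scale, orientation).
#' @export
buildRFSBank <- function() {
  half <- 24L
  ax <- seq(-half, half)
  r2 <- outer(ax^2, rep(1, length(ax))) + outer(rep(1, length(ax)), ax^2)
  sigma <- 10
  gauss <- exp(-r2 / (2 * sigma^2))
  gauss <- gauss / sum(abs(gauss))
  log_ <- (r2 / sigma^4 - 2 / sigma^2) * exp(-r2 / (2 * sigma^2))
  log_ <- log_ - mean(log_)
  log_ <- log_ / sum(abs(log_))
  kernels <- list(gaussian = gauss, log = log_)
  meta <- data.frame(name = c("gaussian", "log"),
                     type = c("gaussian", "log"), scale = NA_integer_,
                     orientation = NA_real_, stringsAsFactors = FALSE)
  scales <- list(c(1, 3), c(2, 6), c(4, 12))
  for (type in c("edge", "bar")) {
    for (si in seq_along(scales)) {
      for (deg in c(0, 30, 60, 90, 120, 150)) {
        nm <- sprintf("%s_s%d_t%d", type, si, deg)
        kernels[[nm]] <- orientedDerivKernel(scales[[si]][1],
                                             scales[[si]][2], deg,
                                             if (type == "edge") 1L else 2L,
                                             half)
        meta <- rbind(meta, data.frame(name = nm, type = type,
                                       scale = si, orientation = deg,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  assertThat(length(kernels) == 38L, "RFS bank must contain 38 kernels")
  list(kernels = kernels, meta = meta)
}

#' Maximum-response (MR8) features
#'
#' The 38 root-filter-set responses are collapsed to 8: the Gaussian and
#' Laplacian-of-Gaussian responses pass through, while the edge and bar
#' responses at each scale keep only the per-pixel maximum across the six
#' orientations (rotational insensitivity).  Each of the 8 response maps is
#' summarized by its signed mean over the ROI.
#'
#' @param roi numeric matrix.
#' @param bank the [buildRFSBank()] result.
#' @return named numeric vector of length 8 (`mr_gaussian`, `mr_log`,
#'   `mr_edge_s1..3`, `mr_bar_s1..3`).
#' @export
mr8Features <- function(roi, bank = buildRFSBank()) {
  assertThat(length(bank$kernels) == 38L, "bank must contain 38 kernels")
  resp <- fftCorrelate(roi, bank$kernels, 24L, cacheKey = "rfs")
  out <- c(mr_gaussian = mean(resp$gaussian), mr_log = mean(resp$log))
  for (type in c("edge", "bar")) {
    for (si in 1:3) {
      nms <- bank$meta$name[bank$meta$type == type & bank$meta$scale == si]
      mx <- Reduce(pmax, resp[nms])
      out[sprintf("mr_%s_s%d", type, si)] <- mean(mx)
    }
  }
  out
}

#' Fourier spectral band features
#'
#' Fraction of the non-DC spectral energy at radial frequencies below and
#' above one quarter of the Nyquist frequency (0.125 cycles/pixel).  The
#' two fractions partition the non-DC energy, so they sum to 1 for any
#' non-constant ROI.
#'
#' @param roi numeric matrix, at least 8 x 8.
#' @return named numeric vector `c(fourier_low_fraction,
#'   fourier_high_fraction)`.
#' @export
fourierFeatures <- function(roi) {
  assertThat(nrow(roi) >= 8 && ncol(roi) >= 8, "ROI must be at least 8 x 8")
  nr <- nrow(roi); nc <- ncol(roi)
  P <- Mod(fft(roi))^2
  fr <- (0:(nr - 1)) / nr; fr[fr > 0.5] <- fr[fr > 0.5] - 1
  fc <- (0:(nc - 1)) / nc; fc[fc > 0.5] <- fc[fc > 0.5] - 1
  rad <- sqrt(outer(fr^2, rep(1, nc)) + outer(rep(1, nr), fc^2))
  P[1, 1] <- 0  # exclude DC
  tot <- sum(P)
  if (tot == 0) return(c(fourier_low_fraction = 0, fourier_high_fraction = 0))
  lo <- sum(P[rad < 0.125]) / tot
  c(fourier_low_fraction = lo, fourier_high_fraction = 1 - lo)
}
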