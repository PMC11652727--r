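#' @include AllClasses.R
NULL

# Run code under a temporary seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a child seed from a parent seed and a stream index, kept within
# 32-bit integer range.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %%
               2147483587) + 1L
}

# Mirror an arbitrary integer index into 1..n (reflection without edge
# repetition; period 2(n-1)).
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  n - abs((i - 1L) %% (2L * (n - 1L)) - (n - 1L))
}

# Reflect-pad a matrix by m rows/columns on every side.
reflectPad <- function(x, m) {
  if (m <= 0) return(x)
  x[reflectIndex(seq(1L - m, nrow(x) + m), nrow(x)),
    reflectIndex(seq(1L - m, ncol(x) + m), ncol(x)), drop = FALSE]
}

.fftCache <- new.env(parent = emptyenv())

# Batched 2-D cross-correlation with reflect padding via FFT.  All kernels
# (odd-sized, half-width <= half) share one forward transform of the
# padded image; kernel transforms are cached under cacheKey so repeated
# calls on same-sized ROIs skip them.  Padding extends to a 2-3-smooth
# size with zeros beyond the reflected ring, which cannot reach the
# cropped interior.
fftCorrelate <- function(x, kernels, half, cacheKey = NULL) {
  nr <- nrow(x); nc <- ncol(x)
  p1 <- reflectPad(x, half)
  Nr <- stats::nextn(nrow(p1), c(2, 3))
  Nc <- stats::nextn(ncol(p1), c(2, 3))
  P <- matrix(0, Nr, Nc)
  P[seq_len(nrow(p1)), seq_len(ncol(p1))] <- p1
  F0 <- stats::fft(P)
  out <- vector("list", length(kernels))
  names(out) <- names(kernels)
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    key <- if (is.null(cacheKey)) NULL else
      paste(cacheKey, names(kernels)[i], Nr, Nc, nrow(k), ncol(k),
            signif(sum(k * seq_along(k)), 12), sep = "|")
    FkC <- if (!is.null(key)) .fftCache[[key]] else NULL
    if (is.null(FkC)) {
      hr <- nrow(k) %/% 2L; hc <- ncol(k) %/% 2L
      K <- matrix(0, Nr, Nc)
      K[((-hr:hr) %% Nr) + 1L, ((-hc:hc) %% Nc) + 1L] <- k
      FkC <- Conj(stats::fft(K))
      if (!is.null(key)) .fftCache[[key]] <- FkC
    }
    R <- Re(stats::fft(F0 * FkC, inverse = TRUE)) / (Nr * Nc)
    out[[i]] <- R[(half + 1):(half + nr), (half + 1):(half + nc),
                  drop = FALSE]
  }
  out
}

# 2-D correlation of an image with one odd-sized kernel, reflect padding;
# output has the size of the input.
convolve2 <- function(x, kernel) {
  stopifnot(nrow(kernel) %% 2 == 1, ncol(kernel) %% 2 == 1)
  m <- max(nrow(kernel), ncol(kernel)) %/% 2L
  fftCorrelate(x, list(k = kernel), m)[[1]]
}

gaussianKernel <- function(sigma, halfSize = ceiling(3 * sigma)) {
  ax <- seq(-halfSize, halfSize)
  k <- outer(ax, ax, function(y, x) exp(-(x^2 + y^2) / (2 * sigma^2)))
  k / sum(k)
}

boxKernel <- function(size) matrix(1 / size^2, size, size)

# Population moments used throughout the image/feature code.
popVar <- function(x) mean((x - mean(x))^2)
popSD <- function(x) sqrt(popVar(x))
popSkew <- function(x) {
  s <- popSD(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}
popKurt <- function(x) {
  s <- popSD(x)
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4
}

# Shannon entropy (nats) of a probability vector; zero bins contribute zero.
shannonEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

assertThat <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
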