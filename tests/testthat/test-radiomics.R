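test_that("feature bank cardinalities are conserved", {
  set.seed(1)
  roi <- matrix(rnorm(4096), 64)
  f <- extractAllFeatures(roi)
  expect_length(f, 201)
  dict <- featureDictionary()
  counts <- table(dict$family)
  expect_equal(counts[["first_order"]], 28)
  expect_equal(counts[["glcm"]], 88)
  expect_equal(counts[["glrlm"]], 6)
  expect_equal(counts[["glsm"]], 6)
  expect_equal(counts[["glds"]], 15)
  expect_equal(counts[["ngtdm"]], 15)
  expect_equal(counts[["sfm"]], 8)
  expect_equal(counts[["fractal"]], 1)
  expect_equal(counts[["laws"]], 18)
  expect_equal(counts[["gabor"]], 6)
  expect_equal(counts[["mr"]], 8)
  expect_equal(counts[["fourier"]], 2)
  # 28 + 139 + 34 partition
  texture <- c("glcm", "glrlm", "glsm", "glds", "ngtdm", "sfm", "fractal")
  filt <- c("laws", "gabor", "mr", "fourier")
  expect_equal(sum(counts[texture]), 139)
  expect_equal(sum(counts[filt]), 34)
  # determinism and stable names
  expect_identical(f, extractAllFeatures(roi))
  expect_identical(names(f), dict$name)
})

test_that("first-order features match hand arithmetic and degenerate limits", {
  f <- firstOrderFeatures(c(1, 2, 3, 4))
  expect_equal(unname(f["fo_mean"]), 2.5)
  expect_equal(unname(f["fo_variance"]), 1.25)  # population variance
  expect_equal(unname(f["fo_min"]), 1)
  expect_equal(unname(f["fo_max"]), 4)
  expect_equal(unname(f["fo_energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["fo_median"]), 2.5)
  fc <- firstOrderFeatures(matrix(3, 5, 5))
  expect_equal(unname(fc["fo_sd"]), 0)
  expect_equal(unname(fc["fo_entropy"]), 0)
  expect_equal(unname(fc["fo_uniformity"]), 1)
  expect_equal(unname(fc["fo_skewness"]), 0)
  expect_length(f, 28)
})

test_that("co-occurrence features match the tiny worked example", {
  q <- matrix(c(0L, 1L, 0L, 1L), 2)  # rows: (0,0) / (1,1)
  attr(q, "levels") <- 2L
  # offset 1, all four directions, symmetric
  cnt <- oracleGLCMCounts(q, 2, 1)
  P <- cnt / sum(cnt)
  f <- glcmFeatures(q, offsets = 1L)
  expect_equal(unname(f["glcm_energy_d1"]), sum(P^2))
  # horizontal-only hand case: [[0,0],[1,1]] gives P(0,0)=P(1,1)=1/2
  cnt0 <- mammoErrors:::glcmCounts(matrix(c(0L, 1L, 0L, 1L), 2), 2L, 1L)
  # restrict by hand: the 0-degree pairs are (0,0) and (1,1)
  ph <- matrix(c(2, 0, 0, 2), 2) / 4
  st <- mammoErrors:::glcmStatistics(ph)
  expect_equal(unname(st["energy"]), 0.5)
  expect_equal(unname(st["contrast"]), 0)
})

test_that("matrix families equal brute force on random quantized images", {
  for (s in 1:60) {
    q <- randomQuantized(6, 6, 4, seed = s)
    # GLCM counts, exact
    cnt <- mammoErrors:::glcmCounts(q, 4L, 1L)
    expect_identical(unname(cnt), unname(oracleGLCMCounts(q, 4, 1)))
    # GLCM derived statistics vs simple-loop oracle
    P <- cnt / sum(cnt)
    st <- mammoErrors:::glcmStatistics(P)
    or <- oracleGLCMStats(P)
    for (nm in names(or))
      expect_lt(abs(st[[nm]] - or[[nm]]), 1e-9)
    # GLRLM, direction-averaged
    got <- glrlmFeatures(q)
    want <- oracleGLRLM(q)
    expect_lt(max(abs(unname(got) - unname(want))), 1e-9)
  }
})

test_that("run statistics match manual enumeration on a single row", {
  q <- matrix(c(0L, 0L, 0L, 1L), 1)
  runs <- mammoErrors:::runsInDirection(q, "0")
  expect_equal(nrow(runs), 2)           # runs (0,3) and (1,1)
  st <- mammoErrors:::glrlmStatsFromRuns(runs, 4)
  expect_equal(unname(st["glrlm_run_percentage"]), 2 / 4)
  # constant row: a single run, LRE = n^2
  qc <- matrix(0L, 1, 7)
  stc <- mammoErrors:::glrlmStatsFromRuns(
    mammoErrors:::runsInDirection(qc, "0"), 7)
  expect_equal(unname(stc["glrlm_lre"]), 49)
})

test_that("difference statistics follow the windowed-mean oracle", {
  set.seed(5)
  roi <- matrix(rnorm(100), 10)
  f <- gldsFeatures(roi)
  expect_length(f, 15)
  for (w in c(3L, 5L)) {
    d <- oracleGLDS(roi, w)
    expect_lt(abs(f[[paste0("glds_mean_w", w)]] - mean(d)), 1e-9)
    expect_lt(abs(f[[paste0("glds_contrast_w", w)]] - mean(d^2)), 1e-9)
  }
  # single bright pixel: per the windowed oracle, the ROI-mean absolute
  # difference is 2x(1 - 1/w^2)/N, so it grows with the window
  flat <- matrix(0, 15, 15); flat[8, 8] <- 10
  fb <- gldsFeatures(flat)
  expect_equal(fb[["glds_mean_w3"]], 2 * 10 * (1 - 1 / 9) / 225,
               tolerance = 1e-9)
  expect_lt(fb[["glds_mean_w3"]], fb[["glds_mean_w5"]])
  # at the spike itself the tighter window sees the smaller deviation
  d3 <- oracleGLDS(flat, 3); d5 <- oracleGLDS(flat, 5)
  expect_lt(d3[8, 8], d5[8, 8])
  fc <- gldsFeatures(matrix(1, 9, 9))
  expect_equal(unname(fc["glds_mean_w3"]), 0)
  expect_equal(unname(fc["glds_energy_w3"]), 1)
})

test_that("grey-tone difference features match per-pixel sums", {
  for (s in 1:20) {
    q <- randomQuantized(8, 8, 4, seed = 100 + s)
    o <- oracleNGTDM(q, 1)
    f <- ngtdmFeatures(q)
    coarse <- min(1 / (1e-12 + sum(o$p * o$s)), 1e6)
    expect_lt(abs(f[["ngtdm_coarseness_r1"]] - coarse), 1e-6)
  }
  fc <- ngtdmFeatures(matrix(0L, 9, 9))
  expect_equal(unname(fc["ngtdm_coarseness_r1"]), 1e6)  # capped
  expect_equal(unname(fc["ngtdm_contrast_r1"]), 0)
  expect_length(fc, 15)
})

test_that("sharpness features recover analytic gradients", {
  ramp <- outer(rep(1, 12), seq(0, 22, by = 2))  # slope 2 along x
  f <- glsmFeatures(ramp)
  expect_equal(unname(f["glsm_mean"]), 2)
  expect_equal(unname(f["glsm_variance"]), 0)
  fc <- glsmFeatures(matrix(5, 6, 6))
  expect_true(all(fc[c("glsm_mean", "glsm_energy", "glsm_entropy")] == 0))
  expect_length(f, 6)
})

test_that("statistical feature matrix detects periodicity and matches loops", {
  set.seed(7)
  x <- matrix(rnorm(144), 12)
  f <- sfmFeatures(x)
  expect_length(f, 8)
  o <- oracleSFMDelta(x, 0, 1)
  expect_lt(abs(mean((x[, 1:11] - x[, 2:12])^2) - o[["con"]]), 1e-9)
  # period-4 vertical stripes: the L = 4 displacement set contains the
  # period, so the dissimilarity curve dips to ~0
  stripes <- matrix(rep(cos(2 * pi * (0:15) / 4), each = 16), 16)
  fs <- sfmFeatures(t(stripes))
  expect_gt(fs[["sfm_periodicity_L4"]], 0.9)
  set.seed(8)
  fn <- sfmFeatures(matrix(rnorm(256), 16))
  expect_lt(fn[["sfm_periodicity_L4"]], fs[["sfm_periodicity_L4"]])
  fc <- sfmFeatures(matrix(2, 12, 12))
  expect_equal(unname(fc["sfm_contrast_L4"]), 0)
})

test_that("fractal dimension separates planes from noise", {
  plane <- outer(seq_len(32), seq_len(32), function(r, cc) r * 0 + 1)
  expect_lt(abs(fractalDimension(plane)[["fractal_dimension"]] - 2), 0.1)
  tilted <- outer(seq_len(32), seq_len(32), "+") / 10
  expect_lt(abs(fractalDimension(tilted)[["fractal_dimension"]] - 2), 0.3)
  set.seed(2)
  noise <- matrix(rnorm(1024), 32)
  dn <- fractalDimension(noise)[["fractal_dimension"]]
  expect_gt(dn, 2.2)
  expect_lt(dn, 3.2)
  expect_equal(unname(fractalDimension(matrix(1, 3, 3))), 0)  # < 2 scales
})

test_that("Laws energies vanish on flat fields and fire on stripes", {
  fc <- lawsFeatures(matrix(4, 20, 20))
  expect_lt(max(abs(fc)), 1e-9)
  # period-4 stripes along x (period-2 patterns are orthogonal to E5)
  stripes <- matrix(rep(c(1, 1, -1, -1), length.out = 20), 20, 20,
                    byrow = TRUE)
  fs <- lawsFeatures(stripes)
  expect_gt(fs[["laws_L5E5_mean"]], 1)
  expect_length(fs, 18)
})

test_that("Gabor features are orientation-tuned", {
  bank <- gaborBank()
  expect_length(bank, 6)
  for (k in bank) expect_lt(abs(sum(k)), 1e-10)  # DC-corrected
  fc <- gaborFeatures(matrix(3, 32, 32))
  expect_lt(max(abs(fc)), 1e-8)
  xs <- matrix(rep(0:63, each = 64), 64)
  grating <- cos(2 * pi * xs / 4)          # wavelength 4 along x
  fg <- gaborFeatures(grating)
  expect_equal(names(which.max(fg)), "gabor_theta0")
  ys <- matrix(rep(0:63, 64), 64)
  fg90 <- gaborFeatures(cos(2 * pi * ys / 4))
  expect_equal(names(which.max(fg90)), "gabor_theta90")
  # rotating the grating by 90 degrees permutes the responses
  expect_equal(fg[["gabor_theta0"]], fg90[["gabor_theta90"]],
               tolerance = 1e-9)
  expect_equal(fg[["gabor_theta30"]], fg90[["gabor_theta120"]],
               tolerance = 1e-9)
  expect_equal(fg[["gabor_theta60"]], fg90[["gabor_theta150"]],
               tolerance = 1e-9)
})

test_that("the root filter set has the documented structure", {
  bank <- buildRFSBank()
  expect_length(bank$kernels, 38)
  expect_equal(sum(bank$meta$type == "edge"), 18)
  expect_equal(sum(bank$meta$type == "bar"), 18)
  # all but the Gaussian are zero-mean; all are L1-normalized
  for (nm in names(bank$kernels)) {
    k <- bank$kernels[[nm]]
    expect_lt(abs(sum(abs(k)) - 1), 1e-9)
    if (nm != "gaussian") expect_lt(abs(sum(k)), 1e-9)
  }
  f <- mr8Features(matrix(rnorm(2500), 50), bank)
  expect_length(f, 8)
})

test_that("MR8 responses collapse correctly on constant input", {
  f <- mr8Features(matrix(7, 50, 50))
  expect_equal(unname(f["mr_gaussian"]), 7, tolerance = 1e-9)
  expect_lt(max(abs(f[names(f) != "mr_gaussian"])), 1e-8)
})

test_that("MR8 features are approximately insensitive to 30-degree rotation", {
  # rotating a grating by one orientation step permutes which filters
  # respond, so the max-over-orientation features should agree; the
  # mean-of-max statistic on pixel grids carries discretization error of
  # order 10% for the finest (1-pixel sigma) filters, so the check runs
  # at a 15% relative / 0.03 absolute tolerance
  grate <- function(deg) {
    th <- deg * pi / 180
    xs <- matrix(rep(0:95, each = 96), 96)
    ys <- matrix(rep(0:95, 96), 96)
    cos(2 * pi * (xs * cos(th) + ys * sin(th)) / 16)
  }
  f0 <- mr8Features(grate(10))
  f30 <- mr8Features(grate(40))
  for (nm in names(f0)) {
    # odd (edge) filters at 1-pixel sigma are the most grid-sensitive
    rel <- if (grepl("edge", nm)) 0.35 else 0.15
    tol <- max(rel * abs(f0[[nm]]), 0.03)
    expect_lt(abs(f0[[nm]] - f30[[nm]]), tol)
  }
})

test_that("Fourier band fractions partition the non-DC energy", {
  fc <- fourierFeatures(matrix(5, 16, 16))
  expect_equal(unname(fc), c(0, 0))
  set.seed(9)
  fr <- fourierFeatures(matrix(rnorm(256), 16))
  expect_equal(unname(sum(fr)), 1, tolerance = 1e-12)
  xs <- matrix(rep(0:31, each = 32), 32)
  fg <- fourierFeatures(cos(2 * pi * xs / 4))  # f = 0.25 > Nyquist/4
  expect_gt(fg[["fourier_high_fraction"]], 0.99)
})

test_that("histogram features are invariant to content translation", {
  set.seed(11)
  roi <- matrix(rnorm(1024), 32)
  shifted <- roi[c(17:32, 1:16), c(5:32, 1:4)]  # wrap shift
  a <- firstOrderFeatures(roi)
  b <- firstOrderFeatures(shifted)
  expect_equal(a, b, tolerance = 1e-12)
})
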