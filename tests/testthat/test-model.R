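makeXY <- function(n = 20, p = 8, nDiff = 6, seed = 1, sep = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- factor(rep(c("easy", "difficult"), c(n - nDiff, nDiff)),
              levels = c("easy", "difficult"))
  X[y == "difficult", 1] <- X[y == "difficult", 1] + sep
  list(X = X, y = y)
}

test_that("SMOTE balances classes with convex-hull synthetic rows", {
  d <- makeXY(13, 4, nDiff = 3, seed = 2)
  expect_warning(out <- smoteOversample(d$X, d$y, k = 5, seed = 3),
                 "reduced")
  expect_equal(as.integer(table(out$y)), c(10L, 10L))
  # originals preserved, synthetic rows appended
  expect_equal(out$X[1:13, ], d$X)
  syn <- out$X[14:20, , drop = FALSE]
  minX <- d$X[d$y == "difficult", ]
  for (j in seq_len(ncol(syn))) {
    expect_true(all(syn[, j] >= min(minX[, j]) - 1e-12))
    expect_true(all(syn[, j] <= max(minX[, j]) + 1e-12))
  }
  out2 <- suppressWarnings(smoteOversample(d$X, d$y, k = 5, seed = 3))
  expect_identical(out$X, out2$X)
  # balanced input passes through untouched
  bal <- makeXY(10, 3, nDiff = 5)
  expect_equal(nrow(smoteOversample(bal$X, bal$y, seed = 1)$X), 10)
  # k larger than the minority triggers the reduction warning
  expect_warning(smoteOversample(d$X, d$y, k = 10, seed = 1), "reduced")
})

test_that("the variance filter keeps only high-variance training features", {
  X <- cbind(a = rep(1, 10), b = rnorm(10, sd = 0.5), c = rnorm(10, sd = 3))
  keep <- varianceFilter(X, 1)
  expect_false(1 %in% keep)  # zero variance
  X2 <- cbind(a = seq(0, 0.9, 0.1) * 2, b = seq(0, 9))  # vars ~0.37, ~9.2
  expect_equal(varianceFilter(X2, 1), 2L, ignore_attr = TRUE)
  expect_warning(keepAll <- varianceFilter(X2 * 0.01, 1), "keeping all")
  expect_length(keepAll, 2)
})

test_that("standardization uses training statistics and inverts", {
  set.seed(4)
  tr <- matrix(rnorm(60, 5, 2), 20, 3)
  z <- standardizeFeatures(tr)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  te <- matrix(rnorm(15, 5, 2), 5, 3)
  zt <- standardizeFeatures(tr, te)
  back <- sweep(sweep(zt, 2, attr(zt, "scale"), "*"), 2,
                attr(zt, "center"), "+")
  expect_lt(max(abs(back - te)), 1e-9)
})

test_that("accuracy counts thresholded calls", {
  y <- factor(c("easy", "easy", "difficult", "difficult", "easy",
                "difficult"), levels = c("easy", "difficult"))
  s <- c(0.1, 0.7, 0.9, 0.2, 0.4, 0.6)
  expect_equal(accuracyAtThreshold(y, s), 4 / 6)  # hand count
  expect_equal(accuracyAtThreshold(y, ifelse(y == "difficult", 1, 0)), 1)
  expect_equal(accuracyAtThreshold(y, ifelse(y == "difficult", 0, 1)), 0)
})

test_that("the bootstrap AUC point estimate is the Mann-Whitney statistic", {
  set.seed(6)
  y <- factor(rep(c("easy", "difficult"), c(12, 8)),
              levels = c("easy", "difficult"))
  s <- rnorm(20) + (y == "difficult")
  bs <- bootstrapAucCI(y, s, reps = 500, seed = 2)
  U <- wilcox.test(s[y == "difficult"], s[y == "easy"])$statistic
  expect_equal(bs$auc, unname(U) / (12 * 8))
  if (requireNamespace("pROC", quietly = TRUE)) {
    a <- pROC::auc(pROC::roc(y, s, levels = c("easy", "difficult"),
                             direction = "<", quiet = TRUE))
    expect_equal(bs$auc, as.numeric(a))
  }
  expect_true(bs$low <= bs$auc && bs$auc <= bs$high)
  # perfect separation pins the interval at 1
  sp <- ifelse(y == "difficult", 2, -2) + rnorm(20, 0, 0.01)
  bp <- bootstrapAucCI(y, sp, reps = 200, seed = 3)
  expect_equal(c(bp$auc, bp$low, bp$high), c(1, 1, 1))
})

test_that("bootstrap intervals tighten with sample size", {
  widths <- vapply(c(40, 400), function(n) {
    set.seed(7)
    y <- factor(rep(c("easy", "difficult"), each = n / 2),
                levels = c("easy", "difficult"))
    s <- rnorm(n) + (y == "difficult") * 1
    bs <- bootstrapAucCI(y, s, reps = 500, seed = 5)
    bs$high - bs$low
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("AUC comparison is antisymmetric and detects separation", {
  mk <- function(auc, draws) new("DifficultyModelResult",
    scores = numeric(4), labels = factor(rep(c("easy", "difficult"), 2),
                                         levels = c("easy", "difficult")),
    auc = auc, aucCI = c(auc, auc), accuracy = 0.5,
    bootstrapAucs = draws, foldTrees = integer(0), topFeatures = list(),
    errorType = "FP", view = "CC")
  set.seed(8)
  a <- mk(0.9, rnorm(500, 0.9, 0.005))
  b <- mk(0.5, rnorm(500, 0.5, 0.005))
  cmp <- compareAUCs(a, b)
  expect_lt(cmp$p, 0.001)
  expect_equal(compareAUCs(b, a)$z, -cmp$z)
  same <- compareAUCs(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
})

test_that("nested CV is a leave-one-out over separable data", {
  d <- makeXY(14, 6, nDiff = 5, seed = 9, sep = 6)
  cfg <- difficultyModelConfig(treeGrid = c(50L, 100L), innerRepeats = 1L,
                               bootstrapReps = 100L, seed = 3)
  res <- nestedCV(d$X, d$y, cfg)
  expect_length(oofScores(res), 14)          # one score per sample
  expect_equal(modelAUC(res), 1)
  expect_length(topFeatures(res), 14)
  expect_true(all(res@foldTrees %in% c(50L, 100L)))
  expect_true(all(vapply(topFeatures(res), function(t)
    "f1" %in% t, logical(1))))
})

test_that("training-only transforms ignore poisoned test rows", {
  d <- makeXY(16, 6, nDiff = 6, seed = 10, sep = 2)
  cfg <- difficultyModelConfig(seed = 5)
  trainIdx <- 1:12; testIdx <- 13:16
  Xfull <- d$X
  mdl <- mammoErrors:::fitPipelineModel(Xfull[trainIdx, ], d$y[trainIdx],
                                        100L, cfg, seed = 11)
  ref <- mdl$predict(Xfull[testIdx, , drop = FALSE])
  # poison the held-out rows: every fitted transform must be unchanged
  Xfull[testIdx, ] <- NaN
  poisoned <- mammoErrors:::fitPipelineModel(Xfull[trainIdx, ],
                                             d$y[trainIdx], 100L, cfg,
                                             seed = 11)
  expect_identical(mdl$selected, poisoned$selected)
  expect_identical(mdl$centre, poisoned$centre)
  expect_identical(mdl$scale, poisoned$scale)
  expect_equal(poisoned$predict(d$X[testIdx, , drop = FALSE]), ref)
})
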