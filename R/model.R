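#' @include AllClasses.R utils.R
NULL

#' Construct the difficulty-model configuration
#'
#' @param treeGrid candidate tree counts (default 100, 250, 500, 1000).
#' @param innerFolds,innerRepeats inner stratified CV geometry (3, 3).
#' @param smoteNeighbours SMOTE k (5).
#' @param varianceThreshold raw-variance filter cut (1).
#' @param bootstrapReps stratified bootstrap replicates (2000).
#' @param ciLevel CI level (0.95).
#' @param decisionThreshold accuracy score cut (0.5).
#' @param smoteBeforeStandardize include synthetic rows in the
#'   standardization statistics (TRUE).
#' @param seed master seed.
#' @return a validated [DifficultyModelConfig-class].
#' @export
difficultyModelConfig <- function(treeGrid = c(100L, 250L, 500L, 1000L),
    innerFolds = 3L, innerRepeats = 3L, smoteNeighbours = 5L,
    varianceThreshold = 1, bootstrapReps = 2000L, ciLevel = 0.95,
    decisionThreshold = 0.5, smoteBeforeStandardize = TRUE, seed = 1L) {
  new("DifficultyModelConfig", treeGrid = as.integer(treeGrid),
      innerFolds = as.integer(innerFolds),
      innerRepeats = as.integer(innerRepeats),
      smoteNeighbours = as.integer(smoteNeighbours),
      varianceThreshold = varianceThreshold,
      bootstrapReps = as.integer(bootstrapReps), ciLevel = ciLevel,
      decisionThreshold = decisionThreshold,
      smoteBeforeStandardize = smoteBeforeStandardize,
      seed = as.integer(seed))
}

#' SMOTE minority oversampling
#'
#' Brings the minority class up to the majority count by interpolating
#' synthetic samples between each drawn minority sample and one of its k
#' nearest minority neighbours (uniform interpolation weight).  Originals
#' are preserved; a minority of one falls back to duplication with small
#' Gaussian jitter (warning); k is reduced when the minority has fewer
#' than k + 1 members (warning).
#'
#' @param X numeric matrix (samples in rows).
#' @param y two-level factor.
#' @param k neighbour count (default 5).
#' @param seed integer seed.
#' @return list with balanced `X` and `y`; original rows come first.
#' @export
smoteOversample <- function(X, y, k = 5L, seed = 1L) {
  y <- factor(y)
  tab <- table(y)
  assertThat(length(tab) == 2L, "y must have exactly two classes")
  minClass <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  if (need == 0L) return(list(X = X, y = y))
  minX <- X[y == minClass, , drop = FALSE]
  nMin <- nrow(minX)
  assertThat(nMin >= 1L, "minority class is empty")
  synth <- withSeed(seed, {
    if (nMin == 1L) {
      warning("minority class of size 1; duplicating with jitter")
      jitterSD <- pmax(apply(X, 2, sd) * 0.01, 1e-8)
      t(replicate(need, minX[1, ] + rnorm(ncol(X), 0, jitterSD)))
    } else {
      kk <- min(k, nMin - 1L)
      if (kk < k) warning("SMOTE k reduced to ", kk)
      d <- as.matrix(dist(minX))
      diag(d) <- Inf
      nnRaw <- vapply(seq_len(nMin), function(i)
        order(d[i, ])[seq_len(kk)], integer(kk))
      nn <- matrix(as.integer(nnRaw), nrow = nMin, byrow = TRUE)
      base <- sample(nMin, need, replace = TRUE)
      nbr <- vapply(base, function(b)
        nn[b, sample.int(kk, 1)], integer(1))
      lam <- runif(need)
      minX[base, , drop = FALSE] +
        lam * (minX[nbr, , drop = FALSE] - minX[base, , drop = FALSE])
    }
  })
  list(X = rbind(X, synth),
       y = factor(c(as.character(y), rep(minClass, need)),
                  levels = levels(y)))
}

#' Variance filter
#'
#' Indices of the features whose variance on the training rows exceeds the
#' threshold.  Computed on raw (pre-standardization) values; the same
#' index set must be applied to validation and test rows.  An empty
#' selection falls back to all features with a warning.
#'
#' @param XTrain numeric training matrix.
#' @param threshold variance cut (default 1).
#' @return integer feature indices.
#' @export
varianceFilter <- function(XTrain, threshold = 1) {
  v <- apply(XTrain, 2, var)
  keep <- which(v > threshold)
  if (!length(keep)) {
    warning("variance filter removed every feature; keeping all")
    keep <- seq_len(ncol(XTrain))
  }
  keep
}

#' Feature standardization from training statistics
#'
#' Per-feature (x - train mean)/train SD; zero-SD features map to 0.
#'
#' @param XTrain training matrix supplying the statistics.
#' @param XApply matrix to transform (default the training matrix).
#' @return transformed matrix with attributes `center` and `scale`.
#' @export
standardizeFeatures <- function(XTrain, XApply = XTrain) {
  mu <- colMeans(XTrain)
  sdv <- apply(XTrain, 2, sd)
  out <- sweep(XApply, 2, mu, "-")
  out <- sweep(out, 2, ifelse(sdv > 0, sdv, 1), "/")
  out[, sdv == 0] <- 0
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

# Rank (Mann-Whitney) AUC of scores for binary labels; positive = second
# factor level.  Ties handled through midranks.
rankAUC <- function(labels, scores) {
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment preserving class proportions.
stratifiedFolds <- function(y, k, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Fit the training-only preprocessing (SMOTE -> variance filter ->
# standardization) and a ranger forest; returns a predictor closure.
# Everything is derived exclusively from (XTrain, yTrain).
fitPipelineModel <- function(XTrain, yTrain, numTrees, config, seed) {
  sm <- suppressWarnings(
    smoteOversample(XTrain, yTrain, config@smoteNeighbours,
                    childSeed(seed, 1L)))
  keep <- suppressWarnings(
    varianceFilter(sm$X, config@varianceThreshold))
  statsSource <- if (config@smoteBeforeStandardize) sm$X else XTrain
  Z <- standardizeFeatures(statsSource[, keep, drop = FALSE],
                           sm$X[, keep, drop = FALSE])
  centre <- attr(Z, "center"); scale <- attr(Z, "scale")
  fit <- ranger::ranger(x = Z, y = sm$y, num.trees = numTrees,
                        mtry = max(1L, floor(sqrt(ncol(Z)))),
                        probability = TRUE, min.node.size = 1L,
                        importance = "impurity", num.threads = 1L,
                        seed = childSeed(seed, 2L))
  posLevel <- levels(yTrain)[2]
  predictFun <- function(Xnew) {
    Zn <- sweep(Xnew[, keep, drop = FALSE], 2, centre, "-")
    Zn <- sweep(Zn, 2, ifelse(scale > 0, scale, 1), "/")
    Zn[, scale == 0] <- 0
    stats::predict(fit, data = Zn, num.threads = 1L)$predictions[, posLevel]
  }
  list(predict = predictFun, selected = keep, centre = centre,
       scale = scale, importance = ranger::importance(fit))
}

# Inner loop: repeated stratified k-fold mean AUC per tree-grid value;
# returns the grid value with the best mean AUC (ties -> fewer trees).
chooseTreeCount <- function(XTrain, yTrain, config, seed) {
  grid <- sort(config@treeGrid)
  aucs <- matrix(NA_real_, length(grid),
                 config@innerFolds * config@innerRepeats)
  col <- 0L
  for (rep in seq_len(config@innerRepeats)) {
    fold <- stratifiedFolds(yTrain, config@innerFolds,
                            childSeed(seed, 100L + rep))
    for (f in seq_len(config@innerFolds)) {
      col <- col + 1L
      tr <- fold != f
      if (length(unique(yTrain[tr])) < 2L ||
          length(unique(yTrain[!tr])) < 2L) next
      for (gi in seq_along(grid)) {
        mdl <- fitPipelineModel(XTrain[tr, , drop = FALSE],
                                droplevels(yTrain[tr]), grid[gi], config,
                                childSeed(seed, 1000L * rep + 10L * f + gi))
        aucs[gi, col] <- rankAUC(yTrain[!tr],
                                 mdl$predict(XTrain[!tr, , drop = FALSE]))
      }
    }
  }
  means <- rowMeans(aucs, na.rm = TRUE)
  means[is.nan(means)] <- -Inf
  grid[which.max(means)]
}

#' Nested cross-validated difficulty model
#'
#' Outer loop: leave-one-out.  Inner loop (per outer iteration): repeated
#' stratified 3-fold CV in which each training fold is SMOTE-balanced,
#' variance-filtered (raw variance > 1) and standardized before fitting a
#' probability random forest (sqrt(p) features per split) at each
#' tree-grid value; the tree count with the best mean inner AUC wins.  The
#' outer training set is then refit with the winning count (same
#' training-only preprocessing) and scores the held-out sample.
#' Out-of-fold scores are aggregated into the AUC (with a stratified
#' bootstrap CI) and accuracy; each outer fold also records its chosen
#' tree count and top-10 features by impurity importance.
#'
#' @param X numeric matrix, areas in rows, features in columns.
#' @param y factor with levels c("easy", "difficult") ("difficult" is the
#'   positive, minority class).
#' @param config a [DifficultyModelConfig-class].
#' @param errorType,view provenance tags stored in the result.
#' @return a [DifficultyModelResult-class].
#' @export
nestedCV <- function(X, y, config = difficultyModelConfig(),
                     errorType = "FP", view = "") {
  y <- factor(y, levels = c("easy", "difficult"))
  assertThat(all(table(y) >= 2L), "each class needs at least 2 samples")
  n <- nrow(X)
  scores <- numeric(n)
  foldTrees <- integer(n)
  tops <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    seed_i <- childSeed(config@seed, i)
    best <- chooseTreeCount(X[tr, , drop = FALSE], y[tr], config, seed_i)
    mdl <- fitPipelineModel(X[tr, , drop = FALSE], y[tr], best, config,
                            childSeed(seed_i, 7L))
    scores[i] <- mdl$predict(X[i, , drop = FALSE])
    foldTrees[i] <- best
    imp <- sort(mdl$importance, decreasing = TRUE)
    tops[[i]] <- names(imp)[seq_len(min(10L, length(imp)))]
  }
  bs <- bootstrapAucCI(y, scores, config@bootstrapReps,
                       childSeed(config@seed, 5555L), config@ciLevel)
  new("DifficultyModelResult", scores = scores, labels = y,
      auc = bs$auc, aucCI = c(bs$low, bs$high), accuracy =
        accuracyAtThreshold(y, scores, config@decisionThreshold),
      bootstrapAucs = bs$draws, foldTrees = foldTrees, topFeatures = tops,
      errorType = errorType, view = view)
}

#' Stratified bootstrap AUC confidence interval
#'
#' The point estimate is the rank (Mann-Whitney) AUC of the scores; the
#' interval is the percentile interval of the AUC over stratified
#' bootstrap resamples (cases redrawn within each class; degenerate
#' resamples redrawn).
#'
#' @param y two-level factor (second level positive).
#' @param scores numeric scores.
#' @param reps bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `low`, `high` and the bootstrap `draws`.
#' @export
bootstrapAucCI <- function(y, scores, reps = 2000L, seed = 1L,
                           level = 0.95) {
  y <- factor(y)
  auc <- rankAUC(y, scores)
  idxPos <- which(y == levels(y)[2]); idxNeg <- which(y == levels(y)[1])
  draws <- withSeed(seed, vapply(seq_len(reps), function(b) {
    repeat {
      take <- c(sample(idxNeg, length(idxNeg), replace = TRUE),
                sample(idxPos, length(idxPos), replace = TRUE))
      a <- rankAUC(y[take], scores[take])
      if (!is.na(a)) return(a)
    }
  }, numeric(1)))
  alpha <- (1 - level) / 2
  qs <- quantile(draws, c(alpha, 1 - alpha), names = FALSE)
  list(auc = auc, low = qs[1], high = qs[2], draws = draws)
}

#' Compare two model AUCs
#'
#' Normal z-test on the AUC difference with standard errors taken from the
#' bootstrap distributions: z = (AUC_a - AUC_b)/sqrt(SE_a^2 + SE_b^2),
#' two-tailed p.  Swapping the arguments negates z.
#'
#' @param resultA,resultB [DifficultyModelResult-class] objects carrying
#'   bootstrap draws.
#' @return list with `z` and `p`.
#' @export
compareAUCs <- function(resultA, resultB) {
  assertThat(length(resultA@bootstrapAucs) > 1 &&
               length(resultB@bootstrapAucs) > 1,
             "both results need bootstrap distributions")
  seA <- sd(resultA@bootstrapAucs); seB <- sd(resultB@bootstrapAucs)
  denom <- sqrt(seA^2 + seB^2)
  z <- if (denom > 0) (resultA@auc - resultB@auc) / denom else 0
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Accuracy at a score threshold
#'
#' Fraction of areas whose thresholded score (score >= t predicts
#' "difficult") matches the label.
#'
#' @param y factor with levels c("easy", "difficult").
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return numeric accuracy in [0, 1].
#' @export
accuracyAtThreshold <- function(y, scores, threshold = 0.5) {
  y <- factor(y, levels = c("easy", "difficult"))
  pred <- ifelse(scores >= threshold, "difficult", "easy")
  mean(pred == as.character(y))
}
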