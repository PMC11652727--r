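#' @include AllClasses.R utils.R
NULL

#' Aggregate per-fold feature rankings into the top five
#'
#' Counts how often each feature appears in the per-fold top-10 lists and
#' returns the five most frequent.  Ties break by the mean within-fold
#' rank (absent folds count as rank 11), then by name.
#'
#' @param perFoldRankings list of character vectors (each at most 10
#'   names, best first), e.g. [topFeatures()] of a model result.
#' @param nTop number of features to return (default 5).
#' @return data.frame (feature, frequency, mean_rank), best first.
#' @export
aggregateTopFeatures <- function(perFoldRankings, nTop = 5L) {
  assertThat(all(lengths(perFoldRankings) <= 10L),
             "each fold contributes at most 10 names")
  allNames <- unique(unlist(perFoldRankings))
  if (!length(allNames))
    return(data.frame(feature = character(0), frequency = integer(0),
                      mean_rank = numeric(0)))
  freq <- vapply(allNames, function(f)
    sum(vapply(perFoldRankings, function(r) f %in% r, logical(1))),
    integer(1))
  meanRank <- vapply(allNames, function(f) {
    mean(vapply(perFoldRankings, function(r) {
      p <- match(f, r)
      if (is.na(p)) 11 else p
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-freq, meanRank, allNames)
  out <- data.frame(feature = allNames, frequency = freq,
                    mean_rank = meanRank,
                    row.names = NULL)[ord, , drop = FALSE]
  if (nrow(out) < nTop)
    warning("fewer than ", nTop, " distinct features available")
  head(out, nTop)
}

#' Mann-Whitney U test between easy and difficult values
#'
#' Rank-sum U with midrank tie handling; the p-value is exact when the
#' combined sample size is at most 20 and there are no ties, and uses the
#' tie-corrected normal approximation otherwise.  Two-tailed.
#'
#' @param easyValues,difficultValues numeric vectors (both non-empty).
#' @return list with `U` (for the easy sample) and `p`.
#' @examples
#' mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyTest <- function(easyValues, difficultValues) {
  assertThat(length(easyValues) > 0 && length(difficultValues) > 0,
             "both groups must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(easyValues, difficultValues,
                exact = (length(easyValues) + length(difficultValues)) <= 20,
                correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` with family size m (defaults to the number of
#' p-values); the significance flag uses a strict `< fwer` comparison.
#'
#' @param pValues numeric raw p-values.
#' @param m family size (default `length(pValues)`).
#' @param fwer family-wise error rate (0.05).
#' @return data.frame (p_raw, p_adjusted, significant).
#' @export
bonferroniAdjust <- function(pValues, m = length(pValues), fwer = 0.05) {
  adj <- pmin(1, pValues * m)
  data.frame(p_raw = pValues, p_adjusted = adj, significant = adj < fwer)
}

#' Median and interquartile range
#'
#' Linear-interpolation (type 7) quantiles, matching how the feature
#' tables report distributions.
#'
#' @param values numeric vector.
#' @return named numeric c(median, q25, q75).
#' @export
summarizeDistribution <- function(values) {
  q <- quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Compare the discriminative features between difficulty groups
#'
#' Takes a fitted model's per-fold top-10 rankings, keeps the five most
#' frequent features, and contrasts their raw (unstandardized) values
#' between easy and difficult areas with two-tailed Mann-Whitney U tests,
#' Bonferroni-corrected over the five-feature family.
#'
#' @param result a [DifficultyModelResult-class].
#' @param featureSet the [RadiomicFeatureSet-class] the model was fit on.
#' @param fwer family-wise error rate (0.05).
#' @return data.frame: feature, frequency, easy/difficult median and IQR
#'   bounds, U, raw and adjusted p, significance flag.
#' @export
compareDiscriminativeFeatures <- function(result, featureSet, fwer = 0.05) {
  top <- aggregateTopFeatures(topFeatures(result))
  fm <- SummarizedExperiment::assay(featureSet, "features")
  lab <- result@labels
  rows <- lapply(seq_len(nrow(top)), function(i) {
    f <- top$feature[i]
    easy <- fm[f, lab == "easy"]
    hard <- fm[f, lab == "difficult"]
    mw <- mannWhitneyTest(easy, hard)
    se <- summarizeDistribution(easy); sh <- summarizeDistribution(hard)
    data.frame(feature = f, frequency = top$frequency[i],
               easy_median = se["median"], easy_q25 = se["q25"],
               easy_q75 = se["q75"], difficult_median = sh["median"],
               difficult_q25 = sh["q25"], difficult_q75 = sh["q75"],
               U = mw$U, p_raw = mw$p, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  adj <- bonferroniAdjust(out$p_raw, m = nrow(out), fwer = fwer)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  out
}
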