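#' @include AllClasses.R utils.R
NULL

#' Hierarchically cluster readers by error agreement
#'
#' Euclidean distances between the readers' binary false-response profiles,
#' merged with Ward's minimum-variance linkage (\code{hclust} method
#' \code{"ward.D2"}, the Ward implementation defined on Euclidean
#' distances).  Merge heights are monotone non-decreasing.
#'
#' @param responses a [ResponseMatrix-class] with at least two readers.
#' @return a [ReaderDendrogram-class].
#' @export
clusterReaders <- function(responses) {
  m <- responseValues(responses)
  assertThat(nrow(m) >= 2L, "at least two readers are required")
  hc <- hclust(dist(m, method = "euclidean"), method = "ward.D2")
  new("ReaderDendrogram", tree = hc, errorType = responses@errorType)
}

# Leaf sets and top internal heights for every internal node of an hclust.
hclustNodes <- function(hc) {
  n <- length(hc$order)
  leaves <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0) -k else leaves[[k]]
    leaves[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  leaves
}

#' Identify outlier readers from the dendrogram
#'
#' Iteratively peels the outer branch of the tree: at the current root, the
#' smaller child branch is the outlier candidate, accepted while the gap
#' between the root merge height and the top height of the remaining branch
#' exceeds `gapFactor` times the interquartile range of all merge heights,
#' and while the running total stays within `maxOutliers`.  Cohorts whose
#' merge heights are homogeneous (IQR ~ 0, e.g. identical readers) yield no
#' outliers.  The result is empty whenever no branch is height-separated.
#'
#' @param dendrogram a [ReaderDendrogram-class].
#' @param maxOutliers cap on the number of peeled readers (default a
#'   quarter of the roster).
#' @param gapFactor gap multiplier on the height IQR (default 1.0).
#' @return character vector of outlier reader ids (possibly empty).
#' @export
identifyOutliers <- function(dendrogram,
                             maxOutliers = floor(length(dendrogram@tree$order) / 4),
                             gapFactor = 1.0) {
  hc <- dendrogram@tree
  n <- length(hc$order)
  if (maxOutliers <= 0) return(character(0))
  scale <- stats::IQR(hc$height)
  if (scale <= .Machine$double.eps) return(character(0))
  leaves <- hclustNodes(hc)
  getLeaves <- function(k) if (k < 0) -k else leaves[[k]]
  getHeight <- function(k) if (k < 0) 0 else hc$height[k]
  peeled <- integer(0)
  node <- n - 1L
  repeat {
    a <- hc$merge[node, 1]; b <- hc$merge[node, 2]
    la <- getLeaves(a); lb <- getLeaves(b)
    if (length(la) < length(lb) ||
        (length(la) == length(lb) && getHeight(a) <= getHeight(b))) {
      outer <- la; keep <- b
    } else {
      outer <- lb; keep <- a
    }
    gap <- hc$height[node] - getHeight(keep)
    if (length(peeled) + length(outer) <= maxOutliers &&
        gap > gapFactor * scale) {
      peeled <- c(peeled, outer)
      if (keep < 0) break
      node <- keep
    } else break
  }
  sort(hc$labels[peeled])
}

#' Exclude outlier readers from the false-positive pipeline
#'
#' Removes the outliers' annotations, drops normal areas whose every
#' positive member mark came from outliers (areas marked solely by the
#' excluded readers), keeps all cancer areas, and rebuilds the
#' false-positive response matrix on the remaining roster.
#'
#' @param annotations full annotation data.frame.
#' @param areaSet a [SuspiciousAreaSet-class].
#' @param readers the full roster (character).
#' @param outliers outlier reader ids (subset of `readers`).
#' @return list with `annotations`, `areaSet`, `readers` (remaining roster)
#'   and `responses` (rebuilt FP [ResponseMatrix-class]).
#' @export
excludeOutliers <- function(annotations, areaSet, readers, outliers) {
  assertThat(all(outliers %in% readers), "outliers must be a subset of the roster")
  remaining <- setdiff(readers, outliers)
  assertThat(length(remaining) > 0L, "cannot exclude every reader")
  keepAnn <- annotations[!annotations$reader_id %in% outliers, , drop = FALSE]
  mem <- areaSet@members
  cutoff <- areaSet@thresholds$positiveRatingCutoff
  posMem <- mem[mem$rating >= cutoff, , drop = FALSE]
  dropIds <- character(0)
  normals <- areaSet@areas$area_id[areaSet@areas$kind == "normal"]
  for (aid in normals) {
    who <- unique(posMem$reader_id[posMem$area_id == aid])
    if (length(who) && all(who %in% outliers)) dropIds <- c(dropIds, aid)
  }
  areaSet@areas <- areaSet@areas[!areaSet@areas$area_id %in% dropIds, ,
                                 drop = FALSE]
  areaSet@members <- mem[!mem$area_id %in% dropIds &
                           !mem$reader_id %in% outliers, , drop = FALSE]
  responses <- buildResponseMatrix(areaSet, remaining, keepAnn, "FP")
  list(annotations = keepAnn, areaSet = areaSet, readers = remaining,
       responses = responses)
}

#' Per-reader false-response report
#'
#' One row per reader with their total false-response count, the cohort
#' median, and whether the reader was flagged as an outlier.
#'
#' @param responses a [ResponseMatrix-class].
#' @param outliers character vector of outlier ids.
#' @return data.frame (reader_id, false_count, cohort_median, is_outlier).
#' @export
outlierReport <- function(responses, outliers = character(0)) {
  counts <- rowSums(responseValues(responses))
  data.frame(reader_id = names(counts), false_count = as.numeric(counts),
             cohort_median = median(counts),
             is_outlier = names(counts) %in% outliers,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a reader dendrogram as Newick text
#'
#' @param dendrogram a [ReaderDendrogram-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeDendrogramNewick <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram@tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
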