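#' @import methods
#' @importFrom stats median quantile sd var rnorm runif rbinom dist hclust
#'   cutree fft wilcox.test p.adjust pnorm setNames aggregate
#' @importFrom utils head write.csv read.csv
NULL

#' Configuration of the synthetic reading-study generator
#'
#' Holds every knob of the synthetic cohort: how many normal and cancer cases
#' to emit, the image geometry, the reader roster (including planted outlier
#' readers), the per-reader false-positive response model, and the oriented
#' texture offset that separates difficult from easy planted areas.
#'
#' The response model is Bernoulli per reader and planted area:
#' \code{P(false positive) = baseFPRate * fpDifficultyMultiplier^(difficult) *
#' outlierFPMultiplier^(outlier)}, capped at 0.95.  Cancer lesions are hit
#' with probability \code{hitRateEasy} or \code{hitRateDifficult}; a miss may
#' still emit a negative (rating < 3) mark with probability
#' \code{negativeMarkRate}.
#'
#' @slot nNormalCases,nCancerCases number of normal / biopsy-proven cancer
#'   cases (defaults 40 and 20, the sampling design of a dense-mammogram
#'   test set).
#' @slot imageSize integer c(rows, cols) of each synthetic view.
#' @slot pixelSpacing mm per pixel.
#' @slot nReaders,nOutlierReaders cohort size and number of planted
#'   high-false-positive readers.
#' @slot baseFPRate probability that a non-outlier reader falsely marks an
#'   easy normal area.
#' @slot outlierFPMultiplier rate multiplier (> 1) for outlier readers.
#' @slot fpDifficultyMultiplier rate multiplier for difficult normal areas.
#' @slot difficultyEffect oriented texture energy injected into difficult
#'   planted areas (0 switches the image-level difficulty signal off).
#' @slot hitRateEasy,hitRateDifficult per-reader probability of correctly
#'   marking an easy / difficult cancer lesion.
#' @slot negativeMarkRate probability that a non-marking reader still leaves
#'   a rating < 3 mark on an area.
#' @slot soloFPPerOutlier idiosyncratic false-positive marks each outlier
#'   reader scatters at locations no other reader marks (these spawn the
#'   solo areas that outlier exclusion removes).
#' @slot annotationJitterSD SD (pixels) of the Gaussian jitter applied to
#'   mark coordinates around the area centre.
#' @slot areasPerView planted suspicious normal areas per view.
#' @slot difficultFraction fraction of planted normal areas that are
#'   difficult.
#' @slot lesionRadiusMM lesion radius written into the truth table.
#' @slot seed master random seed.
#'
#' @seealso [syntheticCohortConfig()] for the user constructor.
#' @export
setClass("SyntheticCohortConfig",
  representation(
    nNormalCases = "integer", nCancerCases = "integer",
    imageSize = "integer", pixelSpacing = "numeric",
    nReaders = "integer", nOutlierReaders = "integer",
    baseFPRate = "numeric", outlierFPMultiplier = "numeric",
    fpDifficultyMultiplier = "numeric", difficultyEffect = "numeric",
    hitRateEasy = "numeric", hitRateDifficult = "numeric",
    negativeMarkRate = "numeric", soloFPPerOutlier = "integer",
    annotationJitterSD = "numeric",
    areasPerView = "integer", difficultFraction = "numeric",
    lesionRadiusMM = "numeric", seed = "integer"
  )
)

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character(0)
  if (object@nOutlierReaders >= object@nReaders)
    msg <- c(msg, "nOutlierReaders must be < nReaders")
  if (any(object@imageSize < 64L))
    msg <- c(msg, "imageSize must be at least 64 x 64")
  probs <- c(object@baseFPRate, object@hitRateEasy, object@hitRateDifficult,
             object@negativeMarkRate, object@difficultFraction)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@outlierFPMultiplier <= 1)
    msg <- c(msg, "outlierFPMultiplier must exceed 1")
  if (object@difficultyEffect < 0)
    msg <- c(msg, "difficultyEffect must be >= 0")
  if (object@soloFPPerOutlier < 0L)
    msg <- c(msg, "soloFPPerOutlier must be >= 0")
  if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic case set: images, lesion truths and planted-area truths
#'
#' Container returned by [generateCaseSet()].  Images are real-valued
#' matrices keyed \code{"<case>_<view>"}; lesion truths and planted-area
#' truths are plain data frames with 0-based pixel coordinates.
#'
#' @slot images named list of numeric matrices.
#' @slot pixelSpacing mm per pixel shared by all images.
#' @slot cases data.frame: case_id, status ("normal"/"cancer").
#' @slot lesions data.frame of lesion truths (lesion_id, case_id, view, side,
#'   x_px, y_px, radius_mm, subtype).
#' @slot plantedAreas data.frame of planted suspicious areas (area_uid,
#'   case_id, view, side, x_px, y_px, kind, hardness, oriented_energy,
#'   orientation_deg, patch_size).
#' @slot config the generating [SyntheticCohortConfig-class].
#' @export
setClass("MammoCaseSet",
  representation(
    images = "list", pixelSpacing = "numeric", cases = "data.frame",
    lesions = "data.frame", plantedAreas = "data.frame",
    config = "SyntheticCohortConfig"
  )
)

setValidity("MammoCaseSet", function(object) {
  cancer <- object@cases$case_id[object@cases$status == "cancer"]
  if (!all(cancer %in% object@lesions$case_id))
    return("every cancer case must carry at least one lesion truth")
  TRUE
})

#' Suspicious areas induced by pooled positive annotations
#'
#' One row of \code{areas} per suspicious area: clustered positive marks on a
#' normal region (kind "normal") or a lesion-anchored cancer region (kind
#' "cancer"), with an inclusive 0-based bounding box, the matched lesion (if
#' any) and, once assigned, the easy/difficult label.  \code{members} holds
#' the positive annotations assigned to each area.
#'
#' @slot areas data.frame: area_id, case_id, view, side, kind, x_min, y_min,
#'   x_max, y_max, lesion_id, n_members, difficulty.
#' @slot members data.frame of member annotations plus their area_id.
#' @slot imageSize integer c(rows, cols) used for bounding-box clipping.
#' @slot thresholds the [pipelineThresholds()] list used to build the set.
#' @export
setClass("SuspiciousAreaSet",
  representation(areas = "data.frame", members = "data.frame",
                 imageSize = "integer", thresholds = "list")
)

#' Readers-by-areas binary error matrix
#'
#' Entry (reader, area) is 1 for a false response: a positive mark inside a
#' normal area (false positive) or the absence of a positive mark inside a
#' cancer area (false negative).
#'
#' @slot values binary matrix, readers in rows, areas in columns.
#' @slot errorType "FP" (normal areas) or "FN" (cancer areas).
#' @export
setClass("ResponseMatrix",
  representation(values = "matrix", errorType = "character")
)

setValidity("ResponseMatrix", function(object) {
  v <- object@values
  if (!all(v %in% c(0, 1))) return("values must be binary")
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    return("values must carry reader row names and area column names")
  if (!object@errorType %in% c("FP", "FN"))
    return("errorType must be 'FP' or 'FN'")
  TRUE
})

#' Ward dendrogram over readers
#'
#' Wraps the \code{\link[stats]{hclust}} tree built from the Euclidean
#' distances between reader error profiles with Ward linkage, together with
#' the error type it describes.
#'
#' @slot tree an \code{hclust} object with reader labels.
#' @slot errorType "FP" or "FN".
#' @export
setClass("ReaderDendrogram",
  representation(tree = "ANY", errorType = "character")
)

setValidity("ReaderDendrogram", function(object) {
  if (!inherits(object@tree, "hclust")) return("tree must be an hclust")
  h <- object@tree$height
  if (is.unsorted(h, strictly = FALSE) && any(diff(h) < -1e-8))
    return("merge heights must be non-decreasing")
  TRUE
})

#' Radiomic feature container
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"features"}
#' (201 radiomic features in rows, suspicious areas in columns), the feature
#' family in \code{rowData} and the area metadata (kind, view, difficulty,
#' false-response count) in \code{colData}.
#'
#' @export
#' @import SummarizedExperiment
setClass("RadiomicFeatureSet", contains = "SummarizedExperiment")

setValidity("RadiomicFeatureSet", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  if (!"family" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must contain a 'family' column")
  TRUE
})

#' Nested cross-validation configuration for the difficulty model
#'
#' Constants of the random-forest difficulty model: leave-one-out outer loop,
#' repeated stratified 3-fold inner loop, SMOTE oversampling of the minority
#' (difficult) class, a raw-variance > 1 feature filter, per-feature
#' standardization, a tree-count grid and a stratified bootstrap for the AUC
#' confidence interval.
#'
#' @slot treeGrid candidate numbers of trees (default 100, 250, 500, 1000).
#' @slot innerFolds,innerRepeats stratified inner CV geometry (3 x 3).
#' @slot smoteNeighbours k for SMOTE (default 5).
#' @slot varianceThreshold keep features with training variance above this
#'   (default 1, computed on pre-standardization values).
#' @slot bootstrapReps stratified bootstrap replicates for the AUC CI
#'   (default 2000).
#' @slot ciLevel confidence level (default 0.95).
#' @slot decisionThreshold score cut for accuracy (default 0.5).
#' @slot smoteBeforeStandardize logical; include SMOTE synthetic rows when
#'   computing standardization statistics (default TRUE).
#' @slot seed master seed fanned out per outer fold.
#' @export
setClass("DifficultyModelConfig",
  representation(
    treeGrid = "integer", innerFolds = "integer", innerRepeats = "integer",
    smoteNeighbours = "integer", varianceThreshold = "numeric",
    bootstrapReps = "integer", ciLevel = "numeric",
    decisionThreshold = "numeric", smoteBeforeStandardize = "logical",
    seed = "integer"
  )
)

setValidity("DifficultyModelConfig", function(object) {
  msg <- character(0)
  if (!length(object@treeGrid)) msg <- c(msg, "treeGrid must be non-empty")
  if (object@innerFolds < 2L) msg <- c(msg, "innerFolds must be >= 2")
  if (object@bootstrapReps < 1L) msg <- c(msg, "bootstrapReps must be >= 1")
  if (object@ciLevel <= 0 || object@ciLevel >= 1)
    msg <- c(msg, "ciLevel must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Result of one nested-CV difficulty model
#'
#' Out-of-fold scores with the aggregated AUC, its stratified-bootstrap
#' confidence interval, accuracy at the decision threshold, and the per-fold
#' chosen tree counts and top-10 features.
#'
#' @slot scores out-of-fold difficulty scores, one per area.
#' @slot labels factor with levels easy/difficult, one per area.
#' @slot auc out-of-fold area under the ROC curve.
#' @slot aucCI length-2 percentile bootstrap interval.
#' @slot accuracy accuracy at the decision threshold.
#' @slot bootstrapAucs the bootstrap AUC draws (for model comparison).
#' @slot foldTrees chosen tree count per outer fold.
#' @slot topFeatures list of per-fold top-10 feature names.
#' @slot errorType,view provenance tags ("FP"/"FN", "CC"/"MLO"/"").
#' @export
setClass("DifficultyModelResult",
  representation(
    scores = "numeric", labels = "factor", auc = "numeric",
    aucCI = "numeric", accuracy = "numeric", bootstrapAucs = "numeric",
    foldTrees = "integer", topFeatures = "list",
    errorType = "character", view = "character"
  )
)

setValidity("DifficultyModelResult", function(object) {
  if (length(object@scores) != length(object@labels))
    return("one score per labelled area is required")
  if (length(object@auc) == 1 && (object@auc < 0 || object@auc > 1))
    return("auc must lie in [0, 1]")
  TRUE
})
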