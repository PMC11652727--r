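#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname readerIds
#' @export
setMethod("readerIds", "ResponseMatrix", function(x) rownames(x@values))

#' @rdname readerIds
#' @export
setMethod("readerIds", "ReaderDendrogram", function(x) x@tree$labels)

#' @rdname areaIds
#' @export
setMethod("areaIds", "ResponseMatrix", function(x) colnames(x@values))

#' @rdname areaIds
#' @export
setMethod("areaIds", "SuspiciousAreaSet", function(x) x@areas$area_id)

#' @rdname responseValues
#' @export
setMethod("responseValues", "ResponseMatrix", function(x) x@values)

#' @rdname areaInfo
#' @export
setMethod("areaInfo", "SuspiciousAreaSet", function(x) x@areas)

#' @rdname areaMembers
#' @export
setMethod("areaMembers", "SuspiciousAreaSet", function(x) x@members)

#' @rdname modelAUC
#' @export
setMethod("modelAUC", "DifficultyModelResult", function(x) x@auc)

#' @rdname modelAUCCI
#' @export
setMethod("modelAUCCI", "DifficultyModelResult", function(x) x@aucCI)

#' @rdname oofScores
#' @export
setMethod("oofScores", "DifficultyModelResult", function(x) x@scores)

#' @rdname topFeatures
#' @export
setMethod("topFeatures", "DifficultyModelResult", function(x) x@topFeatures)

setMethod("show", "SyntheticCohortConfig", function(object) {
  cat("SyntheticCohortConfig:", object@nNormalCases, "normal +",
      object@nCancerCases, "cancer cases;",
      object@nReaders, "readers (", object@nOutlierReaders, "outliers );",
      "difficultyEffect =", object@difficultyEffect, "\n")
})

setMethod("show", "MammoCaseSet", function(object) {
  cat("MammoCaseSet:", nrow(object@cases), "cases,",
      length(object@images), "view images (",
      paste(dim(object@images[[1]]), collapse = " x "), "px at",
      object@pixelSpacing, "mm ),", nrow(object@lesions), "lesions,",
      nrow(object@plantedAreas), "planted areas\n")
})

setMethod("show", "SuspiciousAreaSet", function(object) {
  tab <- table(object@areas$kind)
  cat("SuspiciousAreaSet:", nrow(object@areas), "areas (",
      paste(names(tab), tab, collapse = ", "), ");",
      nrow(object@members), "member annotations\n")
})

setMethod("show", "ResponseMatrix", function(object) {
  cat("ResponseMatrix [", object@errorType, "]:",
      nrow(object@values), "readers x", ncol(object@values), "areas;",
      "false responses:", sum(object@values), "\n")
})

setMethod("show", "ReaderDendrogram", function(object) {
  cat("ReaderDendrogram [", object@errorType, "]:",
      length(object@tree$labels), "readers; top merge height",
      round(max(object@tree$height), 3), "\n")
})

setMethod("show", "DifficultyModelResult", function(object) {
  cat("DifficultyModelResult [", object@errorType,
      if (nzchar(object@view)) paste0("/ ", object@view), "]: AUC",
      sprintf("%.3f (%.3f-%.3f)", object@auc, object@aucCI[1],
              object@aucCI[2]),
      "accuracy", sprintf("%.3f", object@accuracy), "on",
      length(object@scores), "areas\n")
})
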