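#' @include AllClasses.R
NULL

#' Reader identifiers of an object
#' @param x a [ResponseMatrix-class] or [ReaderDendrogram-class].
#' @return character vector of reader ids.
#' @export
setGeneric("readerIds", function(x) standardGeneric("readerIds"))

#' Area identifiers of an object
#' @param x a [ResponseMatrix-class] or [SuspiciousAreaSet-class].
#' @return character vector of area ids.
#' @export
setGeneric("areaIds", function(x) standardGeneric("areaIds"))

#' Binary false-response values
#' @param x a [ResponseMatrix-class].
#' @return the readers-by-areas 0/1 matrix.
#' @export
setGeneric("responseValues", function(x) standardGeneric("responseValues"))

#' Area table of a suspicious-area set
#' @param x a [SuspiciousAreaSet-class].
#' @return data.frame with one row per area.
#' @export
setGeneric("areaInfo", function(x) standardGeneric("areaInfo"))

#' Member annotations of a suspicious-area set
#' @param x a [SuspiciousAreaSet-class].
#' @return data.frame of member annotations with their area_id.
#' @export
setGeneric("areaMembers", function(x) standardGeneric("areaMembers"))

#' Out-of-fold AUC of a fitted difficulty model
#' @param x a [DifficultyModelResult-class].
#' @return numeric AUC.
#' @export
setGeneric("modelAUC", function(x) standardGeneric("modelAUC"))

#' Bootstrap confidence interval of the model AUC
#' @param x a [DifficultyModelResult-class].
#' @return numeric length-2 (lower, upper).
#' @export
setGeneric("modelAUCCI", function(x) standardGeneric("modelAUCCI"))

#' Out-of-fold difficulty scores
#' @param x a [DifficultyModelResult-class].
#' @return numeric vector of scores.
#' @export
setGeneric("oofScores", function(x) standardGeneric("oofScores"))

#' Per-fold top-ranked features
#' @param x a [DifficultyModelResult-class].
#' @return list of character vectors, one per outer fold.
#' @export
setGeneric("topFeatures", function(x) standardGeneric("topFeatures"))
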