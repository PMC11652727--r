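#' @include AllClasses.R annotations.R readers.R radiomics.R model.R stats.R
NULL

# Subset a SuspiciousAreaSet by kind and/or view.
filterAreas <- function(areaSet, kind = NULL, view = NULL) {
  keep <- rep(TRUE, nrow(areaSet@areas))
  if (!is.null(kind)) keep <- keep & areaSet@areas$kind %in% kind
  if (!is.null(view)) keep <- keep & areaSet@areas$view %in% view
  ids <- areaSet@areas$area_id[keep]
  areaSet@areas <- areaSet@areas[keep, , drop = FALSE]
  areaSet@members <- areaSet@members[areaSet@members$area_id %in% ids, ,
                                     drop = FALSE]
  areaSet
}

#' Run the full cohort error analysis
#'
#' End-to-end study replica on one reader cohort: pool positive
#' annotations, build suspicious areas, construct the false-positive
#' response matrix, cluster readers (Ward/Euclidean) and exclude
#' outer-branch outliers together with their solo areas (false-positive
#' pipeline only; the false-negative analysis keeps every reader), label
#' areas easy/difficult by the median split, extract 201 radiomic features
#' per area, fit the nested-CV random-forest difficulty model per error
#' type and view, and test the discriminative power of the top-5 features.
#'
#' @param annotations annotation data.frame (reader_id, case_id, view,
#'   side, x_px, y_px, rating).
#' @param readers character roster of the cohort.
#' @param lesions lesion truth data.frame (may be empty).
#' @param images named list of view images (`"<case>_<view>"`).
#' @param spacing mm per pixel of the images.
#' @param thresholds [pipelineThresholds()] list.
#' @param modelConfig [DifficultyModelConfig-class].
#' @param views views to model (default CC and MLO).
#' @param errorTypes error types to model (default FP and FN).
#' @param outputDir optional directory for report files (area tables,
#'   Newick dendrograms, model summary CSV, run manifest JSON).
#' @return list with `areaSetFP` / `areaSetFN` (labelled area sets),
#'   `dendrograms`, `outliers`, `outlierReport`, `rosterFP`, `models`
#'   (per "<errorType>_<view>" [DifficultyModelResult-class]),
#'   `featureStats` (per model top-5 comparison tables) and `summary`
#'   (one row per model).
#' @export
runCohortAnalysis <- function(annotations, readers, lesions, images,
                              spacing, thresholds = pipelineThresholds(),
                              modelConfig = difficultyModelConfig(),
                              views = c("CC", "MLO"),
                              errorTypes = c("FP", "FN"),
                              outputDir = NULL) {
  validateAnnotations(annotations)
  imageSize <- dim(images[[1]])
  areaSet <- buildSuspiciousAreas(annotations, lesions, imageSize, spacing,
                                  thresholds)
  rmFP <- buildResponseMatrix(areaSet, readers, annotations, "FP")
  dendFP <- clusterReaders(rmFP)
  outliers <- identifyOutliers(dendFP)
  excl <- excludeOutliers(annotations, areaSet, readers, outliers)
  areaSetFP <- assignDifficulty(excl$areaSet, excl$responses)
  rmFN <- buildResponseMatrix(areaSet, readers, annotations, "FN")
  dendFN <- if (nrow(responseValues(rmFN)) >= 2 &&
                ncol(responseValues(rmFN)) > 0)
    clusterReaders(rmFN) else NULL
  areaSetFN <- if (ncol(responseValues(rmFN)) > 0)
    assignDifficulty(areaSet, rmFN) else areaSet
  models <- list(); stats <- list(); summaryRows <- list()
  for (et in errorTypes) {
    src <- if (et == "FP") areaSetFP else areaSetFN
    kind <- if (et == "FP") "normal" else "cancer"
    for (v in views) {
      keyName <- paste0(et, "_", v)
      sub <- filterAreas(src, kind = kind, view = v)
      labs <- factor(sub@areas$difficulty, levels = c("easy", "difficult"))
      if (nrow(sub@areas) < 4L || any(table(labs) < 2L)) {
        warning("skipping ", keyName,
                ": need at least 2 areas per difficulty class")
        next
      }
      fs <- extractFeatureSet(sub, images, spacing)
      X <- t(SummarizedExperiment::assay(fs, "features"))
      res <- nestedCV(X, labs, modelConfig, errorType = et, view = v)
      models[[keyName]] <- res
      stats[[keyName]] <- compareDiscriminativeFeatures(res, fs)
      summaryRows[[keyName]] <- data.frame(
        error_type = et, view = v, n_areas = nrow(X),
        n_difficult = sum(labs == "difficult"), auc = modelAUC(res),
        ci_low = modelAUCCI(res)[1], ci_high = modelAUCCI(res)[2],
        accuracy = res@accuracy)
    }
  }
  summary <- if (length(summaryRows)) do.call(rbind, c(summaryRows,
                                                       make.row.names = FALSE))
    else data.frame()
  out <- list(areaSetFP = areaSetFP, areaSetFN = areaSetFN,
              dendrograms = list(FP = dendFP, FN = dendFN),
              outliers = outliers,
              outlierReport = outlierReport(rmFP, outliers),
              rosterFP = excl$readers, models = models,
              featureStats = stats, summary = summary)
  if (!is.null(outputDir)) writeReportBundle(out, outputDir)
  out
}

writeReportBundle <- function(result, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  writeAreaTable(result$areaSetFP, file.path(outputDir, "areas_fp.csv"))
  writeAreaTable(result$areaSetFN, file.path(outputDir, "areas_fn.csv"))
  write.csv(result$outlierReport,
            file.path(outputDir, "outlier_report.csv"), row.names = FALSE)
  writeDendrogramNewick(result$dendrograms$FP,
                        file.path(outputDir, "dendrogram_fp.nwk"))
  if (!is.null(result$dendrograms$FN))
    writeDendrogramNewick(result$dendrograms$FN,
                          file.path(outputDir, "dendrogram_fn.nwk"))
  if (nrow(result$summary))
    write.csv(result$summary, file.path(outputDir, "model_summary.csv"),
              row.names = FALSE)
  for (nm in names(result$featureStats))
    write.csv(result$featureStats[[nm]],
              file.path(outputDir, paste0("feature_stats_", nm, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(
    list(outliers = result$outliers, roster_fp = result$rosterFP,
         models = names(result$models)),
    file.path(outputDir, "manifest.json"), auto_unbox = TRUE)
  invisible(outputDir)
}

#' Run the synthetic end-to-end demonstration
#'
#' Generates a synthetic cohort (default: 40 normal + 20 cancer cases, 16
#' readers including 2 planted outliers), simulates the readings, and runs
#' [runCohortAnalysis()] on them.  The returned bundle additionally
#' carries the generator truth (`caseSet`, `readers` roster with the
#' planted outliers) so recovered outliers and difficulty labels can be
#' checked against the ground truth.
#'
#' @param seed master seed.
#' @param config [SyntheticCohortConfig-class] (its seed is overridden by
#'   `seed`).
#' @param modelConfig [DifficultyModelConfig-class] (seed likewise).
#' @param views,errorTypes which models to fit (defaults: both views,
#'   both error types).
#' @param outputDir optional report directory.
#' @return the [runCohortAnalysis()] bundle plus `caseSet` and `roster`.
#' @export
runDemo <- function(seed = 1L, config = syntheticCohortConfig(),
                    modelConfig = difficultyModelConfig(),
                    views = c("CC", "MLO"), errorTypes = c("FP", "FN"),
                    outputDir = NULL) {
  config@seed <- as.integer(seed)
  modelConfig@seed <- childSeed(seed, 42L)
  caseSet <- generateCaseSet(config)
  sim <- simulateReaders(caseSet, config)
  res <- runCohortAnalysis(sim$annotations, sim$readers$reader_id,
                           caseSet@lesions, caseSet@images,
                           caseSet@pixelSpacing,
                           modelConfig = modelConfig, views = views,
                           errorTypes = errorTypes, outputDir = outputDir)
  res$caseSet <- caseSet
  res$roster <- sim$readers
  res
}
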