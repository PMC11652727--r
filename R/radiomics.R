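#' @include AllClasses.R utils.R prep.R radiomics-firstorder.R
#'   radiomics-matrices.R radiomics-filters.R
NULL

# Grow an inclusive 0-based bbox symmetrically to at least minSize per
# side, clipping (and sliding) at the image bounds.
growBBox <- function(bb, minSize, imageDim) {
  nr <- imageDim[1]; nc <- imageDim[2]
  grow1 <- function(lo, hi, nmax) {
    need <- minSize - (hi - lo + 1)
    if (need > 0) {
      lo <- lo - ceiling(need / 2); hi <- hi + floor(need / 2)
      if (lo < 0) { hi <- min(hi - lo, nmax - 1); lo <- 0 }
      if (hi > nmax - 1) { lo <- max(0, lo - (hi - nmax + 1)); hi <- nmax - 1 }
    }
    c(lo, hi)
  }
  x <- grow1(bb[1], bb[3], nc)
  y <- grow1(bb[2], bb[4], nr)
  c(x[1], y[1], x[2], y[2])
}

.bankCache <- new.env(parent = emptyenv())

cachedRFSBank <- function() {
  if (is.null(.bankCache$rfs)) .bankCache$rfs <- buildRFSBank()
  .bankCache$rfs
}

cachedGaborBank <- function() {
  if (is.null(.bankCache$gabor)) .bankCache$gabor <- gaborBank()
  .bankCache$gabor
}

featureFamilySizes <- c(first_order = 28L, glcm = 88L, glrlm = 6L,
                        glsm = 6L, glds = 15L, ngtdm = 15L, sfm = 8L,
                        fractal = 1L, laws = 18L, gabor = 6L, mr = 8L,
                        fourier = 2L)

#' Feature dictionary
#'
#' One row per radiomic feature: its stable name, family and position.  The
#' bank totals 201 features: 28 first-order, 139 texture (88 GLCM, 6 GLRLM,
#' 6 GLSM, 15 GLDS, 15 NGTDM, 8 SFM, 1 fractal) and 34 filter-based
#' (18 Laws, 6 Gabor, 8 MR8, 2 Fourier).
#'
#' @return data.frame with columns name, family, index.
#' @export
featureDictionary <- function() {
  probe <- extractAllFeatures(matrix(rnorm(1024), 32))
  fam <- rep(names(featureFamilySizes), featureFamilySizes)
  data.frame(name = names(probe), family = fam,
             index = seq_along(probe), stringsAsFactors = FALSE)
}

#' Extract the full 201-feature radiomic vector
#'
#' Concatenates, in fixed order, the first-order, GLCM, GLRLM, GLSM, GLDS,
#' NGTDM, SFM, fractal-dimension, Laws, Gabor, MR8 and Fourier features of
#' one ROI.  Matrix families use the quantized representation; intensity
#' and filter families use the raw (prepared) ROI.  The result is
#' deterministic and all values finite.
#'
#' @param roi numeric matrix: the prepared (normalized, resampled) ROI.
#' @param qroi quantized companion from [quantizeROI()] of the same ROI
#'   (computed on the fly when missing).
#' @return named numeric vector of length 201.
#' @examples
#' length(extractAllFeatures(matrix(rnorm(4096), 64)))  # 201
#' @export
extractAllFeatures <- function(roi, qroi = suppressWarnings(quantizeROI(roi))) {
  out <- c(firstOrderFeatures(roi),
           glcmFeatures(qroi),
           glrlmFeatures(qroi),
           glsmFeatures(roi),
           gldsFeatures(roi),
           ngtdmFeatures(qroi),
           sfmFeatures(qroi),
           fractalDimension(roi),
           lawsFeatures(roi),
           gaborFeatures(roi, cachedGaborBank()),
           mr8Features(roi, cachedRFSBank()),
           fourierFeatures(roi))
  assertThat(length(out) == 201L,
             sprintf("feature bank emitted %d features, expected 201",
                     length(out)))
  bad <- !is.finite(out)
  if (any(bad)) {
    warning("non-finite features replaced by 0: ",
            paste(names(out)[bad], collapse = ", "))
    out[bad] <- 0
  }
  out
}

#' Extract radiomic features for every suspicious area
#'
#' For each area in the set, the per-view image is normalized to zero mean
#' and unit variance, resampled to the working spacing when needed, the
#' area's bounding box is cropped (coordinates rescaled accordingly), the
#' crop is quantized, and the 201-feature vector is computed.  Results are
#' returned features-by-areas in a [RadiomicFeatureSet-class] whose column
#' metadata carries the area kind, view and difficulty label.
#'
#' Bounding boxes are grown symmetrically about their centre to at least
#' `minROISize` pixels per side (clipped at the image edge): the largest
#' filter supports in the bank (15 x 15 Laws energy windows, 49 x 49 MR8
#' kernels, offset-9 co-occurrence) need that much context, and a fixed
#' analysis window keeps ROI area from acting as a proxy for the number of
#' marks an area attracted.
#'
#' @param areaSet a [SuspiciousAreaSet-class] (ideally after
#'   [assignDifficulty()]).
#' @param images named list of view images (`"<case>_<view>"`).
#' @param spacing mm per pixel of the supplied images.
#' @param targetSpacing working spacing of the radiomic pipeline (0.1 mm).
#' @param quantLevels grey levels for the matrix families (64).
#' @param minROISize minimum ROI side in pixels at the target spacing
#'   (default 72, i.e. 7.2 mm).
#' @return a [RadiomicFeatureSet-class].
#' @export
extractFeatureSet <- function(areaSet, images, spacing, targetSpacing = 0.1,
                              quantLevels = 64L, minROISize = 72L) {
  areas <- areaSet@areas
  assertThat(nrow(areas) > 0, "area set is empty")
  mats <- vector("list", nrow(areas))
  prepared <- list()
  for (i in seq_len(nrow(areas))) {
    a <- areas[i, ]
    key <- paste0(a$case_id, "_", a$view)
    assertThat(key %in% names(images),
               paste("missing image for", key))
    if (is.null(prepared[[key]])) {
      img <- normalizeIntensity(images[[key]])
      if (!isTRUE(all.equal(spacing, targetSpacing)))
        img <- resampleImage(img, spacing, targetSpacing)
      prepared[[key]] <- img
    }
    sf <- spacing / targetSpacing
    bb <- c(round(c(a$x_min, a$y_min) * sf),
            round((c(a$x_max, a$y_max) + 1) * sf) - 1)
    bb <- growBBox(bb, minROISize, dim(prepared[[key]]))
    roi <- extractROI(prepared[[key]], bb)
    mats[[i]] <- extractAllFeatures(roi, suppressWarnings(
      quantizeROI(roi, quantLevels)))
  }
  fm <- do.call(cbind, mats)
  colnames(fm) <- areas$area_id
  fam <- rep(names(featureFamilySizes), featureFamilySizes)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = fm),
    rowData = S4Vectors::DataFrame(family = fam, row.names = rownames(fm)),
    colData = S4Vectors::DataFrame(
      area_id = areas$area_id, case_id = areas$case_id, view = areas$view,
      kind = areas$kind,
      difficulty = areas$difficulty,
      false_count = if ("false_count" %in% names(areas))
        areas$false_count else NA_real_,
      row.names = areas$area_id))
  new("RadiomicFeatureSet", se)
}

#' Write a feature table
#'
#' One CSV row per area: metadata columns followed by the 201 feature
#' values; the feature dictionary is written as a JSON twin.
#'
#' @param featureSet a [RadiomicFeatureSet-class].
#' @param path CSV output path.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(featureSet, path) {
  fm <- t(SummarizedExperiment::assay(featureSet, "features"))
  meta <- as.data.frame(SummarizedExperiment::colData(featureSet))
  write.csv(cbind(meta, as.data.frame(fm)), path, row.names = FALSE)
  dict <- data.frame(
    name = rownames(featureSet),
    family = SummarizedExperiment::rowData(featureSet)$family)
  jsonlite::write_json(dict, sub("\\.csv$", "_dictionary.json", path))
  invisible(path)
}
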