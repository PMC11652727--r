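#' @include AllClasses.R utils.R
NULL

validateAnnotations <- function(ann) {
  need <- c("reader_id", "case_id", "view", "side", "x_px", "y_px", "rating")
  assertThat(all(need %in% names(ann)),
             paste("annotation table must contain columns:",
                   paste(need, collapse = ", ")))
  assertThat(all(ann$rating %in% 1:5), "ratings must lie in 1..5")
  assertThat(all(ann$view %in% c("CC", "MLO")), "view must be CC or MLO")
  invisible(ann)
}

#' Pipeline thresholds
#'
#' The constants that define suspicious-area construction: positive marks
#' are ratings of `positiveRatingCutoff` (3) or more; positive marks
#' cluster while every within-cluster pairwise distance stays at or below
#' `clusterMaxDistance` pixels (250); bounding boxes extend `bboxMargin`
#' pixels (10) beyond the outermost member annotation; an annotation hits a
#' lesion when it lies within `lesionHitRadiusMM` (12.5 mm) of the lesion
#' centre; difficulty is a strict-greater median split of false-response
#' counts.
#'
#' @param positiveRatingCutoff,clusterMaxDistance,bboxMargin,lesionHitRadiusMM
#'   see description.
#' @return a named list of validated thresholds.
#' @export
pipelineThresholds <- function(positiveRatingCutoff = 3L,
                               clusterMaxDistance = 250,
                               bboxMargin = 10,
                               lesionHitRadiusMM = 12.5) {
  th <- list(positiveRatingCutoff = as.integer(positiveRatingCutoff),
             clusterMaxDistance = clusterMaxDistance,
             bboxMargin = bboxMargin,
             lesionHitRadiusMM = lesionHitRadiusMM)
  assertThat(all(unlist(th) > 0), "all thresholds must be strictly positive")
  th
}

#' Keep the positive annotations
#'
#' Retains, in input order, the annotations rated at or above the cutoff
#' (rating >= 3 is a positive cancer call; below 3 is negative).
#'
#' @param annotations validated annotation data.frame.
#' @param cutoff positive rating cutoff (default 3).
#' @return the positive subset, order preserved.
#' @examples
#' ann <- data.frame(reader_id = "R1", case_id = "c", view = "CC",
#'                   side = "L", x_px = 1:5, y_px = 0, rating = 1:5)
#' nrow(poolPositiveAnnotations(ann))  # 3
#' @export
poolPositiveAnnotations <- function(annotations, cutoff = 3L) {
  validateAnnotations(annotations)
  annotations[annotations$rating >= cutoff, , drop = FALSE]
}

#' Cluster annotation points by a diameter constraint
#'
#' Complete-linkage agglomerative clustering of (x, y) points, cut so that
#' every within-cluster pairwise Euclidean distance is at most
#' `maxDistance`.  Complete linkage is the linkage whose cut height bounds
#' the cluster diameter, which is exactly the "no pair farther than 250
#' pixels" rule.
#'
#' @param points numeric matrix or data.frame with two columns (x, y).
#' @param maxDistance largest allowed within-cluster pairwise distance.
#' @return integer cluster labels (1-based), one per point.
#' @examples
#' clusterAnnotations(rbind(c(0, 0), c(100, 0), c(400, 0)), 250)  # 1 1 2
#' @export
clusterAnnotations <- function(points, maxDistance) {
  assertThat(maxDistance > 0, "maxDistance must be > 0")
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  hc <- hclust(dist(points), method = "complete")
  cutree(hc, h = maxDistance)
}

#' Bounding box around a cluster of annotations
#'
#' Inclusive 0-based box extending `margin` pixels beyond the outermost
#' member annotation on every side, clipped to the image bounds.
#'
#' @param cluster matrix/data.frame of (x, y) points; must be non-empty.
#' @param margin pixels added on every side (default 10).
#' @param imageSize integer c(rows, cols) for clipping.
#' @return named numeric c(x_min, y_min, x_max, y_max).
#' @examples
#' makeBoundingBox(cbind(50, 60), margin = 10, imageSize = c(100, 100))
#' @export
makeBoundingBox <- function(cluster, margin = 10, imageSize) {
  cluster <- as.matrix(cluster)
  assertThat(nrow(cluster) >= 1L, "cluster must contain at least one point")
  nr <- imageSize[1]; nc <- imageSize[2]
  c(x_min = max(min(cluster[, 1]) - margin, 0),
    y_min = max(min(cluster[, 2]) - margin, 0),
    x_max = min(max(cluster[, 1]) + margin, nc - 1),
    y_max = min(max(cluster[, 2]) + margin, nr - 1))
}

#' Match annotations to the nearest lesion within the hit radius
#'
#' An annotation hits a lesion when its distance to the lesion centre is at
#' most the hit radius (inclusive), converted from mm to pixels via the
#' spacing.  The nearest qualifying lesion wins; exact ties break by lesion
#' id order.
#'
#' @param points matrix/data.frame of annotation (x, y) pixel coordinates.
#' @param lesions data.frame with lesion_id, x_px, y_px (same view/side).
#' @param spacing mm per pixel.
#' @param hitRadiusMM hit radius in mm (default 12.5).
#' @return character vector of matched lesion ids (NA when unmatched), one
#'   per point.
#' @export
matchAnnotationsToLesions <- function(points, lesions, spacing,
                                      hitRadiusMM = 12.5) {
  assertThat(spacing > 0, "spacing must be > 0")
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(character(0))
  if (is.null(lesions) || nrow(lesions) == 0L) return(rep(NA_character_, n))
  radiusPx <- hitRadiusMM / spacing
  lesions <- lesions[order(lesions$lesion_id), , drop = FALSE]
  vapply(seq_len(n), function(i) {
    d <- sqrt((lesions$x_px - points[i, 1])^2 +
                (lesions$y_px - points[i, 2])^2)
    ok <- which(d <= radiusPx)
    if (!length(ok)) return(NA_character_)
    lesions$lesion_id[ok[which.min(d[ok])]]
  }, character(1))
}

#' Build suspicious areas from annotations and lesion truths
#'
#' Per view image: positive annotations matched to a lesion (within the hit
#' radius of its centre) join that lesion's cancer area; the remaining
#' positive marks are clustered under the 250-pixel diameter rule, and each
#' cluster becomes a normal suspicious area.  Every lesion seeds a cancer
#' area even if no reader marked it (an all-reader miss must still be
#' analysable).  Bounding boxes extend 10 pixels beyond the outermost
#' member annotation (for unmarked lesions, around the lesion disc).
#'
#' @param annotations annotation data.frame (all ratings).
#' @param lesions lesion truth data.frame (may be empty/NULL).
#' @param imageSize integer c(rows, cols).
#' @param spacing mm per pixel.
#' @param thresholds a [pipelineThresholds()] list.
#' @return a [SuspiciousAreaSet-class].
#' @export
buildSuspiciousAreas <- function(annotations, lesions, imageSize, spacing,
                                 thresholds = pipelineThresholds()) {
  validateAnnotations(annotations)
  if (is.null(lesions))
    lesions <- data.frame(lesion_id = character(0), case_id = character(0),
                          view = character(0), side = character(0),
                          x_px = numeric(0), y_px = numeric(0),
                          radius_mm = numeric(0))
  pos <- poolPositiveAnnotations(annotations, thresholds$positiveRatingCutoff)
  keys <- unique(rbind(pos[c("case_id", "view", "side")],
                       lesions[c("case_id", "view", "side")]))
  keys <- keys[order(keys$case_id, keys$view, keys$side), , drop = FALSE]
  areaRows <- list(); memberRows <- list()
  counter <- 0L
  for (i in seq_len(nrow(keys))) {
    kk <- keys[i, ]
    p <- pos[pos$case_id == kk$case_id & pos$view == kk$view &
               pos$side == kk$side, , drop = FALSE]
    ll <- lesions[lesions$case_id == kk$case_id & lesions$view == kk$view &
                    lesions$side == kk$side, , drop = FALSE]
    match <- matchAnnotationsToLesions(p[c("x_px", "y_px")], ll, spacing,
                                       thresholds$lesionHitRadiusMM)
    # one cancer area per lesion, marked or not
    for (j in seq_len(nrow(ll))) {
      counter <- counter + 1L
      mem <- p[!is.na(match) & match == ll$lesion_id[j], , drop = FALSE]
      radiusPx <- ll$radius_mm[j] / spacing
      pts <- rbind(as.matrix(mem[c("x_px", "y_px")]),
                   c(ll$x_px[j] - radiusPx, ll$y_px[j] - radiusPx),
                   c(ll$x_px[j] + radiusPx, ll$y_px[j] + radiusPx))
      bb <- makeBoundingBox(pts, thresholds$bboxMargin, imageSize)
      aid <- sprintf("area%04d", counter)
      areaRows[[counter]] <- data.frame(
        area_id = aid, case_id = kk$case_id, view = kk$view, side = kk$side,
        kind = "cancer", x_min = bb["x_min"], y_min = bb["y_min"],
        x_max = bb["x_max"], y_max = bb["y_max"],
        lesion_id = ll$lesion_id[j], n_members = nrow(mem),
        difficulty = NA_character_, stringsAsFactors = FALSE,
        row.names = NULL)
      if (nrow(mem)) memberRows[[length(memberRows) + 1L]] <-
          cbind(mem, area_id = aid, row.names = NULL)
    }
    # normal areas from the unmatched positive marks
    un <- p[is.na(match), , drop = FALSE]
    if (nrow(un)) {
      cl <- clusterAnnotations(un[c("x_px", "y_px")],
                               thresholds$clusterMaxDistance)
      for (g in sort(unique(cl))) {
        counter <- counter + 1L
        mem <- un[cl == g, , drop = FALSE]
        bb <- makeBoundingBox(mem[c("x_px", "y_px")],
                              thresholds$bboxMargin, imageSize)
        aid <- sprintf("area%04d", counter)
        areaRows[[counter]] <- data.frame(
          area_id = aid, case_id = kk$case_id, view = kk$view,
          side = kk$side, kind = "normal", x_min = bb["x_min"],
          y_min = bb["y_min"], x_max = bb["x_max"], y_max = bb["y_max"],
          lesion_id = NA_character_, n_members = nrow(mem),
          difficulty = NA_character_, stringsAsFactors = FALSE,
          row.names = NULL)
        memberRows[[length(memberRows) + 1L]] <-
          cbind(mem, area_id = aid, row.names = NULL)
      }
    }
  }
  areas <- if (counter) do.call(rbind, areaRows) else
    data.frame(area_id = character(0), case_id = character(0),
               view = character(0), side = character(0), kind = character(0),
               x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
               y_max = numeric(0), lesion_id = character(0),
               n_members = integer(0), difficulty = character(0))
  members <- if (length(memberRows)) do.call(rbind, memberRows) else
    cbind(annotations[0, ], area_id = character(0))
  new("SuspiciousAreaSet", areas = areas, members = members,
      imageSize = as.integer(imageSize), thresholds = thresholds)
}

#' Build the readers-by-areas false-response matrix
#'
#' For a normal area, a reader's entry is 1 when they left at least one
#' positive mark inside the area's bounding box (a false positive).  For a
#' cancer area, the entry is 1 when they left no positive mark inside the
#' box (a false negative: a negative mark or no mark at all).
#'
#' @param areaSet a [SuspiciousAreaSet-class].
#' @param readers character vector: the cohort roster.
#' @param annotations full annotation data.frame (all ratings).
#' @param errorType "FP" (normal areas) or "FN" (cancer areas).
#' @param cutoff positive rating cutoff (default from the area set's
#'   thresholds).
#' @return a [ResponseMatrix-class].
#' @export
buildResponseMatrix <- function(areaSet, readers, annotations,
                                errorType = c("FP", "FN"),
                                cutoff = areaSet@thresholds$positiveRatingCutoff) {
  errorType <- match.arg(errorType)
  validateAnnotations(annotations)
  assertThat(all(annotations$reader_id %in% readers),
             "annotation from a reader absent from the roster")
  kind <- if (errorType == "FP") "normal" else "cancer"
  areas <- areaSet@areas[areaSet@areas$kind == kind, , drop = FALSE]
  pos <- annotations[annotations$rating >= cutoff, , drop = FALSE]
  m <- matrix(0, length(readers), nrow(areas),
              dimnames = list(readers, areas$area_id))
  for (j in seq_len(nrow(areas))) {
    a <- areas[j, ]
    inBox <- pos$case_id == a$case_id & pos$view == a$view &
      pos$side == a$side &
      pos$x_px >= a$x_min & pos$x_px <= a$x_max &
      pos$y_px >= a$y_min & pos$y_px <= a$y_max
    hit <- unique(pos$reader_id[inBox])
    if (errorType == "FP") m[hit, j] <- 1 else m[setdiff(readers, hit), j] <- 1
  }
  new("ResponseMatrix", values = m, errorType = errorType)
}

#' Assign easy/difficult labels by a median split
#'
#' Per area kind (normal areas under false positives, cancer areas under
#' false negatives), each area's false-response count is compared with the
#' median count over areas of that kind: strictly above the median is
#' "difficult", at or below is "easy".  When every count is equal the
#' labelling is degenerate (all easy) and a warning is emitted.
#'
#' @param areaSet a [SuspiciousAreaSet-class].
#' @param responses a [ResponseMatrix-class] built from the matching kind
#'   and (for FP) the post-exclusion roster.
#' @return the area set with `difficulty` and `false_count` filled in for
#'   the matching kind.
#' @examples
#' # counts 1,1,2,3 (median 1.5) -> easy, easy, difficult, difficult
#' @export
assignDifficulty <- function(areaSet, responses) {
  counts <- colSums(responseValues(responses))
  kind <- if (responses@errorType == "FP") "normal" else "cancer"
  idx <- match(names(counts), areaSet@areas$area_id)
  assertThat(!anyNA(idx), "response matrix areas missing from the area set")
  assertThat(all(areaSet@areas$kind[idx] == kind),
             "response matrix kind does not match the area kinds")
  med <- median(counts)
  if (length(counts) && all(counts == counts[1]))
    warning("all false-response counts equal; every area labelled easy")
  areaSet@areas$difficulty[idx] <- ifelse(counts > med, "difficult", "easy")
  if (!"false_count" %in% names(areaSet@areas))
    areaSet@areas$false_count <- NA_real_
  areaSet@areas$false_count[idx] <- counts
  areaSet
}

#' Write the area table
#'
#' CSV with one row per suspicious area (bounding box, kind, member count,
#' false-response count and difficulty label) plus a JSON copy.
#'
#' @param areaSet a [SuspiciousAreaSet-class].
#' @param path CSV output path (a .json twin is written alongside).
#' @return invisibly, `path`.
#' @export
writeAreaTable <- function(areaSet, path) {
  write.csv(areaSet@areas, path, row.names = FALSE)
  jsonlite::write_json(areaSet@areas,
                       sub("\\.csv$", ".json", path), digits = NA)
  invisible(path)
}
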