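#' @include AllClasses.R utils.R
NULL

#' Construct a synthetic cohort configuration
#'
#' The defaults reproduce the design of a dense-mammogram reading study: 60
#' cases (40 normal, 20 biopsy-proven cancers, one lesion each), two views
#' per case (CC and MLO), and a reader cohort of 16 with 2 planted
#' high-false-positive outliers.  Difficult planted areas carry oriented
#' texture at 4 pixels/cycle (the `difficultyEffect` energy) and attract
#' more false-positive marks.
#'
#' @param nNormalCases,nCancerCases case counts (40, 20).
#' @param imageSize image rows and cols (length 1 or 2; default 768).
#' @param pixelSpacing mm/pixel (default 0.1, the working resolution of the
#'   radiomic pipeline, so synthetic images need no resampling).
#' @param nReaders,nOutlierReaders roster size and planted outliers (16, 2).
#' @param baseFPRate easy-area false-positive rate per reader (0.1).
#' @param outlierFPMultiplier rate multiplier for outlier readers (4).
#' @param fpDifficultyMultiplier rate multiplier for difficult areas
#'   (default 7: with the 0.1 base rate and ~14 readers this produces
#'   per-area false-positive counts of ~1-3 on easy areas and ~7-13 on
#'   difficult ones, the bimodal spread a median split needs).
#' @param difficultyEffect oriented texture energy injected into difficult
#'   areas (default 2).
#' @param hitRateEasy,hitRateDifficult lesion hit rates (0.8, 0.4).
#' @param negativeMarkRate chance of a rating < 3 mark when not marking
#'   positively (0.1).
#' @param soloFPPerOutlier idiosyncratic false-positive marks per outlier
#'   reader at locations nobody else marks (default 12; these create the
#'   solo areas that exclusion removes, the signature by which outlying
#'   readers separate in the dendrogram).
#' @param annotationJitterSD mark jitter SD in pixels (12).
#' @param areasPerView planted suspicious normal areas per view (2).
#' @param difficultFraction fraction of difficult planted areas (default
#'   0.4, assigned exactly rather than independently per area; the
#'   difficult class is the minority, which is why the modelling pipeline
#'   carries SMOTE, and easy areas that attract no marks drop out of the
#'   analysis, pulling the realized split towards balance).
#' @param lesionRadiusMM lesion radius written to the truth table (12.5).
#' @param seed master seed.
#' @return a validated [SyntheticCohortConfig-class].
#' @examples
#' cfg <- syntheticCohortConfig(nNormalCases = 4, nCancerCases = 2, seed = 1)
#' @export
syntheticCohortConfig <- function(nNormalCases = 40L, nCancerCases = 20L,
    imageSize = 768L, pixelSpacing = 0.1, nReaders = 16L,
    nOutlierReaders = 2L, baseFPRate = 0.1, outlierFPMultiplier = 4,
    fpDifficultyMultiplier = 7, difficultyEffect = 2,
    hitRateEasy = 0.8, hitRateDifficult = 0.4, negativeMarkRate = 0.1,
    soloFPPerOutlier = 12L,
    annotationJitterSD = 12, areasPerView = 2L, difficultFraction = 0.4,
    lesionRadiusMM = 12.5, seed = 1L) {
  if (length(imageSize) == 1L) imageSize <- rep(imageSize, 2L)
  new("SyntheticCohortConfig",
      nNormalCases = as.integer(nNormalCases),
      nCancerCases = as.integer(nCancerCases),
      imageSize = as.integer(imageSize), pixelSpacing = pixelSpacing,
      nReaders = as.integer(nReaders),
      nOutlierReaders = as.integer(nOutlierReaders),
      baseFPRate = baseFPRate, outlierFPMultiplier = outlierFPMultiplier,
      fpDifficultyMultiplier = fpDifficultyMultiplier,
      difficultyEffect = difficultyEffect, hitRateEasy = hitRateEasy,
      hitRateDifficult = hitRateDifficult,
      negativeMarkRate = negativeMarkRate,
      soloFPPerOutlier = as.integer(soloFPPerOutlier),
      annotationJitterSD = annotationJitterSD,
      areasPerView = as.integer(areasPerView),
      difficultFraction = difficultFraction,
      lesionRadiusMM = lesionRadiusMM, seed = as.integer(seed))
}

# Tukey (tapered cosine) window, flat in the central (1 - alpha) fraction.
tukeyWindow <- function(n, alpha = 0.4) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

#' Generate a textured breast-like patch
#'
#' Sum of a smoothed Gaussian random field (unit variance unless nearly
#' flat) and, when `orientedEnergy > 0`, band-limited noise modulated by a
#' sinusoidal carrier at ~4 pixels/cycle along `orientation`.  The oriented
#' component is what makes "difficult" synthetic areas difficult: it is the
#' structure the wavelength-4 Gabor features of the radiomic bank respond
#' to.
#'
#' @param size patch rows and cols (length 1 or 2, each >= 16).
#' @param smoothness Gaussian smoothing sigma of the base field (pixels).
#' @param orientedEnergy SD multiple of the oriented component (>= 0).
#' @param orientation carrier direction in degrees (0 = variation along x).
#' @param seed integer seed; identical seeds give identical patches.
#' @param wavelength carrier wavelength in pixels/cycle (default 4).
#' @return a numeric matrix.
#' @examples
#' p <- generateTexturePatch(64, smoothness = 4, orientedEnergy = 2,
#'                           orientation = 0, seed = 7)
#' @export
generateTexturePatch <- function(size, smoothness = 4, orientedEnergy = 0,
                                 orientation = 0, seed = 1,
                                 wavelength = 4) {
  if (length(size) == 1L) size <- rep(size, 2L)
  assertThat(all(size >= 16), "patch size must be at least 16 pixels")
  assertThat(orientedEnergy >= 0, "orientedEnergy must be >= 0")
  nr <- size[1]; nc <- size[2]
  withSeed(seed, {
    base <- matrix(rnorm(nr * nc), nr, nc)
    if (!is.finite(smoothness) || smoothness >= min(nr, nc)) {
      base[] <- mean(base)  # the sigma -> infinity limit: a flat field
    } else if (smoothness > 0) {
      half <- min(ceiling(3 * smoothness), min(nr, nc) - 1L)
      ax <- seq(-half, half)
      k1 <- exp(-ax^2 / (2 * smoothness^2))
      k <- outer(k1, k1); k <- k / sum(k)
      base <- convolve2(base, k)
    }
    s <- popSD(base)
    if (s > 1e-8) base <- (base - mean(base)) / s else base <- base - mean(base)
    out <- base
    if (orientedEnergy > 0) {
      env <- matrix(rnorm(nr * nc), nr, nc)
      env <- convolve2(env, gaussianKernel(2))
      th <- orientation * pi / 180
      xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
      ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
      u <- xs * cos(th) + ys * sin(th)
      phase <- runif(1, 0, 2 * pi)
      carrier <- cos(2 * pi * u / wavelength + phase)
      comp <- env * carrier
      cs <- popSD(comp)
      if (cs > 1e-12) comp <- comp / cs
      out <- out + orientedEnergy * comp
    }
    out
  })
}

# Half-ellipse breast support: chest wall on the left image edge.
breastMask <- function(nr, nc) {
  a <- 0.95 * nc
  b <- 0.46 * nr
  cy <- (nr - 1) / 2
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  (xs / a)^2 + ((ys - cy) / b)^2 <= 1
}

# Rejection-sample k centres inside the mask, all at least minSep apart and
# margin pixels away from the mask boundary.
sampleCentres <- function(k, nr, nc, margin, minSep, maxTries = 5000L) {
  mask <- breastMask(nr, nc)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L; sinceLast <- 0L
  while (nrow(pts) < k && tries < maxTries) {
    tries <- tries + 1L
    sinceLast <- sinceLast + 1L
    if (sinceLast > 150L) {  # early picks can block the rest; restart
      pts <- matrix(numeric(0), 0, 2)
      sinceLast <- 0L
    }
    x <- round(runif(1, margin, nc - 1 - margin))
    y <- round(runif(1, margin, nr - 1 - margin))
    corners <- rbind(c(x - margin, y - margin), c(x + margin, y - margin),
                     c(x - margin, y + margin), c(x + margin, y + margin))
    corners <- pmin(pmax(corners, 0), rep(c(nc - 1, nr - 1), each = 4))
    inMask <- all(mask[cbind(corners[, 2] + 1, corners[, 1] + 1)])
    if (!inMask) next
    if (nrow(pts) > 0 &&
        min(sqrt((pts[, 1] - x)^2 + (pts[, 2] - y)^2)) < minSep) next
    pts <- rbind(pts, c(x, y))
    sinceLast <- 0L
  }
  assertThat(nrow(pts) == k,
             "could not place planted areas; enlarge imageSize or reduce areasPerView")
  pts
}

lesionSubtypes <- c("stellate", "architectural distortion", "calcification",
                    "discrete mass", "non-specific density")

#' Generate a synthetic case set
#'
#' Emits `nNormalCases + nCancerCases` cases, each with CC and MLO views of
#' one breast.  Every view carries `areasPerView` planted suspicious normal
#' areas (easy or difficult); cancer views additionally carry one lesion.
#' Difficult areas receive an injected carrier texture at 4 pixels/cycle
#' oriented at 0 degrees with energy `difficultyEffect`; easy areas receive
#' an equal-energy control carrier at the orthogonal orientation (90
#' degrees), so the two classes are energy-matched and differ only in
#' orientation structure (the cue the wavelength-4 Gabor features resolve).
#' Difficult lesions are rendered at lower contrast.  All placements stay
#' inside a half-ellipse breast mask and are mutually separated by more
#' than the 250-pixel clustering threshold, so the annotation-processing
#' stage can recover them.
#'
#' @param config a [SyntheticCohortConfig-class].
#' @return a [MammoCaseSet-class].
#' @examples
#' cs <- generateCaseSet(syntheticCohortConfig(nNormalCases = 2,
#'   nCancerCases = 1, imageSize = 640, seed = 3))
#' length(cs@images)  # 3 cases x 2 views
#' @export
generateCaseSet <- function(config) {
  validObject(config)
  nr <- config@imageSize[1]; nc <- config@imageSize[2]
  views <- c("CC", "MLO")
  patch <- 120L
  radiusPx <- config@lesionRadiusMM / config@pixelSpacing
  nCases <- config@nNormalCases + config@nCancerCases
  caseIds <- sprintf("case%03d", seq_len(nCases))
  status <- rep(c("normal", "cancer"),
                c(config@nNormalCases, config@nCancerCases))
  images <- list()
  lesions <- list(); planted <- list()
  win <- outer(tukeyWindow(patch), tukeyWindow(patch))
  withSeed(config@seed, {
    areaCounter <- 0L
    lesionCounter <- 0L
    subtypePerCase <- if (config@nCancerCases > 0)
      sample(lesionSubtypes, config@nCancerCases, replace = TRUE) else character(0)
    # exact minority assignment of difficult planted areas
    nPlanted <- nCases * 2L * config@areasPerView
    nHard <- round(config@difficultFraction * nPlanted)
    hardAll <- sample(rep(c(TRUE, FALSE), c(nHard, nPlanted - nHard)))
    for (ci in seq_len(nCases)) {
      for (v in views) {
        img <- generateTexturePatch(c(nr, nc), smoothness = 6,
                                    orientedEnergy = 0,
                                    seed = childSeed(config@seed,
                                                     ci * 10L + match(v, views)))
        img <- img * breastMask(nr, nc)
        isCancer <- status[ci] == "cancer"
        k <- config@areasPerView + as.integer(isCancer)
        margin <- if (isCancer) max(patch / 2 + 8, radiusPx * 0.6) else patch / 2 + 8
        centres <- sampleCentres(k, nr, nc, margin = margin, minSep = 330)
        nHardPool <- round(config@difficultFraction * config@areasPerView * 2)
        for (ai in seq_len(config@areasPerView)) {
          areaCounter <- areaCounter + 1L
          hard <- hardAll[areaCounter]
          energy <- if (hard) config@difficultyEffect else 0
          x <- centres[ai, 1]; y <- centres[ai, 2]
          # difficult areas carry the 0-degree carrier; easy areas carry
          # an equal-energy carrier at the orthogonal orientation, so the
          # classes differ in orientation structure rather than in energy
          orient <- if (hard) 0 else 90
          tex <- generateTexturePatch(patch, smoothness = 4,
                                      orientedEnergy =
                                        config@difficultyEffect,
                                      orientation = orient,
                                      seed = childSeed(config@seed,
                                                       100000L + areaCounter))
          rows <- (y - patch / 2 + 1):(y + patch / 2)
          cols <- (x - patch / 2 + 1):(x + patch / 2)
          img[rows, cols] <- img[rows, cols] + win * tex
          planted[[length(planted) + 1L]] <- data.frame(
            area_uid = sprintf("P%05d", areaCounter), case_id = caseIds[ci],
            view = v, side = "L", x_px = x, y_px = y, kind = "normal",
            hardness = if (hard) "difficult" else "easy",
            oriented_energy = energy,
            control_energy = if (hard) 0 else config@difficultyEffect,
            orientation_deg = orient,
            patch_size = patch, stringsAsFactors = FALSE)
        }
        if (isCancer) {
          lesionCounter <- lesionCounter + 1L
          x <- centres[k, 1]; y <- centres[k, 2]
          hardLesion <- runif(1) < config@difficultFraction
          amp <- if (hardLesion) 0.9 else 2.2
          sig <- radiusPx / 2.5
          half <- round(min(radiusPx * 1.2, x, y, nc - 1 - x, nr - 1 - y))
          ax <- seq(-half, half)
          blob <- amp * outer(exp(-ax^2 / (2 * sig^2)),
                              exp(-ax^2 / (2 * sig^2)))
          rows <- (y - half + 1):(y + half + 1)
          cols <- (x - half + 1):(x + half + 1)
          img[rows, cols] <- img[rows, cols] + blob
          lesions[[length(lesions) + 1L]] <- data.frame(
            lesion_id = sprintf("L%04d", lesionCounter), case_id = caseIds[ci],
            view = v, side = "L", x_px = x, y_px = y,
            radius_mm = config@lesionRadiusMM,
            subtype = subtypePerCase[ci - config@nNormalCases],
            hardness = if (hardLesion) "difficult" else "easy",
            stringsAsFactors = FALSE)
        }
        images[[paste0(caseIds[ci], "_", v)]] <- img
      }
    }
  })
  emptyLesions <- data.frame(lesion_id = character(0), case_id = character(0),
                             view = character(0), side = character(0),
                             x_px = numeric(0), y_px = numeric(0),
                             radius_mm = numeric(0), subtype = character(0),
                             hardness = character(0))
  new("MammoCaseSet", images = images, pixelSpacing = config@pixelSpacing,
      cases = data.frame(case_id = caseIds, status = status,
                         stringsAsFactors = FALSE),
      lesions = if (length(lesions)) do.call(rbind, lesions) else emptyLesions,
      plantedAreas = if (length(planted)) do.call(rbind, planted) else
        data.frame(),
      config = config)
}

# False-positive probability of one reader for one planted normal area.
fpRate <- function(hard, outlier, config) {
  pmin(0.95, config@baseFPRate *
         ifelse(hard, config@fpDifficultyMultiplier, 1) *
         ifelse(outlier, config@outlierFPMultiplier, 1))
}

readerRoster <- function(config, seed) {
  ids <- sprintf("R%02d", seq_len(config@nReaders))
  outliers <- withSeed(seed, sample(ids, config@nOutlierReaders))
  data.frame(reader_id = ids, is_outlier = ids %in% outliers,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort's false-positive response matrix
#'
#' Area-level shortcut past the image stage.  The area population has two
#' strata: shared planted areas, on which every reader draws a Bernoulli
#' false positive at the configured rate (base rate, difficulty multiplier
#' for difficult areas, outlier multiplier for outlier readers), and each
#' outlier's idiosyncratic solo areas (`soloFPPerOutlier` apiece, capped
#' at 40% of the total), which their owner marks with certainty and other
#' readers only at a 0.02 background rate.  Useful for studying the
#' reader-clustering stage at scale.
#'
#' @param nAreas total number of synthetic normal areas.
#' @param config a [SyntheticCohortConfig-class].
#' @param seed integer seed.
#' @return a list with `responses` (a [ResponseMatrix-class]), `readers`
#'   (roster with `is_outlier`), `hardness` (per-area factor; solo areas
#'   count as easy) and `solo_owner` (owner reader id, NA for shared
#'   areas).
#' @examples
#' sim <- simulateFPResponseMatrix(50, syntheticCohortConfig(seed = 1), 1)
#' @export
simulateFPResponseMatrix <- function(nAreas, config, seed = config@seed) {
  roster <- readerRoster(config, childSeed(seed, 1L))
  outIdx <- which(roster$is_outlier)
  nSolo <- min(length(outIdx) * config@soloFPPerOutlier,
               floor(0.4 * nAreas))
  perOut <- if (length(outIdx)) nSolo %/% length(outIdx) else 0L
  nSolo <- perOut * length(outIdx)
  nShared <- nAreas - nSolo
  nHard <- round(config@difficultFraction * nShared)
  hard <- withSeed(childSeed(seed, 2L),
                   sample(rep(c(TRUE, FALSE), c(nHard, nShared - nHard))))
  owner <- rep(NA_integer_, nAreas)
  if (nSolo > 0)
    owner[(nShared + 1):nAreas] <- rep(outIdx, each = perOut)
  m <- withSeed(childSeed(seed, 3L), {
    vapply(seq_len(nAreas), function(a) {
      if (is.na(owner[a])) {
        rbinom(nrow(roster), 1L, fpRate(hard[a], roster$is_outlier, config))
      } else {
        r <- rbinom(nrow(roster), 1L, 0.02)
        r[owner[a]] <- 1L
        r
      }
    }, integer(nrow(roster)))
  })
  m <- matrix(as.numeric(m), nrow(roster), nAreas,
              dimnames = list(roster$reader_id,
                              sprintf("A%05d", seq_len(nAreas))))
  hardness <- c(hard, rep(FALSE, nSolo))
  list(responses = new("ResponseMatrix", values = m, errorType = "FP"),
       readers = roster,
       hardness = factor(ifelse(hardness, "difficult", "easy"),
                         levels = c("easy", "difficult")),
       solo_owner = roster$reader_id[owner])
}

#' Simulate reader annotations over a synthetic case set
#'
#' For every reader and planted area (normal areas and lesions), a Bernoulli
#' draw at the configured rate decides whether a positive mark (rating 3-5)
#' is placed at the area centre plus Gaussian jitter; non-marking readers
#' may still leave a rating 1-2 mark.  Marks jittered outside the image are
#' clipped to its bounds.  Outlier readers carry the elevated
#' false-positive rate.  All draws derive from `seed`.
#'
#' @param caseSet a [MammoCaseSet-class].
#' @param config the generating [SyntheticCohortConfig-class].
#' @param seed integer seed (defaults to a stream derived from the config
#'   seed).
#' @return list with `annotations` (reader_id, case_id, view, side, x_px,
#'   y_px, rating), `readers` (roster with `is_outlier`) and `clipped`
#'   (number of marks clipped to the image bounds).
#' @export
simulateReaders <- function(caseSet, config = caseSet@config,
                            seed = childSeed(config@seed, 77L)) {
  assertThat(isTRUE(all.equal(caseSet@pixelSpacing, config@pixelSpacing)),
             "caseSet and config pixel spacings differ")
  roster <- readerRoster(config, childSeed(seed, 1L))
  pa <- caseSet@plantedAreas
  les <- caseSet@lesions
  nr <- config@imageSize[1]; nc <- config@imageSize[2]
  areas <- rbind(
    if (nrow(pa)) data.frame(case_id = pa$case_id, view = pa$view,
                             side = pa$side, x = pa$x_px, y = pa$y_px,
                             kind = "normal", hardness = pa$hardness),
    if (nrow(les)) data.frame(case_id = les$case_id, view = les$view,
                              side = les$side, x = les$x_px, y = les$y_px,
                              kind = "cancer", hardness = les$hardness))
  clipped <- 0L
  out <- withSeed(childSeed(seed, 2L), {
    recs <- vector("list", nrow(roster) * max(nrow(areas), 1L))
    n <- 0L
    for (r in seq_len(nrow(roster))) {
      for (a in seq_len(nrow(areas))) {
        ar <- areas[a, ]
        p <- if (ar$kind == "normal") {
          fpRate(ar$hardness == "difficult", roster$is_outlier[r], config)
        } else {
          if (ar$hardness == "difficult") config@hitRateDifficult else
            config@hitRateEasy
        }
        positive <- runif(1) < p
        emit <- positive || runif(1) < config@negativeMarkRate
        if (!emit) next
        x <- ar$x + rnorm(1, 0, config@annotationJitterSD)
        y <- ar$y + rnorm(1, 0, config@annotationJitterSD)
        if (x < 0 || x > nc - 1 || y < 0 || y > nr - 1) clipped <- clipped + 1L
        x <- min(max(round(x), 0), nc - 1)
        y <- min(max(round(y), 0), nr - 1)
        rating <- if (positive) sample(3:5, 1) else sample(1:2, 1)
        n <- n + 1L
        recs[[n]] <- data.frame(reader_id = roster$reader_id[r],
                                case_id = ar$case_id, view = ar$view,
                                side = ar$side, x_px = x, y_px = y,
                                rating = rating, stringsAsFactors = FALSE)
      }
    }
    # idiosyncratic solo false positives of the outlier readers: random
    # in-breast locations kept clear of the planted/lesion centres
    mask <- breastMask(nr, nc)
    viewKeys <- names(caseSet@images)
    for (r in which(roster$is_outlier)) {
      placed <- 0L; tries <- 0L
      while (placed < config@soloFPPerOutlier && tries < 5000L) {
        tries <- tries + 1L
        key <- sample(viewKeys, 1)
        caseId <- sub("_(CC|MLO)$", "", key)
        viewId <- sub("^.*_", "", key)
        x <- round(runif(1, 20, nc - 21)); y <- round(runif(1, 20, nr - 21))
        if (!mask[y + 1, x + 1]) next
        cen <- areas[areas$case_id == caseId & areas$view == viewId, ,
                     drop = FALSE]
        if (nrow(cen) &&
            min(sqrt((cen$x - x)^2 + (cen$y - y)^2)) < 340) next
        placed <- placed + 1L
        n <- n + 1L
        recs[[n]] <- data.frame(reader_id = roster$reader_id[r],
                                case_id = caseId, view = viewId,
                                side = "L", x_px = x, y_px = y,
                                rating = sample(3:5, 1),
                                stringsAsFactors = FALSE)
      }
    }
    if (n == 0L) data.frame(reader_id = character(0), case_id = character(0),
                            view = character(0), side = character(0),
                            x_px = numeric(0), y_px = numeric(0),
                            rating = integer(0))
    else do.call(rbind, recs[seq_len(n)])
  })
  if (clipped > 0L)
    message(clipped, " mark(s) clipped to the image bounds")
  list(annotations = out, readers = roster, clipped = clipped)
}

#' Write a synthetic case set to disk
#'
#' Images are written as 16-bit PNG (intensities min-max scaled per image)
#' with a JSON sidecar recording the pixel spacing and the scaling; lesion
#' and planted-area truth tables as CSV.
#'
#' @param caseSet a [MammoCaseSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeCaseSet <- function(caseSet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(caseSet@images)) {
    img <- caseSet@images[[nm]]
    rng <- range(img)
    scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    EBImage::writeImage(EBImage::Image(t(scaled)),
                        file.path(dir, paste0(nm, ".png")), bits.per.sample = 16L)
    jsonlite::write_json(
      list(pixel_spacing_mm = caseSet@pixelSpacing,
           intensity_offset = rng[1], intensity_scale = diff(rng)),
      file.path(dir, paste0(nm, ".json")), auto_unbox = TRUE, digits = NA)
  }
  write.csv(caseSet@lesions, file.path(dir, "lesions.csv"), row.names = FALSE)
  write.csv(caseSet@plantedAreas, file.path(dir, "planted_areas.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read / write annotation tables
#'
#' CSV with columns reader_id, case_id, view (CC/MLO), side (L/R), x_px,
#' y_px (0-based pixels) and rating (1-5).
#'
#' @param annotations a data.frame of annotations.
#' @param path CSV path.
#' @return `readAnnotations` returns the validated data.frame.
#' @export
writeAnnotations <- function(annotations, path) {
  write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  validateAnnotations(ann)
  ann
}
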