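test_that("texture patches are deterministic and respect degenerate limits", {
  p1 <- generateTexturePatch(64, smoothness = 4, orientedEnergy = 2,
                             orientation = 0, seed = 7)
  p2 <- generateTexturePatch(64, smoothness = 4, orientedEnergy = 2,
                             orientation = 0, seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, generateTexturePatch(64, 4, 2, 0, seed = 8)))
  # near-infinite smoothing with no oriented part: flat field, the
  # normalization guard must not blow the variance up
  flat <- generateTexturePatch(32, smoothness = 200, orientedEnergy = 0,
                               seed = 1)
  expect_lt(sd(flat), 0.1)
  expect_error(generateTexturePatch(8), "at least 16")
})

test_that("oriented energy raises the matching Gabor response over seeds", {
  diffs <- vapply(1:20, function(s) {
    with0 <- gaborFeatures(generateTexturePatch(64, 4, 5, 0, seed = s))
    none <- gaborFeatures(generateTexturePatch(64, 4, 0, 0, seed = s))
    with0["gabor_theta0"] - none["gabor_theta0"]
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("case sets have the configured geometry and truths", {
  cfg <- syntheticCohortConfig(nNormalCases = 3, nCancerCases = 2,
                               imageSize = 640, seed = 11)
  cs <- generateCaseSet(cfg)
  expect_length(cs@images, 10)        # 5 cases x 2 views
  expect_equal(nrow(cs@cases), 5)
  expect_equal(nrow(cs@lesions), 4)   # one lesion per cancer view
  expect_true(all(cs@lesions$case_id %in%
                    cs@cases$case_id[cs@cases$status == "cancer"]))
  expect_equal(nrow(cs@plantedAreas), 20)
  # difficulty separation is encoded in the truth table
  pa <- cs@plantedAreas
  if (any(pa$hardness == "difficult"))
    expect_gt(mean(pa$oriented_energy[pa$hardness == "difficult"]),
              mean(pa$oriented_energy[pa$hardness == "easy"]))
  # determinism of the truth tables
  cs2 <- generateCaseSet(cfg)
  expect_identical(cs@lesions, cs2@lesions)
  expect_identical(cs@plantedAreas, cs2@plantedAreas)
  # no-cancer configuration emits no lesion truths
  cs0 <- generateCaseSet(syntheticCohortConfig(nNormalCases = 2,
                                               nCancerCases = 0,
                                               imageSize = 640, seed = 1))
  expect_equal(nrow(cs0@lesions), 0)
})

test_that("config invariants are enforced", {
  expect_error(syntheticCohortConfig(nReaders = 4, nOutlierReaders = 4),
               "nOutlierReaders")
  expect_error(syntheticCohortConfig(imageSize = 32), "64")
  expect_error(syntheticCohortConfig(baseFPRate = 1.2), "probabilities")
})

test_that("simulated false-positive rates are calibrated", {
  # realized per-reader FP rate converges to the configured rate
  cfg <- syntheticCohortConfig(nOutlierReaders = 0L, difficultFraction = 0,
                               seed = 1)
  sim <- simulateFPResponseMatrix(1000, cfg, seed = 3)
  rates <- rowMeans(responseValues(sim$responses))
  tol <- 3 * sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(rates - 0.1) < tol))
  # zero rate with no difficulty effect -> zero positive marks
  cfg0 <- syntheticCohortConfig(baseFPRate = 0, difficultyEffect = 0,
                                nNormalCases = 2, nCancerCases = 0,
                                imageSize = 640, negativeMarkRate = 0,
                                soloFPPerOutlier = 0L, seed = 2)
  sim0 <- simulateReaders(generateCaseSet(cfg0), cfg0)
  expect_equal(nrow(sim0$annotations), 0)
})

test_that("total FP counts stay inside the binomial envelope", {
  cfg <- syntheticCohortConfig(nReaders = 14L, nOutlierReaders = 0L,
                               difficultFraction = 0, seed = 1)
  n <- 14 * 100
  lims <- qbinom(c(0.005, 0.995), n, 0.1)
  counts <- vapply(1:50, function(s)
    sum(responseValues(simulateFPResponseMatrix(100, cfg, seed = s)$responses)),
    numeric(1))
  expect_true(all(counts >= lims[1] & counts <= lims[2]))
})

test_that("planted outliers out-mark the non-outlier median", {
  cfg <- syntheticCohortConfig(seed = 1)  # multiplier 4, 2 outliers
  hits <- vapply(1:50, function(s) {
    sim <- simulateFPResponseMatrix(100, cfg, seed = s)
    counts <- rowSums(responseValues(sim$responses))
    out <- sim$readers$is_outlier
    all(counts[out] > median(counts[!out]))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("reader simulation is seeded and marks stay in bounds", {
  cfg <- syntheticCohortConfig(nNormalCases = 2, nCancerCases = 1,
                               imageSize = 640, seed = 4)
  cs <- generateCaseSet(cfg)
  s1 <- simulateReaders(cs, cfg, seed = 5)
  s2 <- simulateReaders(cs, cfg, seed = 5)
  expect_identical(s1$annotations, s2$annotations)
  ann <- s1$annotations
  expect_true(all(ann$x_px >= 0 & ann$x_px <= 639))
  expect_true(all(ann$y_px >= 0 & ann$y_px <= 639))
  expect_true(all(ann$rating %in% 1:5))
})

test_that("case sets round-trip through the disk format", {
  cfg <- syntheticCohortConfig(nNormalCases = 1, nCancerCases = 1,
                               imageSize = 640, seed = 6)
  cs <- generateCaseSet(cfg)
  dir <- withr::local_tempdir()
  writeCaseSet(cs, dir)
  expect_true(file.exists(file.path(dir, "lesions.csv")))
  expect_true(file.exists(file.path(dir, "case001_CC.png")))
  side <- jsonlite::read_json(file.path(dir, "case001_CC.json"))
  expect_equal(side$pixel_spacing_mm, cs@pixelSpacing)
  sim <- simulateReaders(cs, cfg)
  path <- file.path(dir, "ann.csv")
  writeAnnotations(sim$annotations, path)
  back <- readAnnotations(path)
  expect_equal(nrow(back), nrow(sim$annotations))
  expect_equal(back$rating, sim$annotations$rating)
})
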