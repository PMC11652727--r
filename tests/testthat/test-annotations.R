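makeAnn <- function(reader, case, x, y, rating, view = "CC", side = "L") {
  data.frame(reader_id = reader, case_id = case, view = view, side = side,
             x_px = x, y_px = y, rating = rating, stringsAsFactors = FALSE)
}

test_that("positive pooling keeps ratings at or above the cutoff", {
  ann <- makeAnn("R1", "c1", 1:5, 0, 1:5)
  expect_equal(poolPositiveAnnotations(ann)$rating, 3:5)
  expect_equal(nrow(poolPositiveAnnotations(ann[0, ])), 0)
  allNeg <- makeAnn("R1", "c1", 1:3, 0, c(2, 2, 2))
  expect_equal(nrow(poolPositiveAnnotations(allNeg)), 0)
  # order preserved
  shuffled <- makeAnn("R1", "c1", c(9, 1, 5), 0, c(5, 3, 4))
  expect_equal(poolPositiveAnnotations(shuffled)$x_px, c(9, 1, 5))
})

test_that("diameter-constrained clustering matches the worked example", {
  lab <- clusterAnnotations(rbind(c(0, 0), c(100, 0), c(400, 0)), 250)
  expect_equal(lab[1], lab[2])
  expect_false(lab[1] == lab[3])
  expect_equal(clusterAnnotations(cbind(5, 5), 250), 1L)
  expect_equal(unname(clusterAnnotations(rbind(c(1, 1), c(1, 1)), 250)),
               c(1L, 1L))
})

test_that("clustering agrees with naive complete linkage and bounds diameters", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(2:7, 1)
    pts <- matrix(runif(2 * n, 0, 600), n)
    got <- clusterAnnotations(pts, 250)
    want <- oracleCompleteLinkage(pts, 250)
    expect_true(samePartition(got, want), info = paste("seed", s))
    for (g in unique(got)) {
      sub <- pts[got == g, , drop = FALSE]
      if (nrow(sub) > 1) expect_lte(max(dist(sub)), 250)
    }
  }
})

test_that("clustering is invariant to point order", {
  set.seed(9)
  pts <- matrix(runif(24, 0, 800), 12)
  base <- clusterAnnotations(pts, 250)
  for (i in 1:5) {
    perm <- sample(12)
    expect_true(samePartition(base[perm], clusterAnnotations(pts[perm, ], 250)))
  }
})

test_that("bounding boxes extend by the margin and clip at image bounds", {
  expect_equal(makeBoundingBox(cbind(50, 60), 10, c(100, 100)),
               c(x_min = 40, y_min = 50, x_max = 60, y_max = 70))
  expect_equal(makeBoundingBox(rbind(c(0, 0), c(30, 40)), 10, c(100, 100)),
               c(x_min = 0, y_min = 0, x_max = 40, y_max = 50))
  expect_equal(unname(makeBoundingBox(rbind(c(5, 6), c(9, 2)), 0,
                                      c(50, 50))),
               c(5, 2, 9, 6))
  expect_error(makeBoundingBox(cbind(numeric(0), numeric(0)), 10,
                               c(10, 10)), "at least one point")
})

test_that("lesion matching is inclusive at the hit radius and picks nearest", {
  lesions <- data.frame(lesion_id = c("L1", "L2"), x_px = c(0, 300),
                        y_px = c(0, 0))
  # 10 mm away at 0.1 mm spacing = 100 px; radius 12.5 mm = 125 px
  expect_equal(matchAnnotationsToLesions(cbind(100, 0), lesions, 0.1), "L1")
  expect_equal(matchAnnotationsToLesions(cbind(125, 0), lesions, 0.1), "L1")
  expect_equal(matchAnnotationsToLesions(cbind(126, 0), lesions, 0.1),
               NA_character_)
  # nearest of two qualifying lesions wins
  expect_equal(matchAnnotationsToLesions(cbind(180, 0), lesions, 0.1), "L2")
  expect_equal(matchAnnotationsToLesions(cbind(50, 0), NULL, 0.1),
               NA_character_)
})

test_that("response matrices encode false responses per the area kind", {
  lesions <- data.frame(lesion_id = "L1", case_id = "c2", view = "CC",
                        side = "L", x_px = 400, y_px = 400,
                        radius_mm = 12.5)
  ann <- rbind(makeAnn("R1", "c1", 100, 100, 4),
               makeAnn("R2", "c1", 110, 105, 2),
               makeAnn("R1", "c2", 405, 400, 5),
               makeAnn("R3", "c2", 410, 395, 2))
  areas <- buildSuspiciousAreas(ann, lesions, c(1000, 1000), 0.1)
  readers <- c("R1", "R2", "R3")
  fp <- buildResponseMatrix(areas, readers, ann, "FP")
  fn <- buildResponseMatrix(areas, readers, ann, "FN")
  normalId <- areaInfo(areas)$area_id[areaInfo(areas)$kind == "normal"]
  cancerId <- areaInfo(areas)$area_id[areaInfo(areas)$kind == "cancer"]
  # normal area: positive mark inside box -> 1; negative or no mark -> 0
  expect_equal(unname(responseValues(fp)[, normalId]),
               c(R1 = 1, R2 = 0, R3 = 0), ignore_attr = TRUE)
  # cancer area: positive mark -> 0 (true positive); negative mark or no
  # mark -> 1 (false negative)
  expect_equal(unname(responseValues(fn)[, cancerId]),
               c(R1 = 0, R2 = 1, R3 = 1), ignore_attr = TRUE)
  expect_error(buildResponseMatrix(areas, c("R1", "R2"), ann, "FP"),
               "roster")
})

test_that("unmarked lesions still produce a cancer area", {
  lesions <- data.frame(lesion_id = "L1", case_id = "c1", view = "CC",
                        side = "L", x_px = 300, y_px = 300,
                        radius_mm = 12.5)
  ann <- makeAnn("R1", "c1", 100, 100, 1)  # negative mark only
  areas <- buildSuspiciousAreas(ann, lesions, c(1000, 1000), 0.1)
  tab <- areaInfo(areas)
  expect_equal(sum(tab$kind == "cancer"), 1)
  expect_equal(tab$n_members[tab$kind == "cancer"], 0)
})

test_that("difficulty is a strict-greater median split per kind", {
  # counts 1,1,2,3 over four normal areas -> easy easy difficult difficult
  ann <- do.call(rbind, lapply(seq_len(4), function(a) {
    readers <- paste0("R", seq_len(c(1, 1, 2, 3)[a]))
    makeAnn(readers, "c1", 600 * (a - 1) %% 2400 + 10 * seq_along(readers),
            900 * ((a - 1) %/% 2), 5)
  }))
  areas <- buildSuspiciousAreas(ann, NULL, c(3000, 3000), 0.1)
  rm <- buildResponseMatrix(areas, paste0("R", 1:3), ann, "FP")
  expect_equal(sort(unname(colSums(responseValues(rm)))), c(1, 1, 2, 3))
  lab <- assignDifficulty(areas, rm)
  counts <- areaInfo(lab)$false_count
  expect_equal(areaInfo(lab)$difficulty, ifelse(counts > 1.5,
                                                "difficult", "easy"))
  expect_equal(sum(areaInfo(lab)$difficulty == "difficult"), 2)
})

test_that("equal counts degenerate to all-easy with a warning", {
  ann <- rbind(makeAnn("R1", "c1", 10, 10, 4),
               makeAnn("R1", "c1", 600, 600, 4))
  areas <- buildSuspiciousAreas(ann, NULL, c(1000, 1000), 0.1)
  rm <- buildResponseMatrix(areas, "R1", ann, "FP")
  expect_warning(lab <- assignDifficulty(areas, rm), "degenerate|easy")
  expect_true(all(areaInfo(lab)$difficulty == "easy"))
})

test_that("area construction is invariant to annotation order", {
  set.seed(2)
  ann <- makeAnn(sample(paste0("R", 1:5), 30, TRUE), "c1",
                 runif(30, 0, 2900), runif(30, 0, 2900),
                 sample(1:5, 30, TRUE))
  a1 <- buildSuspiciousAreas(ann, NULL, c(3000, 3000), 0.1)
  a2 <- buildSuspiciousAreas(ann[sample(30), ], NULL, c(3000, 3000), 0.1)
  k1 <- areaInfo(a1)[order(areaInfo(a1)$x_min, areaInfo(a1)$y_min),
                     c("x_min", "y_min", "x_max", "y_max", "n_members")]
  k2 <- areaInfo(a2)[order(areaInfo(a2)$x_min, areaInfo(a2)$y_min),
                     c("x_min", "y_min", "x_max", "y_max", "n_members")]
  expect_equal(k1, k2, ignore_attr = TRUE)
})

test_that("per-area false counts on normal areas are in [1, readers]", {
  cfg <- syntheticCohortConfig(nNormalCases = 3, nCancerCases = 0,
                               imageSize = 640, seed = 13)
  cs <- generateCaseSet(cfg)
  sim <- simulateReaders(cs, cfg)
  areas <- buildSuspiciousAreas(sim$annotations, cs@lesions,
                                dim(cs@images[[1]]), cs@pixelSpacing)
  rm <- buildResponseMatrix(areas, sim$readers$reader_id,
                            sim$annotations, "FP")
  counts <- colSums(responseValues(rm))
  expect_true(all(counts >= 1 & counts <= nrow(sim$readers)))
})
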