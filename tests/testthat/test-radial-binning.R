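test_that("distance binning matches the brute-force oracle on random masks, both modes", {
  for (s in 1:30) {
    m <- randomBlobMask(s)
    nm <- asMask(m)
    rOracle <- bruteNormalizedRadius(m)
    for (mode in c("equal_width", "equal_area")) {
      got <- binRaster(computeDistanceBins(nm, mode = mode))
      want <- bruteBins(rOracle, m, 10L, mode)
      expect_identical(got, want,
                       label = sprintf("seed %d mode %s", s, mode))
    }
  }
})

test_that("bin partition conserves mask area and orients center to periphery", {
  nm <- diskMask(40)
  m <- maskRaster(nm)
  for (mode in c("equal_width", "equal_area")) {
    bm <- computeDistanceBins(nm, mode = mode)
    b <- binRaster(bm)
    expect_identical(b > 0L, unname(m))
    expect_identical(sum(tabulate(b[b > 0L], 10)), sum(m))
  }
  # equal_width on a disk: deepest pixel in bin 1, boundary-adjacent in bin 10
  bw <- binRaster(computeDistanceBins(nm, mode = "equal_width"))
  r <- bruteNormalizedRadius(m)
  expect_identical(bw[which.min(r)], 1L)
  boundary <- which(m & (r > max(r[m]) - 1e-9))
  expect_true(all(bw[boundary] == 10L))
})

test_that("equal-area bins are balanced up to tie blocks", {
  nm <- diskMask(40)
  m <- maskRaster(nm)
  b <- binRaster(computeDistanceBins(nm, mode = "equal_area"))
  counts <- tabulate(b[b > 0L], 10)
  r <- bruteNormalizedRadius(m)
  maxTie <- max(table(r[m]))
  expect_true(all(abs(counts - sum(m) / 10) <= maxTie))
})

test_that("profileIntensity averages per bin and validates shapes", {
  nm <- diskMask(30)
  bm <- computeDistanceBins(nm)
  img <- matrix(7, nrow(maskRaster(nm)), ncol(maskRaster(nm)))
  p <- profileIntensity(img, bm)
  expect_equal(meanIntensity(p), rep(7, 10))
  expect_identical(sum(pixelCount(p)), sum(maskRaster(nm)))
  # image equal to its own normalized radius: means strictly increase
  r <- bruteNormalizedRadius(maskRaster(nm))
  r[is.na(r)] <- 0
  p2 <- profileIntensity(r, bm)
  expect_true(all(diff(meanIntensity(p2)) > 0))
  expect_error(profileIntensity(img[1:10, 1:10], bm), "shape")
})

test_that("min-max normalization maps pooled extremes to 0 and 1 and is affine-invariant", {
  mk <- function(v, g, id) new("RadialProfile", meanIntensity = v,
                               pixelCount = rep(10L, 10), nucleusID = id,
                               groupLabel = g, probeID = "chr1")
  p1 <- mk(seq(2, 11), "a", "n1")
  p2 <- mk(seq(3, 12), "b", "n2")
  pm <- normalizeProfiles(list(p1, p2))
  norm <- normalizedProfiles(pm)
  expect_equal(min(norm), 0)
  expect_equal(max(norm), 1)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_false(isDegenerate(pm))
  # positive affine transform of all inputs leaves the matrix unchanged
  p1a <- mk(3.7 * seq(2, 11) + 5, "a", "n1")
  p2a <- mk(3.7 * seq(3, 12) + 5, "b", "n2")
  pma <- normalizeProfiles(list(p1a, p2a))
  expect_equal(normalizedProfiles(pma), norm, tolerance = 1e-12)
  expect_equal(groupMeans(pma), groupMeans(pm), tolerance = 1e-12)
})

test_that("degenerate normalization is flagged, not silently rescaled", {
  mk <- function(g, id) new("RadialProfile", meanIntensity = rep(4, 10),
                            pixelCount = rep(10L, 10), nucleusID = id,
                            groupLabel = g, probeID = "chr1")
  pm <- normalizeProfiles(list(mk("a", "n1"), mk("b", "n2")))
  expect_true(isDegenerate(pm))
  expect_true(all(normalizedProfiles(pm) == 0))
})

test_that("peripherality index behaves at its anchors", {
  expect_equal(peripheralityIndex(rep(1, 10)), 0.5)
  expect_equal(peripheralityIndex(c(rep(0, 9), 3)), 1)
  expect_error(peripheralityIndex(rep(0, 10)), "all-zero")
  # a strongly peripheral noiseless territory scores above 0.5
  p <- sceneParams(territoryRadialMu = 0.9, territoryRadialSigma = 0.02,
                   readNoiseSd = 0, background = 0, seed = 2)
  co <- simulateTerritoryCohort(5, p, seed = 77)
  idx <- vapply(co$profiles, peripheralityIndex, numeric(1))
  expect_true(all(idx > 0.5))
})
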