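test_that("rasterized nucleus masks have the analytic ellipse area", {
  cases <- list(c(20, 20, pi * 400), c(30, 15, pi * 450))
  for (cs in cases) {
    p <- sceneParams(nucleusSemiaxes = cs[1:2], imageSize = c(72, 72), seed = 7)
    m <- makeNucleusMask(p)
    expect_lt(abs(sum(maskRaster(m)) - cs[3]) / cs[3], 0.02)
    expect_equal(length(unique(EBImage::bwlabel(maskRaster(m) * 1)[maskRaster(m)])), 1)
  }
})

test_that("mask generation is deterministic and rejects oversized ellipses", {
  p <- sceneParams(boundaryPerturbAmp = 0.1, seed = 11)
  expect_identical(maskRaster(makeNucleusMask(p)), maskRaster(makeNucleusMask(p)))
  expect_error(sceneParams(nucleusSemiaxes = c(45, 20), imageSize = c(80, 80)),
               "margin")
})

test_that("zero photon scale and zero read noise give a probe channel equal to background", {
  p <- sceneParams(photonScale = 0, readNoiseSd = 0, background = 37, seed = 5)
  sc <- renderTerritoryScene(makeNucleusMask(p), p)
  expect_true(all(probeChannel(sc) == 37))
})

test_that("territory ground truth hits requested radial extremes (brute-force radius oracle)", {
  pC <- sceneParams(territoryRadialMu = 0, territoryRadialSigma = 0.02,
                    territoryAreaFraction = 0.02, seed = 3)
  mC <- makeNucleusMask(pC)
  scC <- renderTerritoryScene(mC, pC)
  rOracle <- bruteNormalizedRadius(maskRaster(mC))
  expect_equal(meanRadius(scC), mean(rOracle[territoryTruth(scC)]), tolerance = 1e-12)
  expect_lt(meanRadius(scC), 0.2)

  pP <- sceneParams(territoryRadialMu = 0.95, territoryRadialSigma = 0.02,
                    territoryAreaFraction = 0.02, seed = 3)
  scP <- renderTerritoryScene(makeNucleusMask(pP), pP)
  expect_equal(meanRadius(scP), mean(rOracle[territoryTruth(scP)]), tolerance = 1e-12)
  expect_gt(meanRadius(scP), 0.8)
})

test_that("ground truth is computed pre-noise and invariant to noise parameters", {
  base <- sceneParams(seed = 21)
  noisy <- sceneParams(photonScale = 1000, readNoiseSd = 50, seed = 21)
  m <- makeNucleusMask(base)
  s1 <- renderTerritoryScene(m, base)
  s2 <- renderTerritoryScene(m, noisy)
  expect_identical(territoryTruth(s1), territoryTruth(s2))
  expect_identical(meanRadius(s1), meanRadius(s2))
})

test_that("seeded scene rendering is bit-identical", {
  p <- sceneParams(seed = 9)
  m <- makeNucleusMask(p)
  expect_identical(probeChannel(renderTerritoryScene(m, p)),
                   probeChannel(renderTerritoryScene(m, p)))
})

test_that("increasing territoryRadialMu strictly increases mean ground-truth radius", {
  mus <- seq(0.1, 0.9, by = 0.2)
  means <- vapply(seq_along(mus), function(i) {
    p <- sceneParams(territoryRadialMu = mus[i], territoryRadialSigma = 0.02,
                     seed = 1)
    mean(simulateTerritoryCohort(12, p, seed = 50 + i)$truth)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
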