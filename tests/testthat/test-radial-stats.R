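test_that("two-way ANOVA output is well-formed and needs two groups of >= 2 nuclei", {
  set.seed(1)
  mat <- matrix(runif(100), 10, 10)
  groups <- rep(c("a", "b"), each = 5)
  cmp <- compareRadialDistributions(mat, groups)
  at <- anovaTable(cmp)
  expect_setequal(at$term, c("group", "bin", "group:bin"))
  expect_true(all(at$p >= 0 & at$p <= 1))
  expect_identical(at$df[at$term == "bin"], 9)
  pb <- perBinStats(cmp)
  expect_identical(nrow(pb), 10L)
  expect_true(all(pb$p_adj >= pb$p - 1e-12))
  expect_error(compareRadialDistributions(mat, rep("a", 10)), "two groups")
  expect_error(compareRadialDistributions(mat[1:3, ], c("a", "b", "b")),
               "at least 2")
})

test_that("jointly permuting group labels leaves the bin main effect unchanged", {
  set.seed(7)
  mat <- matrix(runif(120), 12, 10)
  g <- rep(c("a", "b"), each = 6)
  f1 <- anovaTable(compareRadialDistributions(mat, g))
  gSwap <- ifelse(g == "a", "b", "a")
  f2 <- anovaTable(compareRadialDistributions(mat, gSwap))
  expect_equal(f1$F[f1$term == "bin"], f2$F[f2$term == "bin"], tolerance = 1e-10)
  expect_equal(f1$F[f1$term == "group"], f2$F[f2$term == "group"],
               tolerance = 1e-10)
})

test_that("distinct radial positions are detected as a group:bin interaction", {
  p1 <- sceneParams(territoryRadialMu = 0.4, seed = 1)
  p2 <- sceneParams(territoryRadialMu = 0.7, seed = 1)
  a <- simulateTerritoryCohort(12, p1, seed = 11, groupLabel = "ctrl")
  b <- simulateTerritoryCohort(12, p2, seed = 12, groupLabel = "mut")
  pm <- normalizeProfiles(c(a$profiles, b$profiles))
  cmp <- compareRadialDistributions(pm)
  at <- anovaTable(cmp)
  expect_lt(at$p[at$term == "group:bin"], 0.001)
})
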