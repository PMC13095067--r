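test_that("zero base probability simulates no true DEGs, and seeds reproduce", {
  p <- degSimParams(baseDegProb = 0, seed = 4)
  tab <- simulateDEGTable(p)
  expect_identical(sum(tab$is_deg_true), 0L)
  p2 <- degSimParams(seed = 9)
  expect_identical(simulateDEGTable(p2), simulateDEGTable(p2))
})

test_that("chromosome enrichment multiplier matches its binomial expectation", {
  fracs <- vapply(1:120, function(s) {
    p <- degSimParams(genesPerChromosome = setNames(rep(500L, 4),
                                                    c("1", "2", "3", "4")),
                      baseDegProb = 0.02,
                      enrichedChromosomes = c("1" = 5), seed = s)
    tab <- simulateDEGTable(p)
    mean(tab$is_deg_true[tab$chromosome == "1"])
  }, numeric(1))
  # 120 x 500 Bernoulli(0.10) draws: SE of the grand mean ~ 0.0012
  expect_lt(abs(mean(fracs) - 0.10), 4 * sqrt(0.1 * 0.9 / (120 * 500)))
})

test_that("true DEGs clear the published thresholds at the configured distribution rates", {
  p <- degSimParams(seed = 31)
  tab <- simulateDEGTable(p)
  degs <- filterDEGs(tab)
  recall <- mean(tab$gene_id[tab$is_deg_true] %in% degs$gene_id)
  # expected recall = P(Beta(1,19) < .05) * P(|lfc| > .5) under the alt model
  pPadj <- pbeta(0.05, 1, 19)
  pLfc <- 1 - (pnorm(0.5, 1.5, 0.4) - pnorm(-0.5, 1.5, 0.4))
  expect_lt(abs(recall - pPadj * pLfc), 0.08)
})
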