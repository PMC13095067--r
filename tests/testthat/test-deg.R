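toyTable <- function() {
  data.frame(gene_id = paste0("g", 1:4),
             chromosome = c("1", "1", "2", "3"),
             log2fc = c(1.2, 1.2, 0.1, -0.8),
             padj = c(0.01, 0.20, 0.01, 0.01),
             stringsAsFactors = FALSE)
}

test_that("DEG filtering applies strict padj and |log2FC| thresholds", {
  out <- filterDEGs(toyTable())
  expect_setequal(out$gene_id, c("g1", "g4"))
  expect_equal(unname(attr(out, "thresholds")), c(0.05, 0.5))
  empty <- filterDEGs(toyTable()[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("rows with missing statistics are rejected and counted", {
  tab <- toyTable()
  tab$padj[2] <- NA
  out <- filterDEGs(tab)
  expect_identical(attr(out, "rejected"), 1L)
  expect_setequal(out$gene_id, c("g1", "g4"))
})

test_that("filtering is idempotent and monotone in its thresholds", {
  tab <- simulateDEGTable(degSimParams(seed = 6))
  once <- filterDEGs(tab)
  twice <- filterDEGs(once)
  expect_equal(once$gene_id, twice$gene_id)
  n0 <- nrow(filterDEGs(tab, padjMax = 0.05, lfcMin = 0.5))
  expect_gte(nrow(filterDEGs(tab, padjMax = 0.10, lfcMin = 0.5)), n0)
  expect_gte(nrow(filterDEGs(tab, padjMax = 0.05, lfcMin = 0.25)), n0)
})

test_that("chromosome summaries count, percentage and conserve DEGs", {
  tab <- data.frame(gene_id = paste0("g", 1:30),
                    chromosome = rep(c("1", "2", "X"), each = 10),
                    log2fc = rep(c(2, 0, 2), 10),
                    padj = rep(c(0.001, 0.5, 0.001), 10),
                    is_ecm = rep(c(TRUE, FALSE), 15))
  degs <- filterDEGs(tab)
  s <- summarizeByChromosome(degs, tab)
  expect_identical(sum(s$n_deg), nrow(degs))
  expect_true(all(s$deg_percent >= 0 & s$deg_percent <= 100))
  chr1 <- s[s$chromosome == "1", ]
  expect_equal(chr1$deg_percent, 100 * chr1$n_deg / 10)
  # absent chromosomes are absent, not zero-divided
  expect_false("21" %in% s$chromosome)
  expect_error(summarizeByChromosome(data.frame(gene_id = "zz",
                                                chromosome = "1"), tab),
               "absent")
})

test_that("a chromosome at exactly the genome-wide DEG rate has p = 1", {
  tab <- data.frame(gene_id = paste0("g", 1:1000),
                    chromosome = rep(c("1", "2"), c(100, 900)),
                    log2fc = 2,
                    padj = c(rep(0.001, 10), rep(0.9, 90),
                             rep(0.001, 90), rep(0.9, 810)))
  s <- enrichmentTest(summarizeByChromosome(filterDEGs(tab), tab))
  expect_equal(s$p, c(1, 1))
})

test_that("an enriched chromosome ranks top and reaches significance", {
  hits <- vapply(1:25, function(s) {
    p <- degSimParams(enrichedChromosomes = c("7" = 5), seed = 100 + s)
    tab <- simulateDEGTable(p)
    summ <- enrichmentTest(summarizeByChromosome(filterDEGs(tab), tab))
    top <- summ$chromosome[which.max(summ$deg_percent)]
    top == "7" && summ$p_adj[summ$chromosome == "7"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("DESeq2-style tables are mapped onto canonical columns", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("a", "b"), seqnames = c("chr1", "chrX"),
                         log2FoldChange = c(1, -2), padj = c(0.01, 0.2)),
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  tab <- readDEGTable(f)
  expect_setequal(names(tab), c("gene_id", "chromosome", "log2fc", "padj"))
  expect_setequal(tab$chromosome, c("1", "X"))
})
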