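#' Filter a differential-expression table to DEGs
#'
#' Keeps genes with adjusted p strictly below `padjMax` and absolute log2
#' fold-change strictly above `lfcMin` (both directions).  Rows with missing
#' `padj` or `log2fc` are dropped before filtering; their count is reported
#' in the `rejected` attribute.  The thresholds used are echoed in the
#' `thresholds` attribute.
#'
#' @param table data.frame with at least `gene_id`, `chromosome`, `log2fc`,
#'   `padj` (see [readDEGTable()] for DESeq2-style column mapping).
#' @param padjMax adjusted-p threshold (default 0.05).
#' @param lfcMin absolute log2 fold-change threshold (default 0.5).
#' @return The DEG subset (same columns), with attributes `thresholds` and
#'   `rejected`.
#' @examples
#' tab <- simulateDEGTable(degSimParams())
#' nrow(filterDEGs(tab))
#' @export
filterDEGs <- function(table, padjMax = 0.05, lfcMin = 0.5) {
  .checkDEGTable(table)
  ok <- !is.na(table$padj) & !is.na(table$log2fc)
  rejected <- sum(!ok)
  tab <- table[ok, , drop = FALSE]
  out <- tab[tab$padj < padjMax & abs(tab$log2fc) > lfcMin, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(padj_max = padjMax, lfc_min = lfcMin)
  attr(out, "rejected") <- rejected
  out
}

.checkDEGTable <- function(table) {
  need <- c("gene_id", "chromosome", "log2fc", "padj")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("DEG table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$gene_id))
    stop("gene_id values must be unique")
  bad <- !is.na(table$padj) & (table$padj < 0 | table$padj > 1)
  if (any(bad)) stop("padj values outside [0, 1]")
  allowed <- c(as.character(1:22), "X", "Y")
  if (!all(table$chromosome %in% allowed))
    stop("chromosome labels must be in 1..22, X, Y")
  invisible(TRUE)
}

#' Per-chromosome DEG counts and percentages
#'
#' Tallies, for every chromosome present in the full table, the number of
#' genes, the number of DEGs, the DEG percentage relative to that
#' chromosome's gene count, the DEG share relative to all DEGs, and the
#' number of ECM-flagged DEGs (when the table carries an `is_ecm` column).
#' Chromosomes with no genes in the table are absent from the output, never
#' zero-divided.
#'
#' @param degs DEG subset from [filterDEGs()]; every gene must be present in
#'   `table`.
#' @param table the full DEG table the subset came from.
#' @return data.frame with one row per chromosome: `chromosome`, `n_genes`,
#'   `n_deg`, `deg_percent`, `share_of_degs`, `n_ecm_deg`.
#' @export
summarizeByChromosome <- function(degs, table) {
  .checkDEGTable(table)
  if (!all(degs$gene_id %in% table$gene_id))
    stop("DEG subset contains genes absent from the full table")
  chromLevels <- c(as.character(1:22), "X", "Y")
  present <- chromLevels[chromLevels %in% unique(table$chromosome)]
  nGenes <- table(factor(table$chromosome, levels = present))
  nDeg <- table(factor(degs$chromosome, levels = present))
  totalDeg <- nrow(degs)
  ecm <- if ("is_ecm" %in% names(degs))
    tapply(degs$is_ecm, factor(degs$chromosome, levels = present),
           function(v) sum(v, na.rm = TRUE))
  else rep(NA_integer_, length(present))
  ecm[is.na(ecm) & nDeg == 0 & "is_ecm" %in% names(degs)] <- 0L
  out <- data.frame(
    chromosome = present,
    n_genes = as.integer(nGenes),
    n_deg = as.integer(nDeg),
    deg_percent = 100 * as.integer(nDeg) / as.integer(nGenes),
    share_of_degs = if (totalDeg > 0) 100 * as.integer(nDeg) / totalDeg else 0,
    n_ecm_deg = as.integer(ecm),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-chromosome DEG enrichment test
#'
#' Exact two-sided binomial test of each chromosome's DEG fraction against
#' the genome-wide DEG fraction, with Benjamini-Hochberg adjustment across
#' chromosomes.  A chromosome whose DEG count sits at the binomial mode for
#' the genome-wide rate yields p = 1.
#'
#' @param summary per-chromosome summary from [summarizeByChromosome()].
#' @param adjust p-value adjustment method (see [stats::p.adjust()]).
#' @return `summary` with added `p` and `p_adj` columns.
#' @export
enrichmentTest <- function(summary, adjust = "BH") {
  need <- c("chromosome", "n_genes", "n_deg")
  if (!all(need %in% names(summary)))
    stop("summary lacks columns: ", paste(setdiff(need, names(summary)), collapse = ", "))
  totGenes <- sum(summary$n_genes)
  totDeg <- sum(summary$n_deg)
  if (totGenes == 0) stop("summary has no genes")
  p0 <- totDeg / totGenes
  summary$p <- vapply(seq_len(nrow(summary)), function(i) {
    if (p0 == 0 || p0 == 1)
      return(1)
    binom.test(summary$n_deg[i], summary$n_genes[i], p = p0,
               alternative = "two.sided")$p.value
  }, numeric(1))
  summary$p_adj <- p.adjust(summary$p, method = adjust)
  summary
}
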