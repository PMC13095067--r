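#' Construct DEG-table simulation parameters
#'
#' Ground-truth model behind the synthetic differential-expression tables:
#' each gene is truly differentially expressed with a per-chromosome
#' probability (baseline times an optional enrichment multiplier).  True
#' DEGs draw |log2FC| from Normal(`effectSizeMu`, `effectSizeSd`) with a
#' random sign and adjusted p from Beta(`altPadjShape1`, `altPadjShape2`);
#' null genes draw log2FC from Normal(0, `nullLfcSd`) and adjusted p from
#' Uniform(0, 1).  ECM flags are drawn with `ecmFraction` among true DEGs
#' and `ecmBackground` otherwise.
#'
#' @param genesPerChromosome named integer vector (chromosomes "1".."22","X").
#' @param baseDegProb baseline DEG probability.
#' @param enrichedChromosomes named multipliers >= 1, e.g. `c("1" = 5)`.
#' @param effectSizeMu,effectSizeSd true-DEG |log2FC| distribution.
#' @param altPadjShape1,altPadjShape2 Beta parameters for true-DEG padj.
#' @param nullLfcSd null log2FC SD.
#' @param ecmFraction,ecmBackground ECM-flag probabilities.
#' @param seed integer seed.
#' @return A validated [DEGSimParams-class].
#' @export
degSimParams <- function(genesPerChromosome = setNames(rep(1000L, 23),
                                                       c(as.character(1:22), "X")),
                         baseDegProb = 0.02,
                         enrichedChromosomes = numeric(),
                         effectSizeMu = 1.5, effectSizeSd = 0.4,
                         altPadjShape1 = 1, altPadjShape2 = 19,
                         nullLfcSd = 0.2,
                         ecmFraction = 0.3, ecmBackground = 0.02,
                         seed = 1L) {
  new("DEGSimParams",
      genesPerChromosome = setNames(as.integer(genesPerChromosome),
                                    names(genesPerChromosome)),
      baseDegProb = baseDegProb,
      enrichedChromosomes = enrichedChromosomes,
      effectSizeMu = effectSizeMu, effectSizeSd = effectSizeSd,
      altPadjShape1 = altPadjShape1, altPadjShape2 = altPadjShape2,
      nullLfcSd = nullLfcSd,
      ecmFraction = ecmFraction, ecmBackground = ecmBackground,
      seed = as.integer(seed))
}

#' Simulate a differential-expression table with ground truth
#'
#' @param params a [DEGSimParams-class].
#' @return data.frame with columns `gene_id`, `chromosome`, `log2fc`,
#'   `padj`, `is_ecm` and the ground-truth flag `is_deg_true`.
#' @examples
#' tab <- simulateDEGTable(degSimParams(enrichedChromosomes = c("1" = 5)))
#' mean(tab$is_deg_true[tab$chromosome == "1"])
#' @export
simulateDEGTable <- function(params) {
  stopifnot(is(params, "DEGSimParams"))
  validObject(params)
  chroms <- names(params@genesPerChromosome)
  counts <- params@genesPerChromosome
  chromosome <- rep(chroms, counts)
  nGenes <- length(chromosome)
  probs <- rep(params@baseDegProb, length(chroms))
  names(probs) <- chroms
  if (length(params@enrichedChromosomes)) {
    hit <- names(params@enrichedChromosomes)
    probs[hit] <- pmin(1, probs[hit] * params@enrichedChromosomes)
  }
  .withStream(params@seed, "deg", {
    isDeg <- runif(nGenes) < probs[chromosome]
    nAlt <- sum(isDeg)
    log2fc <- rnorm(nGenes, 0, params@nullLfcSd)
    padj <- runif(nGenes)
    if (nAlt) {
      log2fc[isDeg] <- sample(c(-1, 1), nAlt, replace = TRUE) *
        rnorm(nAlt, params@effectSizeMu, params@effectSizeSd)
      padj[isDeg] <- rbeta(nAlt, params@altPadjShape1, params@altPadjShape2)
    }
    isEcm <- runif(nGenes) < ifelse(isDeg, params@ecmFraction,
                                    params@ecmBackground)
    data.frame(
      gene_id = sprintf("gene_%05d", seq_len(nGenes)),
      chromosome = chromosome,
      log2fc = log2fc,
      padj = padj,
      is_ecm = isEcm,
      is_deg_true = isDeg,
      stringsAsFactors = FALSE
    )
  })
}
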