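# File readers/writers for the pipeline's on-disk formats: multi-channel
# TIFF scenes, two-column trace CSVs, DESeq2-style DE tables.

#' Write / read a synthetic scene as TIFF
#'
#' The two fluorescence channels and the mask are written as separate
#' 32-bit TIFF files (`<stem>_probe.tif`, `<stem>_counterstain.tif`,
#' `<stem>_mask.tif`); ground truth goes to `<stem>_truth.csv`.
#'
#' @param scene a [TerritoryScene-class].
#' @param stem path stem (directory must exist).
#' @return Invisibly, the vector of files written.
#' @export
writeScene <- function(scene, stem) {
  stopifnot(is(scene, "TerritoryScene"))
  files <- paste0(stem, c("_probe.tif", "_counterstain.tif", "_mask.tif",
                          "_truth.csv"))
  # EBImage writes float TIFFs on [0,1]; rescale by a fixed 16-bit range
  sc <- 65535
  EBImage::writeImage(EBImage::Image(scene@probe / sc), files[1], type = "tiff",
                      bits.per.sample = 32L)
  EBImage::writeImage(EBImage::Image(scene@counterstain / sc), files[2],
                      type = "tiff", bits.per.sample = 32L)
  EBImage::writeImage(EBImage::Image(scene@mask@mask * 1), files[3],
                      type = "tiff", bits.per.sample = 8L)
  write.csv(data.frame(nucleus_id = scene@mask@nucleusID,
                       group = scene@mask@groupLabel,
                       probe = scene@mask@probeID,
                       territory_px = sum(scene@territory),
                       mean_radius = scene@meanRadius,
                       pixel_size = scene@mask@pixelSize),
            files[4], row.names = FALSE)
  invisible(files)
}

#' @rdname writeScene
#' @param channel which channel to read back ("probe" or "counterstain").
#' @return `readSceneChannel` returns the channel as a numeric matrix in
#'   camera counts.
#' @export
readSceneChannel <- function(stem, channel = c("probe", "counterstain")) {
  channel <- match.arg(channel)
  img <- EBImage::readImage(paste0(stem, "_", channel, ".tif"))
  matrix(EBImage::imageData(img), nrow = dim(img)[1]) * 65535
}

#' @rdname writeScene
#' @param pixelSize,nucleusID,groupLabel,probeID metadata for the mask read
#'   back from disk.
#' @return `readSceneMask` returns a [NuclearMask-class].
#' @export
readSceneMask <- function(stem, pixelSize = 0.2, nucleusID = "nucleus",
                          groupLabel = "group", probeID = "probe") {
  img <- EBImage::readImage(paste0(stem, "_mask.tif"))
  raster <- matrix(EBImage::imageData(img) > 0.5, nrow = dim(img)[1])
  new("NuclearMask", mask = raster, pixelSize = pixelSize,
      nucleusID = nucleusID, groupLabel = groupLabel, probeID = probeID)
}

#' Read / write a beat trace as two-column CSV
#'
#' CSV layout: `time_s`, `value`.  Sampling must be uniform; the frame rate
#' is inferred from the time column on read.
#'
#' @param path CSV file.
#' @param modality "displacement" or "calcium_ratio".
#' @param pacingRate pacing rate metadata, Hz.
#' @return A [BeatTrace-class].
#' @export
readBeatTrace <- function(path, modality = "displacement", pacingRate = NA_real_) {
  d <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("trace CSV needs columns time_s, value")
  dt <- diff(d$time_s)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("non-uniform sampling in ", path)
  new("BeatTrace", samples = d$value, frameRate = 1 / dt[1],
      pacingRate = pacingRate, modality = modality)
}

#' @rdname readBeatTrace
#' @param trace a [BeatTrace-class] to write.
#' @export
writeBeatTrace <- function(trace, path) {
  t <- (seq_along(trace@samples) - 1) / trace@frameRate
  write.csv(data.frame(time_s = t, value = trace@samples), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Accepts TSV or CSV (by extension) with DESeq2-style column names mapped
#' onto the package's canonical ones: `log2FoldChange` -> `log2fc`,
#' `padj` stays, `gene`/`gene_name` -> `gene_id`, `chr`/`seqnames` ->
#' `chromosome`.  A "chr" prefix on chromosome labels is stripped.
#'
#' @param path file path.
#' @param mapping named character vector of extra column renames
#'   (new_name = old_name).
#' @return data.frame with canonical columns, validated.
#' @export
readDEGTable <- function(path, mapping = character()) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  std <- c(gene_id = "gene", gene_id = "gene_name", gene_id = "gene_id",
           chromosome = "chr", chromosome = "seqnames",
           chromosome = "chromosome",
           log2fc = "log2FoldChange", log2fc = "log2fc",
           padj = "padj", is_ecm = "is_ecm")
  map <- c(std, mapping)
  for (i in seq_along(map)) {
    old <- map[[i]]; newn <- names(map)[i]
    if (old %in% names(d) && !newn %in% names(d))
      names(d)[names(d) == old] <- newn
  }
  if ("chromosome" %in% names(d))
    d$chromosome <- sub("^chr", "", as.character(d$chromosome))
  .checkDEGTable(d)
  d
}
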