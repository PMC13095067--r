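#' Render a markdown summary report for a pipeline run
#'
#' Collects whatever stage outputs exist under `runDir` into one document:
#' the normalized radial heatmap matrix (plus a PNG heatmap), per-bin group
#' statistics, beat summaries, EC50 fits and per-chromosome DEG tables.
#' Sections whose stage has not run are marked absent.  Regeneration is
#' idempotent: the report carries no timestamps, so rerunning on the same
#' run directory reproduces it byte for byte.
#'
#' @param runDir a pipeline run directory (see [runPipeline()]).
#' @return Character vector of files written (report.md, optional PNG).
#' @export
makeReport <- function(runDir) {
  if (!dir.exists(runDir)) stop("run directory not found: ", runDir)
  lines <- c("# CardioPheno run report", "")
  files <- character()

  fmtTable <- function(d, digits = 3) {
    d[] <- lapply(d, function(col) if (is.numeric(col)) signif(col, digits) else col)
    header <- paste("|", paste(names(d), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|")
    body <- apply(d, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(header, sep, body)
  }

  pmFile <- file.path(runDir, "profile", "profile_matrix.csv")
  lines <- c(lines, "## Radial territory profiling", "")
  if (file.exists(pmFile)) {
    pm <- read.csv(pmFile)
    meta <- jsonlite::read_json(file.path(runDir, "profile", "profile_meta.json"),
                                simplifyVector = TRUE)
    lines <- c(lines,
               sprintf("Probe %s, normalization scope `%s`. Rows are group means of min-max normalized per-bin intensities; bins run center (1) to periphery (10).",
                       meta$probe, meta$scope), "")
    if (isTRUE(meta$degenerate))
      lines <- c(lines,
                 "**WARNING: degenerate normalization (all pooled bin means equal); matrix forced to zero.**",
                 "")
    lines <- c(lines, fmtTable(pm), "")
    png <- file.path(runDir, "profile", "heatmap.png")
    mat <- as.matrix(pm[, -1, drop = FALSE])
    grDevices::png(png, width = 640, height = 200 + 60 * nrow(mat))
    graphics::par(mar = c(4, 8, 2, 1))
    graphics::image(t(mat[rev(seq_len(nrow(mat))), , drop = FALSE]),
                    axes = FALSE, col = grDevices::hcl.colors(64, "viridis"),
                    zlim = c(0, 1), main = "Normalized radial intensity")
    graphics::axis(1, at = seq(0, 1, length.out = ncol(mat)),
                   labels = seq_len(ncol(mat)))
    graphics::axis(2, at = seq(0, 1, length.out = nrow(mat)),
                   labels = rev(pm[[1]]), las = 2)
    grDevices::dev.off()
    files <- c(files, png)
    lines <- c(lines, sprintf("![heatmap](%s)", file.path("profile", "heatmap.png")), "")
  } else lines <- c(lines, "_Stage absent._", "")

  cmpFile <- file.path(runDir, "compare", "per_bin.csv")
  lines <- c(lines, "## Group comparison (two-way ANOVA)", "")
  if (file.exists(cmpFile)) {
    lines <- c(lines, fmtTable(read.csv(file.path(runDir, "compare", "anova.csv"))),
               "", fmtTable(read.csv(cmpFile)), "")
  } else lines <- c(lines, "_Stage absent._", "")

  beatFile <- file.path(runDir, "beats", "trace_summaries.csv")
  lines <- c(lines, "## Contraction metrics", "")
  if (file.exists(beatFile)) {
    lines <- c(lines, fmtTable(read.csv(beatFile)), "")
  } else lines <- c(lines, "_Stage absent._", "")

  ecFile <- file.path(runDir, "calcium", "ec50_fits.json")
  lines <- c(lines, "## Calcium sensitivity (Hill fits)", "")
  if (file.exists(ecFile)) {
    fits <- jsonlite::read_json(ecFile, simplifyVector = TRUE)
    lines <- c(lines, fmtTable(as.data.frame(fits)), "")
  } else lines <- c(lines, "_Stage absent._", "")

  degFiles <- Sys.glob(file.path(runDir, "degs", "chromosome_summary_*.csv"))
  lines <- c(lines, "## DEGs per chromosome", "")
  if (length(degFiles)) {
    for (f in sort(degFiles)) {
      lines <- c(lines, sprintf("### Table %s", sub("^chromosome_summary_|\\.csv$", "", basename(f))),
                 "", fmtTable(read.csv(f)), "")
    }
  } else lines <- c(lines, "_Stage absent._", "")

  rpt <- file.path(runDir, "report.md")
  writeLines(lines, rpt)
  c(rpt, files)
}
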