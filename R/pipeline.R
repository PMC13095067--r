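#' Default pipeline run configuration
#'
#' One nested list drives the whole synthetic end-to-end analysis; it
#' round-trips losslessly through JSON ([writeRunConfig()] /
#' [readRunConfig()]).  Stage sections: `scene` (cohort sizes and
#' scene parameters per group), `trace` and `calcium` (beat/calcium
#' simulation and analysis settings), `deg` (DE-table simulation and
#' thresholds), `binning`, `normalization` and `beats` (analysis options).
#'
#' @param seed integer master seed for every stage.
#' @param nPerGroup nuclei per group for the painting arm.
#' @param tracesPerGroup traces per group for the contraction arm.
#' @return Named list (class "cardioPhenoConfig").
#' @export
defaultRunConfig <- function(seed = 1L, nPerGroup = 30L, tracesPerGroup = 6L) {
  cfg <- list(
    version = as.character(utils::packageVersion("CardioPheno")),
    seed = as.integer(seed),
    stages = c("simulate", "profile", "beats", "calcium", "degs",
               "compare", "report"),
    scene = list(
      n_per_group = as.integer(nPerGroup),
      groups = c("mutant", "control"),
      radial_mu = c(mutant = 0.7, control = 0.5),
      radial_sigma = 0.08,
      area_fraction = 0.08,
      semiaxes = c(30, 22),
      image_size = c(80, 80),
      photon_scale = 200, read_noise_sd = 5, background = 100,
      pixel_size = 0.2, probe = "chr1"
    ),
    trace = list(
      n_per_group = as.integer(tracesPerGroup),
      groups = c("mutant", "control"),
      amplitude_mu = c(mutant = 0.6, control = 1.0),
      amplitude_cv = c(mutant = 0.25, control = 0.10),
      rise_time = c(mutant = 0.28, control = 0.20),
      decay_time = c(mutant = 0.20, control = 0.15),
      frame_rate = 63, duration = 25, pacing_rate = 1,
      timing_jitter_sd = 0.01, noise_sd = 0.02
    ),
    calcium = list(
      ec50 = c(mutant = 1.1, control = 0.8),
      hill = 2, fmax = 1,
      concentrations = seq(0.3, 3.0, by = 0.3),
      noise_sd = 0.03
    ),
    deg = list(
      n_tables = 2L,
      genes_per_chromosome = 1000L,
      base_deg_prob = 0.02,
      enriched = c("1" = 5, "2" = 3, "3" = 2.5, "4" = 2.5),
      padj_max = 0.05, lfc_min = 0.5
    ),
    binning = list(n_bins = 10L, mode = "equal_width"),
    normalization = list(scope = "global"),
    beats = list(onset_fraction = 0.1, min_prominence = 0.3)
  )
  class(cfg) <- c("cardioPhenoConfig", "list")
  cfg
}

.knownConfigKeys <- c("version", "seed", "stages", "scene", "trace",
                      "calcium", "deg", "binning", "normalization", "beats")

.validateConfig <- function(config) {
  unknown <- setdiff(names(config), .knownConfigKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.numeric(config$seed)) stop("config$seed must be an integer")
  bad <- setdiff(config$stages,
                 c("simulate", "profile", "beats", "calcium", "degs",
                   "compare", "report"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @rdname defaultRunConfig
#' @param config a run configuration list.
#' @param path JSON file path.
#' @export
writeRunConfig <- function(config, path) {
  .validateConfig(config)
  # named atomic vectors must become JSON objects, not bare arrays,
  # or the per-group names would be lost in the round trip
  keepNames <- function(x) {
    if (is.list(x)) lapply(x, keepNames)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(keepNames(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (sec in c("scene", "trace", "calcium")) {
    for (f in names(cfg[[sec]])) {
      v <- cfg[[sec]][[f]]
      if (is.list(v)) cfg[[sec]][[f]] <- unlist(v)
    }
  }
  if (!is.null(cfg$deg$enriched)) cfg$deg$enriched <- unlist(cfg$deg$enriched)
  .validateConfig(cfg)
  class(cfg) <- c("cardioPhenoConfig", "list")
  cfg
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order inside `outDir`:
#' `simulate` writes seeded synthetic scenes (TIFF), traces (CSV),
#' calcium-response curves (CSV) and DE tables (TSV); `profile` bins the
#' scene masks and quantifies per-bin probe intensity plus nuclear shape;
#' `beats` and `calcium` compute contraction and calcium metrics and the
#' Hill EC50 fits; `degs` applies the DEG thresholds and summarizes per
#' chromosome; `compare` runs the two-way ANOVA on normalized profiles;
#' `report` renders a markdown summary.  A manifest (JSON) records the
#' config, seed, per-stage output files with MD5 digests, and
#' machine-readable warnings; rerunning with an identical config gives
#' bit-identical data outputs.
#'
#' @param config run configuration (see [defaultRunConfig()]), or a path to
#'   a JSON config.
#' @param outDir run directory, created if absent.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  .validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, started = format(Sys.time()),
                   stages = list(), warnings = list())
  order <- c("simulate", "profile", "beats", "calcium", "degs", "compare",
             "report")
  stages <- order[order %in% config$stages]
  for (st in stages) {
    res <- switch(st,
      simulate = .stageSimulate(config, outDir),
      profile = .stageProfile(config, outDir),
      beats = .stageBeats(config, outDir),
      calcium = .stageCalcium(config, outDir),
      degs = .stageDegs(config, outDir),
      compare = .stageCompare(config, outDir),
      report = list(files = makeReport(outDir), warnings = character()))
    files <- res$files
    manifest$stages[[st]] <- list(
      files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
    if (length(res$warnings)) manifest$warnings[[st]] <- res$warnings
    message("[CardioPheno] stage '", st, "': ", length(files), " file(s)")
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.sceneParamsFor <- function(sc, group, i, seed) {
  sceneParams(nucleusSemiaxes = sc$semiaxes, imageSize = sc$image_size,
              territoryRadialMu = sc$radial_mu[[group]],
              territoryRadialSigma = sc$radial_sigma,
              territoryAreaFraction = sc$area_fraction,
              photonScale = sc$photon_scale, readNoiseSd = sc$read_noise_sd,
              background = sc$background, pixelSize = sc$pixel_size,
              seed = (seed * 1000 + match(group, sc$groups) * 500 + i) %% 2147483647)
}

.stageSimulate <- function(config, outDir) {
  files <- character(); warns <- character()
  sc <- config$scene
  sceneDir <- file.path(outDir, "sim", "scenes")
  dir.create(sceneDir, showWarnings = FALSE, recursive = TRUE)
  for (g in sc$groups) {
    for (i in seq_len(sc$n_per_group)) {
      p <- .sceneParamsFor(sc, g, i, config$seed)
      mk <- makeNucleusMask(p, nucleusID = sprintf("%s_n%03d", g, i),
                            groupLabel = g, probeID = sc$probe)
      scene <- renderTerritoryScene(mk, p)
      files <- c(files, writeScene(scene, file.path(sceneDir,
                                                    sprintf("%s_n%03d", g, i))))
    }
  }
  tr <- config$trace
  traceDir <- file.path(outDir, "sim", "traces")
  dir.create(traceDir, showWarnings = FALSE, recursive = TRUE)
  for (g in tr$groups) {
    for (i in seq_len(tr$n_per_group)) {
      tp <- traceParams(frameRate = tr$frame_rate, duration = tr$duration,
                        pacingRate = tr$pacing_rate,
                        amplitudeMu = tr$amplitude_mu[[g]],
                        amplitudeCv = tr$amplitude_cv[[g]],
                        riseTime = tr$rise_time[[g]],
                        decayTime = tr$decay_time[[g]],
                        timingJitterSd = tr$timing_jitter_sd,
                        noiseSd = tr$noise_sd,
                        seed = (config$seed * 2000 + match(g, tr$groups) * 100 + i) %% 2147483647)
      sim <- simulateBeatTrace(tp)
      if (sim$overlap) warns <- c(warns, sprintf("overlapping beats in %s trace %d", g, i))
      f <- file.path(traceDir, sprintf("%s_t%02d.csv", g, i))
      writeBeatTrace(sim$trace, f)
      ft <- file.path(traceDir, sprintf("%s_t%02d_truth.csv", g, i))
      write.csv(sim$truth, ft, row.names = FALSE)
      files <- c(files, f, ft)
    }
  }
  ca <- config$calcium
  caDir <- file.path(outDir, "sim", "calcium")
  dir.create(caDir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(ca$ec50)) {
    d <- simulateCalciumResponse(ca$ec50[[g]], ca$hill, ca$fmax,
                                 ca$concentrations, ca$noise_sd,
                                 seed = (config$seed * 3000 + match(g, names(ca$ec50))) %% 2147483647)
    f <- file.path(caDir, paste0(g, "_response.csv"))
    write.csv(d, f, row.names = FALSE)
    files <- c(files, f)
  }
  dg <- config$deg
  degDir <- file.path(outDir, "sim", "deg")
  dir.create(degDir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(dg$n_tables)) {
    dp <- degSimParams(
      genesPerChromosome = setNames(rep(as.integer(dg$genes_per_chromosome), 23),
                                    c(as.character(1:22), "X")),
      baseDegProb = dg$base_deg_prob,
      enrichedChromosomes = dg$enriched,
      seed = (config$seed * 4000 + k) %% 2147483647)
    tab <- simulateDEGTable(dp)
    f <- file.path(degDir, sprintf("deg_table_%d.tsv", k))
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  list(files = files, warnings = warns)
}

.stageProfile <- function(config, outDir) {
  sceneDir <- file.path(outDir, "sim", "scenes")
  masks <- Sys.glob(file.path(sceneDir, "*_mask.tif"))
  if (!length(masks))
    stop("no scene masks found under ", sceneDir,
         "; run the 'simulate' stage first (or point the run directory ",
         "at one that contains its output)")
  sc <- config$scene
  profDir <- file.path(outDir, "profile")
  dir.create(profDir, showWarnings = FALSE, recursive = TRUE)
  profiles <- list(); shapes <- list()
  binmapCache <- NULL
  for (mf in sort(masks)) {
    stem <- sub("_mask\\.tif$", "", mf)
    id <- basename(stem)
    g <- sub("_n[0-9]+$", "", id)
    mk <- readSceneMask(stem, pixelSize = sc$pixel_size, nucleusID = id,
                        groupLabel = g, probeID = sc$probe)
    if (is.null(binmapCache) ||
        !identical(dim(binmapCache@bins), dim(mk@mask)) ||
        !identical(binmapCache@bins > 0L, unname(mk@mask))) {
      binmapCache <- computeDistanceBins(mk, nBins = config$binning$n_bins,
                                         mode = config$binning$mode)
    }
    img <- readSceneChannel(stem, "probe")
    profiles[[id]] <- profileIntensity(img, binmapCache, nucleusID = id,
                                       groupLabel = g, probeID = sc$probe)
    shapes[[id]] <- cbind(nucleus_id = id, group = g, shapeDescriptors(mk))
  }
  pm <- normalizeProfiles(profiles, scope = config$normalization$scope)
  warns <- if (pm@degenerate) "degenerate normalization: max == min" else character()
  longRows <- lapply(profiles, function(p) data.frame(
    nucleus_id = p@nucleusID, group = p@groupLabel, probe = p@probeID,
    bin = seq_along(p@meanIntensity), mean_intensity = p@meanIntensity,
    pixel_count = p@pixelCount))
  f1 <- file.path(profDir, "profiles.csv")
  write.csv(do.call(rbind, longRows), f1, row.names = FALSE)
  f2 <- file.path(profDir, "profile_matrix.csv")
  write.csv(data.frame(group = rownames(pm@groupMeans), pm@groupMeans), f2,
            row.names = FALSE)
  f3 <- file.path(profDir, "normalized_profiles.csv")
  write.csv(cbind(pm@meta, pm@normalized), f3, row.names = FALSE)
  f4 <- file.path(profDir, "shape_descriptors.csv")
  write.csv(do.call(rbind, shapes), f4, row.names = FALSE)
  f5 <- file.path(profDir, "profile_meta.json")
  perip <- vapply(profiles, peripheralityIndex, numeric(1))
  jsonlite::write_json(list(degenerate = pm@degenerate,
                            scope = pm@scope, probe = pm@probeID,
                            peripherality = as.list(perip)),
                       f5, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = c(f1, f2, f3, f4, f5), warnings = warns)
}

.stageBeats <- function(config, outDir) {
  traceDir <- file.path(outDir, "sim", "traces")
  tf <- setdiff(Sys.glob(file.path(traceDir, "*_t[0-9][0-9].csv")), character())
  if (!length(tf))
    stop("no trace CSVs found under ", traceDir, "; run the 'simulate' stage first")
  beatDir <- file.path(outDir, "beats")
  dir.create(beatDir, showWarnings = FALSE, recursive = TRUE)
  allBeats <- list(); summaries <- list()
  for (f in sort(tf)) {
    id <- sub("\\.csv$", "", basename(f))
    tr <- readBeatTrace(f, pacingRate = config$trace$pacing_rate)
    beats <- detectBeats(tr, minProminence = config$beats$min_prominence,
                         onsetFraction = config$beats$onset_fraction)
    if (nrow(beats)) allBeats[[id]] <- cbind(trace = id, beats)
    summaries[[id]] <- cbind(trace = id, group = sub("_t[0-9]+$", "", id),
                             summarizeTrace(beats),
                             onset_fraction = config$beats$onset_fraction)
  }
  f1 <- file.path(beatDir, "beats.csv")
  write.csv(do.call(rbind, allBeats), f1, row.names = FALSE)
  f2 <- file.path(beatDir, "trace_summaries.csv")
  write.csv(do.call(rbind, summaries), f2, row.names = FALSE)
  list(files = c(f1, f2), warnings = character())
}

.stageCalcium <- function(config, outDir) {
  caDir <- file.path(outDir, "sim", "calcium")
  rf <- Sys.glob(file.path(caDir, "*_response.csv"))
  if (!length(rf))
    stop("no calcium response curves under ", caDir, "; run the 'simulate' stage first")
  out <- file.path(outDir, "calcium")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(sort(rf), function(f) {
    d <- read.csv(f)
    fit <- fitCalciumResponse(d$concentration, d$force)
    list(group = sub("_response\\.csv$", "", basename(f)),
         status = fit@status, ec50 = fit@ec50, hill = fit@hill,
         fmax = fit@fmax, residual = fit@residual,
         ec50_in_range = fit@ec50InRange)
  })
  f1 <- file.path(out, "ec50_fits.json")
  jsonlite::write_json(fits, f1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(files = f1, warnings = character())
}

.stageDegs <- function(config, outDir) {
  degDir <- file.path(outDir, "sim", "deg")
  tf <- Sys.glob(file.path(degDir, "deg_table_*.tsv"))
  if (!length(tf))
    stop("no DE tables under ", degDir, "; run the 'simulate' stage first")
  out <- file.path(outDir, "degs")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (f in sort(tf)) {
    k <- sub("^deg_table_|\\.tsv$", "", basename(f))
    tab <- readDEGTable(f)
    degs <- filterDEGs(tab, padjMax = config$deg$padj_max,
                       lfcMin = config$deg$lfc_min)
    summ <- enrichmentTest(summarizeByChromosome(degs, tab))
    fo <- file.path(out, sprintf("chromosome_summary_%s.csv", k))
    write.csv(summ, fo, row.names = FALSE)
    files <- c(files, fo)
  }
  list(files = files, warnings = character())
}

.stageCompare <- function(config, outDir) {
  f <- file.path(outDir, "profile", "normalized_profiles.csv")
  if (!file.exists(f))
    stop("no normalized profiles at ", f, "; run the 'profile' stage first")
  d <- read.csv(f)
  binCols <- grep("^bin", names(d), value = TRUE)
  cmp <- compareRadialDistributions(as.matrix(d[binCols]), groups = d$group)
  out <- file.path(outDir, "compare")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(out, "anova.csv")
  write.csv(cmp@anova, f1, row.names = FALSE)
  f2 <- file.path(out, "per_bin.csv")
  write.csv(cmp@perBin, f2, row.names = FALSE)
  list(files = c(f1, f2), warnings = character())
}
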