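#' @import methods
#' @importFrom stats aov median quantile rnorm rpois rbeta runif sd setNames
#'   binom.test p.adjust t.test approx coef resid cor
#' @importFrom utils write.csv read.csv head
NULL

#' Parameters for synthetic nucleus / territory scenes
#'
#' Holds the geometry, territory-placement and camera-noise parameters used by
#' [makeNucleusMask()] and [renderTerritoryScene()].  Radial position of the
#' territory is controlled on the normalized distance-to-boundary scale
#' (0 = nuclear center, 1 = boundary), the same scale the radial binning
#' operates on, so generated scenes carry an exact radial ground truth.
#'
#' @slot nucleusSemiaxes numeric(2), ellipse semi-axes in pixels.
#' @slot imageSize integer(2), image dimensions in pixels (rows, cols).
#' @slot territoryRadialMu target normalized radius of the territory in [0,1].
#' @slot territoryRadialSigma SD of the sampled target radius.
#' @slot territoryAreaFraction territory area as a fraction of the mask area,
#'   in (0, 0.5].
#' @slot boundaryPerturbAmp amplitude of a smooth (low-order Fourier) radial
#'   boundary perturbation, as a fraction of the local radius; 0 = exact
#'   ellipse.
#' @slot photonScale expected photon counts at full territory signal.
#' @slot readNoiseSd SD of additive Gaussian read noise (counts).
#' @slot background camera offset (counts).
#' @slot pixelSize microns per pixel.
#' @slot seed integer seed; all scene randomness derives from it through
#'   named substreams.
#' @export
setClass("SceneParams", representation(
  nucleusSemiaxes = "numeric",
  imageSize = "integer",
  territoryRadialMu = "numeric",
  territoryRadialSigma = "numeric",
  territoryAreaFraction = "numeric",
  boundaryPerturbAmp = "numeric",
  photonScale = "numeric",
  readNoiseSd = "numeric",
  background = "numeric",
  pixelSize = "numeric",
  seed = "integer"
))

setValidity("SceneParams", function(object) {
  msg <- character()
  a <- object@nucleusSemiaxes
  if (length(a) != 2L || any(!is.finite(a)) || any(a <= 0))
    msg <- c(msg, "nucleusSemiaxes must be two positive numbers")
  sz <- object@imageSize
  if (length(sz) != 2L || any(sz < 8L))
    msg <- c(msg, "imageSize must be two integers >= 8")
  if (length(a) == 2L && length(sz) == 2L &&
      (2 * a[1] + 4 > sz[1] || 2 * a[2] + 4 > sz[2]))
    msg <- c(msg, "semiaxes must fit inside the image with >= 2 px margin")
  mu <- object@territoryRadialMu
  if (!is.finite(mu) || mu < 0 || mu > 1)
    msg <- c(msg, "territoryRadialMu must be in [0, 1]")
  if (object@territoryRadialSigma < 0) msg <- c(msg, "territoryRadialSigma must be >= 0")
  f <- object@territoryAreaFraction
  if (!is.finite(f) || f <= 0 || f > 0.5)
    msg <- c(msg, "territoryAreaFraction must be in (0, 0.5]")
  if (object@boundaryPerturbAmp < 0 || object@boundaryPerturbAmp > 0.3)
    msg <- c(msg, "boundaryPerturbAmp must be in [0, 0.3]")
  for (s in c("photonScale", "readNoiseSd", "background"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be >= 0"))
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Parameters for synthetic paced beat traces
#'
#' @slot frameRate sampling rate, Hz.
#' @slot duration recording length, s.
#' @slot pacingRate electrical pacing rate, Hz.
#' @slot amplitudeMu mean beat amplitude (trace units).
#' @slot amplitudeCv coefficient of variation of per-beat amplitudes.
#' @slot riseTime contraction upstroke duration, s.
#' @slot decayTime relaxation exponential time constant, s.
#' @slot baseline resting level (trace units).
#' @slot timingJitterSd SD of per-beat onset jitter, s.
#' @slot noiseSd SD of additive Gaussian sample noise (trace units).
#' @slot riseShape "linear" or "exponential" upstroke.
#' @slot seed integer seed.
#' @export
setClass("TraceParams", representation(
  frameRate = "numeric", duration = "numeric", pacingRate = "numeric",
  amplitudeMu = "numeric", amplitudeCv = "numeric",
  riseTime = "numeric", decayTime = "numeric", baseline = "numeric",
  timingJitterSd = "numeric", noiseSd = "numeric",
  riseShape = "character", seed = "integer"
))

setValidity("TraceParams", function(object) {
  msg <- character()
  if (object@frameRate <= 0 || object@duration <= 0 || object@pacingRate <= 0)
    msg <- c(msg, "frameRate, duration and pacingRate must be > 0")
  if (object@frameRate / object@pacingRate < 2)
    msg <- c(msg, "need >= 2 samples per beat (frameRate/pacingRate)")
  if (object@pacingRate * object@duration < 3)
    msg <- c(msg, "need >= 3 beats (pacingRate * duration)")
  for (s in c("amplitudeCv", "timingJitterSd", "noiseSd"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be >= 0"))
  if (object@riseTime <= 0 || object@decayTime <= 0)
    msg <- c(msg, "riseTime and decayTime must be > 0")
  if (!object@riseShape %in% c("linear", "exponential"))
    msg <- c(msg, "riseShape must be 'linear' or 'exponential'")
  if (length(msg)) msg else TRUE
})

#' Parameters for synthetic differential-expression tables
#'
#' @slot genesPerChromosome named integer vector over chromosomes
#'   (names "1".."22","X"), genes simulated per chromosome.
#' @slot baseDegProb baseline probability that a gene is truly differentially
#'   expressed.
#' @slot enrichedChromosomes named numeric vector of per-chromosome
#'   multipliers (>= 1) applied to `baseDegProb`.
#' @slot effectSizeMu mean absolute log2 fold-change of true DEGs.
#' @slot effectSizeSd SD of the true-DEG log2 fold-change magnitude.
#' @slot altPadjShape1,altPadjShape2 Beta parameters of the adjusted-p
#'   distribution for true DEGs.
#' @slot nullLfcSd SD of null-gene log2 fold-changes (null adjusted p is
#'   Uniform(0,1)).
#' @slot ecmFraction probability that a true DEG is flagged as
#'   extracellular-matrix related.
#' @slot ecmBackground same probability for non-DEGs.
#' @slot seed integer seed.
#' @export
setClass("DEGSimParams", representation(
  genesPerChromosome = "integer",
  baseDegProb = "numeric",
  enrichedChromosomes = "numeric",
  effectSizeMu = "numeric",
  effectSizeSd = "numeric",
  altPadjShape1 = "numeric",
  altPadjShape2 = "numeric",
  nullLfcSd = "numeric",
  ecmFraction = "numeric",
  ecmBackground = "numeric",
  seed = "integer"
))

setValidity("DEGSimParams", function(object) {
  msg <- character()
  g <- object@genesPerChromosome
  if (is.null(names(g)) || any(g <= 0L)) msg <- c(msg, "genesPerChromosome must be named and > 0")
  if (!all(names(g) %in% c(as.character(1:22), "X", "Y")))
    msg <- c(msg, "chromosome names must be in 1..22, X, Y")
  if (object@baseDegProb < 0 || object@baseDegProb > 1)
    msg <- c(msg, "baseDegProb must be in [0, 1]")
  m <- object@enrichedChromosomes
  if (length(m) && (is.null(names(m)) || any(m < 1)))
    msg <- c(msg, "enrichment multipliers must be named and >= 1")
  for (s in c("ecmFraction", "ecmBackground"))
    if (slot(object, s) < 0 || slot(object, s) > 1)
      msg <- c(msg, paste(s, "must be in [0, 1]"))
  if (object@altPadjShape1 <= 0 || object@altPadjShape2 <= 0)
    msg <- c(msg, "Beta shapes must be > 0")
  if (length(msg)) msg else TRUE
})

#' A binarized nuclear mask
#'
#' A single segmented nucleus: a logical raster with exactly one 4-connected
#' foreground component, plus the physical pixel size and identifiers used
#' downstream (nucleus, experimental group, FISH probe).
#'
#' @slot mask logical matrix; TRUE = nucleus.
#' @slot pixelSize microns per pixel.
#' @slot nucleusID,groupLabel,probeID character identifiers.
#' @export
setClass("NuclearMask", representation(
  mask = "matrix", pixelSize = "numeric",
  nucleusID = "character", groupLabel = "character", probeID = "character"
))

setValidity("NuclearMask", function(object) {
  msg <- character()
  m <- object@mask
  if (!is.logical(m)) msg <- c(msg, "mask must be a logical matrix")
  else if (sum(m) < 1L) msg <- c(msg, "mask has no foreground")
  else if (.nComponents4(m) != 1L)
    msg <- c(msg, "mask must contain exactly one 4-connected component")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Radial bin map of a nuclear mask
#'
#' Integer raster partitioning a mask into concentric bins ordered
#' center (1) to periphery (nBins); 0 marks background.
#'
#' @slot bins integer matrix.
#' @slot nBins number of bins.
#' @slot mode "equal_width" or "equal_area".
#' @export
setClass("RadialBinMap", representation(
  bins = "matrix", nBins = "integer", mode = "character"
))

setValidity("RadialBinMap", function(object) {
  b <- object@bins
  msg <- character()
  if (!is.integer(b)) msg <- c(msg, "bins must be an integer matrix")
  else {
    if (any(b < 0L | b > object@nBins)) msg <- c(msg, "bin indices out of range")
  }
  if (!object@mode %in% c("equal_width", "equal_area"))
    msg <- c(msg, "mode must be 'equal_width' or 'equal_area'")
  if (length(msg)) msg else TRUE
})

#' Per-nucleus radial intensity profile
#'
#' Mean probe fluorescence per radial bin for one nucleus.
#'
#' @slot meanIntensity numeric, one mean per bin (center to periphery).
#' @slot pixelCount integer, pixels per bin; sums to the mask area.
#' @slot nucleusID,groupLabel,probeID character identifiers.
#' @export
setClass("RadialProfile", representation(
  meanIntensity = "numeric", pixelCount = "integer",
  nucleusID = "character", groupLabel = "character", probeID = "character"
))

setValidity("RadialProfile", function(object) {
  msg <- character()
  if (length(object@meanIntensity) != length(object@pixelCount))
    msg <- c(msg, "meanIntensity and pixelCount lengths differ")
  if (any(object@meanIntensity < 0, na.rm = TRUE))
    msg <- c(msg, "meanIntensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Normalized group-by-bin profile matrix
#'
#' Min-max normalized radial profiles pooled over groups for one probe:
#' the group-level heatmap matrix plus the per-nucleus normalized profiles
#' retained for statistics.
#'
#' @slot groupMeans groups x bins matrix of mean normalized intensity.
#' @slot normalized nuclei x bins matrix of per-nucleus normalized profiles.
#' @slot meta data.frame with nucleus_id and group for each row of
#'   `normalized`.
#' @slot probeID probe identifier.
#' @slot scope "global" (one min/max pooled over all bins and nuclei) or
#'   "per_bin" (per-bin min/max over nuclei).
#' @slot degenerate TRUE when max == min and the normalization collapsed to 0.
#' @export
setClass("ProfileMatrix", representation(
  groupMeans = "matrix", normalized = "matrix", meta = "data.frame",
  probeID = "character", scope = "character", degenerate = "logical"
))

#' A sampled contraction or calcium-ratio trace
#'
#' Uniformly sampled displacement (video-edge capture) or ratiometric calcium
#' (405/480 nm emission ratio) recording under electrical pacing.
#'
#' @slot samples numeric vector of trace values.
#' @slot frameRate sampling rate, Hz.
#' @slot pacingRate pacing rate, Hz (metadata; NA when unknown).
#' @slot modality "displacement" or "calcium_ratio".
#' @export
setClass("BeatTrace", representation(
  samples = "numeric", frameRate = "numeric",
  pacingRate = "numeric", modality = "character"
))

setValidity("BeatTrace", function(object) {
  msg <- character()
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (length(object@samples) < 3 * object@frameRate)
    msg <- c(msg, "trace must span at least 3 seconds")
  if (!object@modality %in% c("displacement", "calcium_ratio"))
    msg <- c(msg, "modality must be 'displacement' or 'calcium_ratio'")
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Synthetic two-channel territory scene
#'
#' Output of [renderTerritoryScene()]: the noisy probe and counterstain
#' channels plus the pre-noise ground truth (territory pixel set and its mean
#' normalized radius) the radial profiling stage is expected to recover.
#'
#' @slot probe,counterstain numeric matrices (camera counts).
#' @slot mask the [NuclearMask-class] the scene was rendered on.
#' @slot territory logical matrix of pre-noise territory pixels.
#' @slot meanRadius ground-truth mean normalized radius of the territory.
#' @slot params the [SceneParams-class] used.
#' @export
setClass("TerritoryScene", representation(
  probe = "matrix", counterstain = "matrix", mask = "NuclearMask",
  territory = "matrix", meanRadius = "numeric", params = "SceneParams"
))

#' Two-way ANOVA comparison of radial distributions
#'
#' @slot anova data.frame of ANOVA terms (group, bin, interaction) with
#'   degrees of freedom, F and p.
#' @slot perBin data.frame of per-bin group means, SEM, raw and adjusted p.
#' @slot adjustMethod multiplicity adjustment used for per-bin contrasts.
#' @export
setClass("BinComparisonResult", representation(
  anova = "data.frame", perBin = "data.frame", adjustMethod = "character"
))

#' Hill fit of a force-calcium dose-response curve
#'
#' @slot concentrations external calcium concentrations, mmol/L.
#' @slot force measured force at each concentration (trace units).
#' @slot ec50 fitted half-maximal effective calcium concentration, mmol/L.
#' @slot hill fitted Hill coefficient.
#' @slot fmax fitted maximal force.
#' @slot residual root-mean-square fit residual.
#' @slot status "ok" or "failed".
#' @slot ec50InRange TRUE when the fitted EC50 lies within the measured
#'   concentration range.
#' @export
setClass("CalciumResponseCurve", representation(
  concentrations = "numeric", force = "numeric",
  ec50 = "numeric", hill = "numeric", fmax = "numeric",
  residual = "numeric", status = "character", ec50InRange = "logical"
))
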