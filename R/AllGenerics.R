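#' @name accessors
#' @title Accessors for CardioPheno classes
#' @description Slot accessors for the core data containers.
#' @param object an object of the documented class.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("maskRaster", function(object) standardGeneric("maskRaster"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("nucleusID", function(object) standardGeneric("nucleusID"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("probeID", function(object) standardGeneric("probeID"))
#' @rdname accessors
#' @export
setGeneric("binRaster", function(object) standardGeneric("binRaster"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("binMode", function(object) standardGeneric("binMode"))
#' @rdname accessors
#' @export
setGeneric("meanIntensity", function(object) standardGeneric("meanIntensity"))
#' @rdname accessors
#' @export
setGeneric("pixelCount", function(object) standardGeneric("pixelCount"))
#' @rdname accessors
#' @export
setGeneric("groupMeans", function(object) standardGeneric("groupMeans"))
#' @rdname accessors
#' @export
setGeneric("normalizedProfiles", function(object) standardGeneric("normalizedProfiles"))
#' @rdname accessors
#' @export
setGeneric("profileMeta", function(object) standardGeneric("profileMeta"))
#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(object) standardGeneric("isDegenerate"))
#' @rdname accessors
#' @export
setGeneric("traceSamples", function(object) standardGeneric("traceSamples"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("pacingRate", function(object) standardGeneric("pacingRate"))
#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("territoryTruth", function(object) standardGeneric("territoryTruth"))
#' @rdname accessors
#' @export
setGeneric("probeChannel", function(object) standardGeneric("probeChannel"))
#' @rdname accessors
#' @export
setGeneric("counterstainChannel", function(object) standardGeneric("counterstainChannel"))
#' @rdname accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))
#' @rdname accessors
#' @export
setGeneric("hillCoef", function(object) standardGeneric("hillCoef"))
#' @rdname accessors
#' @export
setGeneric("fmaxEstimate", function(object) standardGeneric("fmaxEstimate"))
#' @rdname accessors
#' @export
setGeneric("fitStatus", function(object) standardGeneric("fitStatus"))
#' @rdname accessors
#' @export
setGeneric("anovaTable", function(object) standardGeneric("anovaTable"))
#' @rdname accessors
#' @export
setGeneric("perBinStats", function(object) standardGeneric("perBinStats"))

setMethod("maskRaster", "NuclearMask", function(object) object@mask)
setMethod("pixelSize", "NuclearMask", function(object) object@pixelSize)
setMethod("nucleusID", "NuclearMask", function(object) object@nucleusID)
setMethod("groupLabel", "NuclearMask", function(object) object@groupLabel)
setMethod("probeID", "NuclearMask", function(object) object@probeID)
setMethod("nucleusID", "RadialProfile", function(object) object@nucleusID)
setMethod("groupLabel", "RadialProfile", function(object) object@groupLabel)
setMethod("probeID", "RadialProfile", function(object) object@probeID)
setMethod("binRaster", "RadialBinMap", function(object) object@bins)
setMethod("nBins", "RadialBinMap", function(object) object@nBins)
setMethod("binMode", "RadialBinMap", function(object) object@mode)
setMethod("meanIntensity", "RadialProfile", function(object) object@meanIntensity)
setMethod("pixelCount", "RadialProfile", function(object) object@pixelCount)
setMethod("groupMeans", "ProfileMatrix", function(object) object@groupMeans)
setMethod("normalizedProfiles", "ProfileMatrix", function(object) object@normalized)
setMethod("profileMeta", "ProfileMatrix", function(object) object@meta)
setMethod("isDegenerate", "ProfileMatrix", function(object) object@degenerate)
setMethod("probeID", "ProfileMatrix", function(object) object@probeID)
setMethod("traceSamples", "BeatTrace", function(object) object@samples)
setMethod("frameRate", "BeatTrace", function(object) object@frameRate)
setMethod("pacingRate", "BeatTrace", function(object) object@pacingRate)
setMethod("modality", "BeatTrace", function(object) object@modality)
setMethod("territoryTruth", "TerritoryScene", function(object) object@territory)
setMethod("probeChannel", "TerritoryScene", function(object) object@probe)
setMethod("counterstainChannel", "TerritoryScene", function(object) object@counterstain)
setMethod("maskRaster", "TerritoryScene", function(object) object@mask@mask)
setMethod("ec50", "CalciumResponseCurve", function(object) object@ec50)
setMethod("hillCoef", "CalciumResponseCurve", function(object) object@hill)
setMethod("fmaxEstimate", "CalciumResponseCurve", function(object) object@fmax)
setMethod("fitStatus", "CalciumResponseCurve", function(object) object@status)
setMethod("anovaTable", "BinComparisonResult", function(object) object@anova)
setMethod("perBinStats", "BinComparisonResult", function(object) object@perBin)

#' Ground-truth mean normalized radius of a synthetic scene
#' @param object a [TerritoryScene-class].
#' @return Numeric scalar in [0, 1].
#' @export
setGeneric("meanRadius", function(object) standardGeneric("meanRadius"))
setMethod("meanRadius", "TerritoryScene", function(object) object@meanRadius)

setMethod("show", "NuclearMask", function(object) {
  cat(sprintf("NuclearMask '%s' (%s, probe %s): %d x %d px, area %d px (%.1f um^2), %.4f um/px\n",
              object@nucleusID, object@groupLabel, object@probeID,
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              sum(object@mask) * object@pixelSize^2, object@pixelSize))
})

setMethod("show", "RadialBinMap", function(object) {
  counts <- tabulate(object@bins[object@bins > 0L], nbins = object@nBins)
  cat(sprintf("RadialBinMap: %d bins (%s), pixel counts: %s\n",
              object@nBins, object@mode, paste(counts, collapse = " ")))
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile '%s' (%s, probe %s), %d bins\n",
              object@nucleusID, object@groupLabel, object@probeID,
              length(object@meanIntensity)))
  print(round(object@meanIntensity, 2))
})

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix probe %s, scope %s, %d nuclei, %d groups%s\n",
              object@probeID, object@scope, nrow(object@normalized),
              nrow(object@groupMeans),
              if (object@degenerate) " [DEGENERATE normalization]" else ""))
  print(round(object@groupMeans, 3))
})

setMethod("show", "BeatTrace", function(object) {
  cat(sprintf("BeatTrace (%s): %d samples @ %.1f Hz (%.1f s), pacing %.2f Hz\n",
              object@modality, length(object@samples), object@frameRate,
              length(object@samples) / object@frameRate, object@pacingRate))
})

setMethod("show", "TerritoryScene", function(object) {
  cat(sprintf("TerritoryScene: %d x %d px, territory %d px, ground-truth mean radius %.3f\n",
              nrow(object@probe), ncol(object@probe), sum(object@territory),
              object@meanRadius))
})

setMethod("show", "CalciumResponseCurve", function(object) {
  if (object@status == "ok")
    cat(sprintf("Hill fit: EC50 %.3f mmol/L%s, h %.2f, Fmax %.3f, RMS residual %.3g\n",
                object@ec50, if (object@ec50InRange) "" else " [outside data range]",
                object@hill, object@fmax, object@residual))
  else cat("Hill fit: FAILED\n")
})

setMethod("show", "BinComparisonResult", function(object) {
  cat("Two-way ANOVA (group x bin):\n")
  print(object@anova)
  cat(sprintf("Per-bin contrasts (%s-adjusted):\n", object@adjustMethod))
  print(object@perBin, digits = 3)
})

#' @rawNamespace exportMethods(show)
NULL
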