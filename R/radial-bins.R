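#' Partition a nuclear mask into concentric radial bins
#'
#' For every foreground pixel, the exact Euclidean distance D to the nearest
#' background pixel is computed (the image border counts as background, on
#' the 4-connected neighborhood) and rescaled to a normalized radius
#' r = 1 - D/Dmax, so the deepest pixel has r = 0 and boundary pixels
#' approach 1.  Bins are numbered center (1) to periphery (`nBins`); with the
#' default 10 bins, bins 1-5 are the nuclear center and 6-10 the periphery.
#'
#' Two binning geometries are supported:
#' \describe{
#'   \item{equal_width}{bin = min(floor(r * nBins) + 1, nBins): rings of
#'     equal normalized radial width (erosion-ring style).}
#'   \item{equal_area}{thresholds are the empirical `nBins`-quantiles of r
#'     over the foreground, so bins hold equal pixel counts up to tie blocks
#'     (pixels with identical r always share a bin).}
#' }
#'
#' @param mask a [NuclearMask-class].
#' @param nBins number of bins (>= 2); default 10.
#' @param mode "equal_width" (default) or "equal_area".
#' @return A [RadialBinMap-class] whose positive pixels exactly partition the
#'   mask foreground.
#' @examples
#' p <- sceneParams(seed = 1)
#' bm <- computeDistanceBins(makeNucleusMask(p))
#' table(binRaster(bm)[binRaster(bm) > 0])
#' @export
computeDistanceBins <- function(mask, nBins = 10L, mode = c("equal_width", "equal_area")) {
  stopifnot(is(mask, "NuclearMask"))
  validObject(mask)
  mode <- match.arg(mode)
  if (!.isCount(nBins) || nBins < 2) stop("nBins must be an integer >= 2")
  nBins <- as.integer(nBins)
  m <- mask@mask
  r <- .normalizedRadiusMap(m)
  bins <- matrix(0L, nrow(m), ncol(m))
  rf <- r[m]
  if (mode == "equal_width") {
    bins[m] <- as.integer(pmin(floor(rf * nBins) + 1, nBins))
  } else {
    # upper thresholds t_k = k-th n-quantile of sorted r; a pixel falls in
    # the first bin whose threshold is >= its r, so tie blocks stay together
    rs <- sort(rf)
    nfg <- length(rs)
    t <- rs[ceiling(seq_len(nBins - 1L) * nfg / nBins)]
    bins[m] <- findInterval(rf, t, left.open = TRUE) + 1L
  }
  new("RadialBinMap", bins = bins, nBins = nBins, mode = mode)
}

#' Mean probe intensity per radial bin
#'
#' @param image numeric matrix of fluorescence intensities, same shape as the
#'   bin map.
#' @param binmap a [RadialBinMap-class].
#' @param nucleusID,groupLabel,probeID identifiers stamped on the profile.
#' @return A [RadialProfile-class]: per-bin mean intensity and pixel count
#'   (counts sum to the mask area).
#' @export
profileIntensity <- function(image, binmap, nucleusID = "nucleus",
                             groupLabel = "group", probeID = "probe") {
  stopifnot(is(binmap, "RadialBinMap"))
  if (!is.matrix(image) || !identical(dim(image), dim(binmap@bins)))
    stop("image and bin map shapes differ")
  b <- binmap@bins
  fg <- b > 0L
  k <- factor(b[fg], levels = seq_len(binmap@nBins))
  means <- as.numeric(tapply(image[fg], k, mean))
  counts <- as.integer(table(k))
  means[is.na(means)] <- 0
  new("RadialProfile", meanIntensity = means, pixelCount = counts,
      nucleusID = nucleusID, groupLabel = groupLabel, probeID = probeID)
}

#' Min-max normalize radial profiles into a heatmap matrix
#'
#' Normalizes per-nucleus bin means with extrema pooled over both groups and
#' all nuclei for a single probe, then averages the normalized profiles per
#' group.  The default ("global") scope takes one minimum and one maximum
#' over every bin mean of every profile, so over the pooled set the minimum
#' maps to 0 and the maximum to 1; "per_bin" uses per-bin extrema instead.
#'
#' @param profiles list of [RadialProfile-class] objects sharing a probe.
#' @param scope "global" (default) or "per_bin".
#' @return A [ProfileMatrix-class].  When all pooled values are equal the
#'   normalization is degenerate: entries are set to 0 and the
#'   `degenerate` flag raised.
#' @export
normalizeProfiles <- function(profiles, scope = c("global", "per_bin")) {
  scope <- match.arg(scope)
  if (!length(profiles)) stop("no profiles supplied")
  stopifnot(all(vapply(profiles, is, TRUE, "RadialProfile")))
  probes <- unique(vapply(profiles, probeID, ""))
  if (length(probes) != 1L)
    stop("all profiles must share one probe (got: ", paste(probes, collapse = ", "), ")")
  raw <- do.call(rbind, lapply(profiles, meanIntensity))
  groups <- vapply(profiles, groupLabel, "")
  ids <- vapply(profiles, nucleusID, "")
  degenerate <- FALSE
  if (scope == "global") {
    lo <- min(raw); hi <- max(raw)
    if (hi == lo) {
      degenerate <- TRUE
      norm <- raw * 0
    } else norm <- (raw - lo) / (hi - lo)
  } else {
    lo <- apply(raw, 2, min); hi <- apply(raw, 2, max)
    span <- hi - lo
    if (all(span == 0)) {
      degenerate <- TRUE
      norm <- raw * 0
    } else {
      span[span == 0] <- 1   # constant bins map to 0
      norm <- sweep(sweep(raw, 2, lo), 2, span, "/")
    }
  }
  colnames(norm) <- paste0("bin", seq_len(ncol(norm)))
  gm <- do.call(rbind, lapply(split(seq_along(groups), groups), function(ix)
    colMeans(norm[ix, , drop = FALSE])))
  new("ProfileMatrix", groupMeans = gm, normalized = norm,
      meta = data.frame(nucleus_id = ids, group = groups,
                        stringsAsFactors = FALSE),
      probeID = probes, scope = scope, degenerate = degenerate)
}

#' Peripherality index of a radial profile
#'
#' Fraction of the binned signal falling in the peripheral half of the bins
#' (bins 6-10 of 10): sum(bins 6..10) / sum(all bins).  0.5 for a uniform
#' profile, 1 for purely peripheral signal.
#'
#' @param profile a [RadialProfile-class] or a nonnegative numeric vector of
#'   even length (one value per bin, center to periphery).
#' @return Numeric scalar in [0, 1].
#' @export
peripheralityIndex <- function(profile) {
  v <- if (is(profile, "RadialProfile")) profile@meanIntensity else profile
  if (!is.numeric(v) || length(v) < 2L || length(v) %% 2L != 0L)
    stop("profile must have an even number of bins")
  if (any(v < 0)) stop("profile values must be nonnegative")
  tot <- sum(v)
  if (tot == 0) stop("peripherality index undefined for an all-zero profile")
  sum(v[(length(v) / 2 + 1):length(v)]) / tot
}
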