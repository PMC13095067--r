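#' Construct scene parameters
#'
#' Defaults emulate the study's imaging setup at desk scale: a single
#' ellipsoidal hiPSC-CM nucleus per field, a painted-chromosome territory
#' occupying a small fraction of the nuclear area at a controlled radial
#' position, and a Poisson + Gaussian camera noise model.
#'
#' @param nucleusSemiaxes ellipse semi-axes in pixels (a, b).
#' @param imageSize image dimensions in pixels.
#' @param territoryRadialMu target normalized radius (0 = center,
#'   1 = boundary).
#' @param territoryRadialSigma SD of the sampled target radius.
#' @param territoryAreaFraction territory area / mask area, in (0, 0.5].
#' @param boundaryPerturbAmp smooth boundary perturbation amplitude
#'   (fraction of radius); 0 gives an exact ellipse.
#' @param photonScale expected photon counts at full signal.
#' @param readNoiseSd Gaussian read-noise SD, counts.
#' @param background camera offset, counts.
#' @param pixelSize microns per pixel.
#' @param seed integer seed.
#' @return A validated [SceneParams-class].
#' @examples
#' p <- sceneParams(seed = 1)
#' m <- makeNucleusMask(p)
#' @export
sceneParams <- function(nucleusSemiaxes = c(30, 22), imageSize = c(80, 80),
                        territoryRadialMu = 0.5, territoryRadialSigma = 0.08,
                        territoryAreaFraction = 0.08,
                        boundaryPerturbAmp = 0,
                        photonScale = 200, readNoiseSd = 5, background = 100,
                        pixelSize = 0.2, seed = 1L) {
  new("SceneParams",
      nucleusSemiaxes = as.numeric(nucleusSemiaxes),
      imageSize = as.integer(imageSize),
      territoryRadialMu = territoryRadialMu,
      territoryRadialSigma = territoryRadialSigma,
      territoryAreaFraction = territoryAreaFraction,
      boundaryPerturbAmp = boundaryPerturbAmp,
      photonScale = photonScale, readNoiseSd = readNoiseSd,
      background = background, pixelSize = pixelSize,
      seed = as.integer(seed))
}

#' Generate an elliptical nuclear mask
#'
#' Rasterizes an ellipse (optionally with a smooth low-order Fourier boundary
#' perturbation) centered in the image.  The result always has a single
#' 4-connected foreground component.
#'
#' @param params a [SceneParams-class].
#' @param nucleusID,groupLabel,probeID identifiers attached to the mask.
#' @return A [NuclearMask-class].
#' @export
makeNucleusMask <- function(params, nucleusID = "nucleus_1",
                            groupLabel = "group", probeID = "probe") {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  nr <- params@imageSize[1]; nc <- params@imageSize[2]
  a <- params@nucleusSemiaxes[1]; b <- params@nucleusSemiaxes[2]
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  x <- matrix(seq_len(nr) - cx, nr, nc)
  y <- matrix(seq_len(nc) - cy, nr, nc, byrow = TRUE)
  # elliptical radius of each pixel; <= 1 is inside the unperturbed ellipse
  rho <- sqrt((x / a)^2 + (y / b)^2)
  if (params@boundaryPerturbAmp > 0) {
    coefs <- .withStream(params@seed, "perturb",
                         rnorm(6, 0, params@boundaryPerturbAmp / sqrt(3)))
    th <- atan2(y / b, x / a)
    pert <- coefs[1] * cos(2 * th) + coefs[2] * sin(2 * th) +
      coefs[3] * cos(3 * th) + coefs[4] * sin(3 * th) +
      coefs[5] * cos(4 * th) + coefs[6] * sin(4 * th)
    pert <- pmax(pmin(pert, 0.3), -0.3)
    mask <- rho <= 1 + pert
  } else {
    mask <- rho <= 1
  }
  new("NuclearMask", mask = mask, pixelSize = params@pixelSize,
      nucleusID = nucleusID, groupLabel = groupLabel, probeID = probeID)
}

# Pick the territory pixel set: seed point at a target normalized radius
# along a random angle from the deepest pixel, then take the nearest
# `targetArea` mask pixels (a compact blob clipped to the mask).
.placeTerritory <- function(mask, rmap, params) {
  fg <- which(mask)
  area <- length(fg)
  targetArea <- max(1L, round(params@territoryAreaFraction * area))
  if (targetArea > area)
    stop("territoryAreaFraction infeasible for this mask")
  nr <- nrow(mask)
  ij <- arrayInd(fg, dim(mask))
  rfg <- rmap[fg]
  .withStream(params@seed, "territory", {
    target <- min(max(rnorm(1, params@territoryRadialMu,
                            params@territoryRadialSigma), 0), 1)
    theta <- runif(1, 0, 2 * pi)
    deep <- fg[which.min(rfg)]
    dc <- arrayInd(deep, dim(mask))
    # angular sector around theta; fall back to all pixels if sector empty
    ang <- atan2(ij[, 2] - dc[2], ij[, 1] - dc[1])
    dang <- abs(((ang - theta + pi) %% (2 * pi)) - pi)
    cand <- which(dang < pi / 8 | rfg < 0.05)
    if (!length(cand)) cand <- seq_along(fg)
    seedIdx <- cand[which.min(abs(rfg[cand] - target))]
    d2 <- (ij[, 1] - ij[seedIdx, 1])^2 + (ij[, 2] - ij[seedIdx, 2])^2
    sel <- fg[order(d2, fg)[seq_len(targetArea)]]
    terr <- matrix(FALSE, nrow(mask), ncol(mask))
    terr[sel] <- TRUE
    terr
  })
}

#' Render a two-channel synthetic FISH scene
#'
#' Places a chromosome-territory blob inside the mask at the radial position
#' requested in `params`, then renders a probe channel (territory signal,
#' small Gaussian blur, Poisson photon noise, Gaussian read noise, constant
#' background) and a counterstain channel covering the whole nucleus.  The
#' ground-truth territory pixel set and its mean normalized radius are
#' computed before any noise is applied, so they are invariant to the noise
#' parameters.
#'
#' @param mask a [NuclearMask-class] from [makeNucleusMask()].
#' @param params the [SceneParams-class]; placement and noise draw from
#'   independent substreams of `params@seed`.
#' @param blurSigma Gaussian blur SD in pixels applied to the pre-noise
#'   signal (small optical blur; 0 disables).
#' @param rmap optional precomputed normalized-radius map of `mask` (as used
#'   by the binning); avoids recomputing the distance transform when many
#'   scenes share one mask.
#' @param shotNoise apply Poisson photon noise (TRUE, default); FALSE gives
#'   the deterministic expected signal, so that together with
#'   `readNoiseSd = 0` the rendering is exactly noiseless.
#' @return A [TerritoryScene-class].
#' @export
renderTerritoryScene <- function(mask, params, blurSigma = 0.8, rmap = NULL,
                                 shotNoise = TRUE) {
  stopifnot(is(mask, "NuclearMask"), is(params, "SceneParams"))
  validObject(params)
  m <- mask@mask
  if (is.null(rmap)) rmap <- .normalizedRadiusMap(m)
  terr <- .placeTerritory(m, rmap, params)
  truth <- mean(rmap[terr])
  signal <- params@photonScale * (terr * 1)
  if (blurSigma > 0 && params@photonScale > 0)
    signal <- as.matrix(EBImage::gblur(signal, sigma = blurSigma))
  signal[signal < 0] <- 0
  nucSignal <- params@photonScale * (m * 1)
  chans <- .withStream(params@seed, "noise", {
    shot <- if (shotNoise)
      matrix(rpois(length(signal), signal), nrow(signal)) else signal
    read <- if (params@readNoiseSd > 0)
      matrix(rnorm(length(signal), 0, params@readNoiseSd), nrow(signal))
    else 0
    shot2 <- if (shotNoise)
      matrix(rpois(length(nucSignal), nucSignal), nrow(nucSignal)) else nucSignal
    read2 <- if (params@readNoiseSd > 0)
      matrix(rnorm(length(nucSignal), 0, params@readNoiseSd), nrow(nucSignal))
    else 0
    list(probe = params@background + shot + read,
         counter = params@background + shot2 + read2)
  })
  new("TerritoryScene", probe = chans$probe, counterstain = chans$counter, mask = mask,
      territory = terr, meanRadius = truth, params = params)
}

#' Simulate a cohort of territory scenes and their radial profiles
#'
#' Convenience wrapper for simulation studies: renders `n` scenes with
#' per-nucleus seeds derived from `seed`, bins each mask, and returns the
#' per-nucleus radial profiles together with the ground truth.  When all
#' nuclei share the same geometry (no boundary perturbation) the bin map is
#' computed once and reused.
#'
#' @param n number of nuclei.
#' @param params template [SceneParams-class]; the seed slot is replaced per
#'   nucleus.
#' @param seed cohort seed.
#' @param groupLabel,probeID identifiers stamped on the profiles.
#' @param nbins,mode binning settings, see [computeDistanceBins()].
#' @param shotNoise passed to [renderTerritoryScene()].
#' @return List with `profiles` (list of [RadialProfile-class]),
#'   `truth` (numeric vector of ground-truth mean radii) and `scenes`
#'   (kept only when `keepScenes = TRUE`).
#' @param keepScenes keep rendered scenes (memory-heavy for large n).
#' @export
simulateTerritoryCohort <- function(n, params, seed = 1L,
                                    groupLabel = "group", probeID = "probe",
                                    nbins = 10L, mode = "equal_width",
                                    keepScenes = FALSE, shotNoise = TRUE) {
  stopifnot(.isCount(n))
  sharedGeometry <- params@boundaryPerturbAmp == 0
  binmap <- NULL
  rmap <- NULL
  profiles <- vector("list", n)
  truth <- numeric(n)
  scenes <- if (keepScenes) vector("list", n) else NULL
  for (i in seq_len(n)) {
    pi_ <- params
    pi_@seed <- as.integer((as.double(seed) * 1000L + i) %% 2147483647)
    mk <- makeNucleusMask(pi_, nucleusID = sprintf("%s_n%03d", groupLabel, i),
                          groupLabel = groupLabel, probeID = probeID)
    if (is.null(binmap) || !sharedGeometry) {
      binmap <- computeDistanceBins(mk, nBins = nbins, mode = mode)
      rmap <- .normalizedRadiusMap(mk@mask)
    }
    sc <- renderTerritoryScene(mk, pi_, rmap = rmap, shotNoise = shotNoise)
    profiles[[i]] <- profileIntensity(sc@probe, binmap,
                                      nucleusID = mk@nucleusID,
                                      groupLabel = groupLabel,
                                      probeID = probeID)
    truth[i] <- sc@meanRadius
    if (keepScenes) scenes[[i]] <- sc
  }
  list(profiles = profiles, truth = truth, scenes = scenes)
}
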