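#' Construct beat-trace simulation parameters
#'
#' Defaults follow the study's acquisition settings for video-edge capture of
#' paced hiPSC-CMs: 63 frames/s for 25 s under 1 Hz electrical pacing.
#' Pulse shape is a linear rise over `riseTime` followed by an exponential
#' decay with time constant `decayTime`, so onset, peak and fractional-return
#' times are available in closed form for tests.
#'
#' @inheritParams sceneParams
#' @param frameRate sampling rate, Hz.
#' @param duration recording length, s.
#' @param pacingRate pacing rate, Hz.
#' @param amplitudeMu mean beat amplitude (trace units, e.g. um).
#' @param amplitudeCv per-beat amplitude coefficient of variation.
#' @param riseTime upstroke duration, s.
#' @param decayTime relaxation time constant, s.
#' @param baseline resting level.
#' @param timingJitterSd per-beat onset jitter SD, s.
#' @param noiseSd additive Gaussian noise SD.
#' @param riseShape "linear" (default) or "exponential".
#' @return A validated [TraceParams-class].
#' @export
traceParams <- function(frameRate = 63, duration = 25, pacingRate = 1,
                        amplitudeMu = 1, amplitudeCv = 0.1,
                        riseTime = 0.2, decayTime = 0.15, baseline = 0,
                        timingJitterSd = 0.01, noiseSd = 0.02,
                        riseShape = "linear", seed = 1L) {
  new("TraceParams", frameRate = frameRate, duration = duration,
      pacingRate = pacingRate, amplitudeMu = amplitudeMu,
      amplitudeCv = amplitudeCv, riseTime = riseTime, decayTime = decayTime,
      baseline = baseline, timingJitterSd = timingJitterSd, noiseSd = noiseSd,
      riseShape = riseShape, seed = as.integer(seed))
}

#' Simulate a paced beat trace with known ground truth
#'
#' Builds a displacement (or calcium-ratio) trace as a sum of per-beat
#' pulses at jittered pacing times, plus baseline and Gaussian sample noise.
#' Each pulse rises over `riseTime` to its amplitude and decays
#' exponentially with `decayTime`.  The returned ground-truth table lists
#' every beat's onset time, peak time and amplitude as constructed, before
#' noise.
#'
#' @param params a [TraceParams-class].
#' @param modality "displacement" (default) or "calcium_ratio".
#' @return List with `trace` (a [BeatTrace-class]), `truth` (data.frame:
#'   beat, onset_s, peak_s, amplitude) and `overlap` (TRUE when
#'   riseTime + 5*decayTime exceeds the pacing period, i.e. beats overlap
#'   substantially; flagged, not an error).
#' @examples
#' sim <- simulateBeatTrace(traceParams(noiseSd = 0, timingJitterSd = 0,
#'                                      amplitudeCv = 0))
#' nrow(sim$truth)
#' @export
simulateBeatTrace <- function(params, modality = "displacement") {
  stopifnot(is(params, "TraceParams"))
  validObject(params)
  fr <- params@frameRate
  n <- floor(fr * params@duration)
  tgrid <- (seq_len(n) - 1) / fr
  nBeats <- floor(params@pacingRate * params@duration)
  period <- 1 / params@pacingRate
  overlap <- params@riseTime + 5 * params@decayTime > period
  sim <- .withStream(params@seed, "trace", {
    jitter <- if (params@timingJitterSd > 0)
      rnorm(nBeats, 0, params@timingJitterSd) else numeric(nBeats)
    amps <- if (params@amplitudeCv > 0)
      pmax(params@amplitudeMu * (1 + params@amplitudeCv * rnorm(nBeats)), 0)
    else rep(params@amplitudeMu, nBeats)
    noise <- if (params@noiseSd > 0) rnorm(n, 0, params@noiseSd) else numeric(n)
    list(jitter = jitter, amps = amps, noise = noise)
  })
  onsets <- pmax((seq_len(nBeats) - 1) * period + sim$jitter, 0)
  x <- rep(params@baseline, n)
  for (k in seq_len(nBeats)) {
    dt <- tgrid - onsets[k]
    active <- dt >= 0
    pulse <- numeric(n)
    rising <- active & dt < params@riseTime
    if (params@riseShape == "linear") {
      pulse[rising] <- sim$amps[k] * dt[rising] / params@riseTime
    } else {
      pulse[rising] <- sim$amps[k] *
        (1 - exp(-3 * dt[rising] / params@riseTime)) / (1 - exp(-3))
    }
    decaying <- active & dt >= params@riseTime
    pulse[decaying] <- sim$amps[k] *
      exp(-(dt[decaying] - params@riseTime) / params@decayTime)
    x <- x + pulse
  }
  x <- x + sim$noise
  trace <- new("BeatTrace", samples = x, frameRate = fr,
               pacingRate = params@pacingRate, modality = modality)
  truth <- data.frame(beat = seq_len(nBeats), onset_s = onsets,
                      peak_s = onsets + params@riseTime, amplitude = sim$amps)
  list(trace = trace, truth = truth, overlap = overlap)
}

#' Simulate a force-calcium dose-response curve
#'
#' Hill-model forces over a concentration grid, with optional Gaussian
#' noise: F(c) = fmax * c^h / (ec50^h + c^h) + noise.  The default grid
#' covers the stepwise external-calcium protocol from 0.3 to 3.0 mmol/L.
#'
#' @param ec50 half-maximal concentration, mmol/L.
#' @param hill Hill coefficient (> 0).
#' @param fmax maximal force (trace units).
#' @param concentrations concentration grid, mmol/L (all > 0).
#' @param noiseSd Gaussian noise SD (trace units).
#' @param seed integer seed.
#' @return data.frame with `concentration` and `force`.
#' @export
simulateCalciumResponse <- function(ec50, hill, fmax,
                                    concentrations = seq(0.3, 3.0, by = 0.3),
                                    noiseSd = 0, seed = 1L) {
  stopifnot(ec50 > 0, hill > 0, all(concentrations > 0), noiseSd >= 0)
  f <- fmax * concentrations^hill / (ec50^hill + concentrations^hill)
  if (noiseSd > 0)
    f <- f + .withStream(seed, "calcium", rnorm(length(f), 0, noiseSd))
  data.frame(concentration = concentrations, force = f)
}
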