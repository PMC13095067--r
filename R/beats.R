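#' Segment beats in a contraction or calcium trace
#'
#' Peaks are found by prominence-based detection with a refractory interval;
#' for each retained peak the preceding trough is located, a local baseline
#' is estimated as the median of a short window ending at the trough
#' (robust to slow drift), and the rise onset is the last sample at or below
#' baseline + `onsetFraction` of the beat amplitude before the upstroke
#' crosses that threshold.  The end of relaxation is the subsequent
#' displacement minimum (the next beat's trough, or the post-peak minimum
#' for the final beat).  All thresholds are fractional, so segmentation is
#' invariant to positive rescaling and additive offsets of the trace.
#'
#' @param trace a [BeatTrace-class].
#' @param minProminence minimum peak prominence as a fraction of the trace
#'   excursion (95th - 5th percentile); beats below it are discarded.
#' @param minInterval refractory interval between retained peaks, s;
#'   defaults to half the pacing period when pacing is known, else 0.25 s.
#' @param onsetFraction rise-onset threshold as a fraction of beat
#'   amplitude above local baseline.
#' @return data.frame with one row per beat: `onset`, `trough`, `peak`,
#'   `end` (1-based sample indices), `baseline`, `amplitude`,
#'   `contraction_time` and `relaxation_time` (s).  Zero rows when no peaks
#'   qualify.  The onset fraction used is attached as attribute
#'   `onsetFraction`.
#' @examples
#' sim <- simulateBeatTrace(traceParams(noiseSd = 0, timingJitterSd = 0,
#'                                      amplitudeCv = 0))
#' nrow(detectBeats(sim$trace))
#' @export
detectBeats <- function(trace, minProminence = 0.3, minInterval = NULL,
                        onsetFraction = 0.1) {
  stopifnot(is(trace, "BeatTrace"))
  validObject(trace)
  x <- trace@samples
  n <- length(x)
  fr <- trace@frameRate
  if (is.null(minInterval))
    minInterval <- if (is.finite(trace@pacingRate) && trace@pacingRate > 0)
      0.5 / trace@pacingRate else 0.25
  empty <- data.frame(onset = integer(), trough = integer(), peak = integer(),
                      end = integer(), baseline = numeric(),
                      amplitude = numeric(), contraction_time = numeric(),
                      relaxation_time = numeric())
  attr(empty, "onsetFraction") <- onsetFraction
  exc <- quantile(x, 0.95) - quantile(x, 0.05)
  if (exc == 0) return(empty)
  cand <- .localMaxima(x)
  if (!length(cand)) return(empty)
  prom <- .prominence(x, cand)
  cand <- cand[prom >= minProminence * exc]
  if (!length(cand)) return(empty)
  # refractory: keep taller peaks first
  keep <- logical(length(cand))
  gap <- round(minInterval * fr)
  for (i in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < gap)) keep[i] <- TRUE
  }
  peaks <- sort(cand[keep])
  np <- length(peaks)
  troughs <- integer(np)
  for (i in seq_len(np)) {
    lo <- if (i == 1) 1L else peaks[i - 1] + 1L
    win <- x[lo:peaks[i]]
    # last index attaining the minimum: the sample adjacent to the upstroke
    troughs[i] <- lo + max(which(win == min(win))) - 1L
  }
  ibi <- if (np > 1) median(diff(peaks)) else round(fr * minInterval * 2)
  w <- max(3L, round(0.15 * ibi))
  rows <- lapply(seq_len(np), function(i) {
    pk <- peaks[i]; tr <- troughs[i]
    blo <- max(if (i == 1) 1L else peaks[i - 1] + 1L, tr - w + 1L)
    base <- median(x[blo:tr])
    amp <- x[pk] - base
    if (amp <= 0 || amp < minProminence * exc) return(NULL)
    thr <- base + onsetFraction * amp
    below <- which(x[tr:pk] <= thr)
    onset <- if (length(below)) tr + max(below) - 1L else tr
    if (onset >= pk) return(NULL)  # degenerate beat
    # end of relaxation: first minimum reached after the peak (before the
    # next peak, or in the remaining tail for the final beat)
    lim <- if (i < np) peaks[i + 1] else n
    endIdx <- pk + which.min(x[(pk + 1):lim])
    if (endIdx <= pk) return(NULL)
    data.frame(onset = onset, trough = tr, peak = pk, end = endIdx,
               baseline = base, amplitude = amp,
               contraction_time = (pk - onset) / fr,
               relaxation_time = (endIdx - pk) / fr)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  attr(out, "onsetFraction") <- onsetFraction
  out
}

# Indices of strict-left / weak-right local maxima (first sample of plateaus).
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

# Topographic prominence of each peak: height above the higher of the two
# lowest saddles toward the nearest higher ground (or trace edge).
.prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higherL <- which(left > h)
    minL <- min(x[(if (length(higherL)) max(higherL) else 1):p])
    right <- x[(p + 1):length(x)]
    higherR <- which(right > h)
    minR <- min(x[p:(if (length(higherR)) p + min(higherR) else length(x))])
    h - max(minL, minR)
  }, numeric(1))
}

#' Contraction and relaxation times of a beat
#'
#' Contraction time is the interval from rise onset to peak; relaxation
#' time from peak to the end-of-relaxation minimum, both on the sample grid.
#'
#' @param trace the [BeatTrace-class] the beats came from.
#' @param beats data.frame from [detectBeats()] (or rows of it).
#' @return data.frame with `contraction_time` and `relaxation_time` in
#'   seconds, one row per beat.  Degenerate beats (peak at onset) are
#'   rejected with an error.
#' @export
beatTimings <- function(trace, beats) {
  stopifnot(is(trace, "BeatTrace"))
  if (any(beats$peak <= beats$onset))
    stop("degenerate beat: peak does not follow onset")
  fr <- trace@frameRate
  data.frame(contraction_time = (beats$peak - beats$onset) / fr,
             relaxation_time = (beats$end - beats$peak) / fr)
}

#' Per-trace beat summary with heterogeneity index
#'
#' Means and beat-to-beat standard deviations (sample SD, n-1) of amplitude,
#' contraction time and relaxation time across the beats of one recording.
#' The SD is the heterogeneity index: a proxy for contraction irregularity.
#'
#' @param beats data.frame from [detectBeats()].
#' @return One-row data.frame: `n_beats`, then `<metric>_mean` and
#'   `<metric>_sd` for amplitude, contraction_time and relaxation_time.
#'   With zero beats all metrics are NA; with one beat the SDs are NA.
#' @export
summarizeTrace <- function(beats) {
  metrics <- c("amplitude", "contraction_time", "relaxation_time")
  if (!nrow(beats)) {
    out <- data.frame(n_beats = 0L)
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- NA_real_
      out[[paste0(m, "_sd")]] <- NA_real_
    }
    return(out)
  }
  out <- data.frame(n_beats = nrow(beats))
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- mean(beats[[m]])
    out[[paste0(m, "_sd")]] <- if (nrow(beats) > 1) sd(beats[[m]]) else NA_real_
  }
  out
}
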