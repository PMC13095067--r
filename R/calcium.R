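#' Calcium-transient metrics of a ratiometric trace
#'
#' Computes the diastolic (resting) ratio and the diastolic time of a paced
#' ratiometric calcium trace.  Transients are segmented with
#' [detectBeats()]; the diastolic ratio is the mean of the per-transient
#' pre-onset baseline windows.  For each transient the diastolic time is
#' the interval from the ratio peak to the first return to within 10
#' percent of the transient height above baseline (i.e. 90 percent of the
#' way back to the diastolic level), with the crossing linearly
#' interpolated between samples.  Transients that never return before the
#' next onset are excluded with a warning.
#'
#' @param trace a [BeatTrace-class] with modality "calcium_ratio".
#' @param returnFraction residual fraction of the transient height defining
#'   the return level (default 0.10).
#' @param ... passed to [detectBeats()].
#' @return List with `diastolic_ratio`, `diastolic_time` (s),
#'   `transient_amplitude` (means over transients), `n_transients`,
#'   `n_excluded` and the per-transient data.frame `transients`.
#'   With no detectable transients all metrics are NA and
#'   `n_transients` is 0.
#' @export
calciumMetrics <- function(trace, returnFraction = 0.10, ...) {
  stopifnot(is(trace, "BeatTrace"))
  if (trace@modality != "calcium_ratio")
    stop("calciumMetrics expects a calcium_ratio trace")
  beats <- detectBeats(trace, ...)
  emptyOut <- list(diastolic_ratio = NA_real_, diastolic_time = NA_real_,
                   transient_amplitude = NA_real_, n_transients = 0L,
                   n_excluded = 0L, transients = data.frame())
  if (!nrow(beats)) return(emptyOut)
  if (nrow(beats) < 3)
    stop("need at least 3 transients in a paced calcium trace")
  x <- trace@samples
  fr <- trace@frameRate
  diastolic <- mean(beats$baseline)
  n <- length(x)
  rows <- lapply(seq_len(nrow(beats)), function(i) {
    pk <- beats$peak[i]
    peakVal <- x[pk]
    level <- diastolic + returnFraction * (peakVal - diastolic)
    stopIdx <- if (i < nrow(beats)) beats$onset[i + 1] else n
    if (stopIdx <= pk) return(NULL)
    seg <- x[pk:stopIdx]
    below <- which(seg <= level)
    if (!length(below)) return(NULL)  # never returned: excluded
    k <- min(below)
    tcross <- if (k == 1) 0
    else (k - 2) + (seg[k - 1] - level) / (seg[k - 1] - seg[k])
    data.frame(transient = i, peak = pk,
               amplitude = peakVal - diastolic,
               diastolic_time = tcross / fr)
  })
  kept <- do.call(rbind, rows)
  nExcl <- nrow(beats) - if (is.null(kept)) 0L else nrow(kept)
  if (nExcl > 0)
    warning(nExcl, " transient(s) never returned to within ",
            round(100 * returnFraction), "% of baseline and were excluded")
  if (is.null(kept) || !nrow(kept)) {
    out <- emptyOut
    out$n_excluded <- nExcl
    out$diastolic_ratio <- diastolic
    return(out)
  }
  list(diastolic_ratio = diastolic,
       diastolic_time = mean(kept$diastolic_time),
       transient_amplitude = mean(kept$amplitude),
       n_transients = nrow(kept),
       n_excluded = nExcl,
       transients = kept)
}

#' Fit a Hill model to a force-calcium response curve
#'
#' Bounded least-squares fit of F(c) = Fmax * c^h / (EC50^h + c^h) to forces
#' measured under a stepwise external-calcium protocol (e.g. 0.3 to 3.0
#' mmol/L).  EC50 is constrained to [0.1 * min(c), 10 * max(c)] and the
#' Hill coefficient to (0, 8]; a fit whose EC50 lies outside the measured
#' concentration range is flagged.
#'
#' @param concentrations calcium concentrations, mmol/L (>= 4 distinct).
#' @param force measured force at each concentration.
#' @return A [CalciumResponseCurve-class].  Degenerate or non-convergent
#'   data yield status "failed" with NA estimates.
#' @examples
#' d <- simulateCalciumResponse(ec50 = 0.9, hill = 2, fmax = 1)
#' ec50(fitCalciumResponse(d$concentration, d$force))
#' @export
fitCalciumResponse <- function(concentrations, force) {
  if (length(concentrations) != length(force))
    stop("concentrations and force lengths differ")
  if (length(unique(concentrations)) < 4)
    stop("need at least 4 distinct concentrations")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  failed <- new("CalciumResponseCurve", concentrations = concentrations,
                force = force, ec50 = NA_real_, hill = NA_real_,
                fmax = NA_real_, residual = NA_real_, status = "failed",
                ec50InRange = FALSE)
  if (sd(force) == 0) return(failed)
  lowerC <- 0.1 * min(concentrations); upperC <- 10 * max(concentrations)
  fmax0 <- max(force)
  half <- fmax0 / 2
  ec0 <- concentrations[which.min(abs(force - half))]
  ec0 <- min(max(ec0, lowerC), upperC)
  df <- data.frame(c = concentrations, f = force)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ fmax * c^h / (ec50^h + c^h), data = df,
      start = list(fmax = fmax0, ec50 = ec0, h = 1.5),
      lower = c(fmax = 1e-12, ec50 = lowerC, h = 1e-3),
      upper = c(fmax = 10 * abs(fmax0) + 1, ec50 = upperC, h = 8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- coef(fit)
  new("CalciumResponseCurve", concentrations = concentrations, force = force,
      ec50 = unname(cf["ec50"]), hill = unname(cf["h"]),
      fmax = unname(cf["fmax"]),
      residual = sqrt(mean(resid(fit)^2)), status = "ok",
      ec50InRange = cf["ec50"] >= min(concentrations) &&
        cf["ec50"] <= max(concentrations))
}
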