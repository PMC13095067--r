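test_that("diastolic time of an exponential-decay transient equals tau*ln(10)", {
  tau <- 0.15
  p <- traceParams(riseTime = 0.06, decayTime = tau, noiseSd = 0,
                   timingJitterSd = 0, amplitudeCv = 0, baseline = 1.2)
  sim <- simulateBeatTrace(p, modality = "calcium_ratio")
  cm <- calciumMetrics(sim$trace)
  expect_gt(cm$n_transients, 20)
  expect_lt(abs(cm$diastolic_time - tau * log(10)), 1 / 63)
  expect_lt(abs(cm$diastolic_ratio - 1.2), 0.02)
})

test_that("additive offsets shift the diastolic ratio but not the diastolic time", {
  p <- traceParams(riseTime = 0.06, decayTime = 0.12, noiseSd = 0,
                   timingJitterSd = 0, amplitudeCv = 0)
  tr <- simulateBeatTrace(p, modality = "calcium_ratio")$trace
  shifted <- new("BeatTrace", samples = traceSamples(tr) + 0.7,
                 frameRate = frameRate(tr), pacingRate = pacingRate(tr),
                 modality = "calcium_ratio")
  a <- calciumMetrics(tr)
  b <- calciumMetrics(shifted)
  expect_equal(b$diastolic_time, a$diastolic_time, tolerance = 1e-9)
  expect_equal(b$diastolic_ratio - a$diastolic_ratio, 0.7, tolerance = 1e-9)
})

test_that("baseline-only calcium traces give an explicit empty result", {
  flat <- new("BeatTrace", samples = rep(1.1, 500), frameRate = 63,
              pacingRate = 1, modality = "calcium_ratio")
  cm <- calciumMetrics(flat)
  expect_identical(cm$n_transients, 0L)
  expect_true(is.na(cm$diastolic_time))
  expect_error(calciumMetrics(simulateBeatTrace(traceParams())$trace),
               "calcium_ratio")
})

test_that("transients that never return to baseline are excluded with a warning", {
  # decay so slow the ratio never re-approaches baseline within a beat
  p <- traceParams(riseTime = 0.05, decayTime = 3, noiseSd = 0,
                   timingJitterSd = 0, amplitudeCv = 0)
  sim <- simulateBeatTrace(p, modality = "calcium_ratio")
  expect_warning(cm <- calciumMetrics(sim$trace), "excluded")
  expect_gt(cm$n_excluded, 0)
})

test_that("noiseless Hill data are recovered to better than 1%", {
  d <- simulateCalciumResponse(0.9, 2, 1.5)
  fit <- fitCalciumResponse(d$concentration, d$force)
  expect_identical(fitStatus(fit), "ok")
  expect_lt(abs(ec50(fit) - 0.9) / 0.9, 0.01)
  expect_lt(abs(hillCoef(fit) - 2) / 2, 0.01)
  expect_true(fit@ec50InRange)
})

test_that("EC50 estimation stays within 10% median error at 5% noise", {
  errs <- vapply(1:60, function(s) {
    d <- simulateCalciumResponse(0.9, 2, 1, noiseSd = 0.05, seed = s)
    fit <- fitCalciumResponse(d$concentration, d$force)
    if (fitStatus(fit) != "ok") return(NA_real_)
    abs(ec50(fit) - 0.9) / 0.9
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("degenerate dose-response data yield a failed fit, not a crash", {
  expect_identical(fitStatus(fitCalciumResponse(seq(0.3, 3, 0.3), rep(2, 10))),
                   "failed")
  expect_error(fitCalciumResponse(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
})
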