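test_that("noiseless 1 Hz traces segment into 25 beats with frame-accurate timings", {
  p <- traceParams(noiseSd = 0, timingJitterSd = 0, amplitudeCv = 0)
  sim <- simulateBeatTrace(p)
  beats <- detectBeats(sim$trace)
  expect_identical(nrow(beats), 25L)
  # peak indices within one sample of ground truth
  truthPeakIdx <- sim$truth$peak_s * 63 + 1
  expect_true(all(abs(beats$peak - truthPeakIdx) <= 1))
  # contraction time: onset -> peak, ground truth = rise time
  expect_true(all(abs(beats$contraction_time - 0.2) <= 1 / 63))
  # relaxation: peak -> next displacement minimum; ground truth = period - rise
  interior <- beats$relaxation_time[-25]
  expect_true(all(abs(interior - 0.8) <= 1 / 63))
})

test_that("constant traces contain no beats", {
  expect_identical(nrow(detectBeats(asTrace(rep(1.3, 400)))), 0L)
})

test_that("beat segmentation is invariant to positive rescaling and offsets", {
  p <- traceParams(seed = 8)
  tr <- simulateBeatTrace(p)$trace
  b0 <- detectBeats(tr)
  b2 <- detectBeats(asTrace(2 * traceSamples(tr)))
  b3 <- detectBeats(asTrace(traceSamples(tr) + 11))
  for (col in c("onset", "peak", "end")) {
    expect_identical(b0[[col]], b2[[col]])
    expect_identical(b0[[col]], b3[[col]])
  }
})

test_that("a symmetric triangular pulse gives equal contraction and relaxation times", {
  fr <- 64
  # triangular pulse: 0.25 s up, 0.25 s down, then a flat diastolic interval
  pulse <- c((0:16) / 16, (15:0) / 16, rep(0, 31))
  x <- rep(pulse, 6)
  beats <- detectBeats(asTrace(x, fr = fr), onsetFraction = 0)
  expect_gt(nrow(beats), 3)
  expect_true(all(abs(beats$contraction_time - beats$relaxation_time) <= 1 / fr))
})

test_that("beatTimings reproduces detectBeats timings and rejects degenerate beats", {
  sim <- simulateBeatTrace(traceParams(seed = 2))
  beats <- detectBeats(sim$trace)
  bt <- beatTimings(sim$trace, beats)
  expect_equal(bt$contraction_time, beats$contraction_time)
  expect_equal(bt$relaxation_time, beats$relaxation_time)
  bad <- beats; bad$onset[1] <- bad$peak[1]
  expect_error(beatTimings(sim$trace, bad), "degenerate")
})

test_that("trace summaries average beats and use the SD heterogeneity index", {
  b <- data.frame(amplitude = c(1, 2, 3), contraction_time = c(0.2, 0.2, 0.2),
                  relaxation_time = c(0.5, 0.6, 0.7))
  s <- summarizeTrace(b)
  expect_identical(s$n_beats, 3L)
  expect_equal(s$amplitude_mean, 2)
  expect_equal(s$amplitude_sd, 1)
  expect_equal(s$contraction_time_sd, 0)
  # identical beats: zero heterogeneity for every metric
  ident <- b[rep(2, 8), ]
  sI <- summarizeTrace(ident)
  expect_equal(sI$amplitude_sd, 0)
  expect_equal(sI$relaxation_time_sd, 0)
  # empty summary is explicit, not an error
  s0 <- summarizeTrace(detectBeats(asTrace(rep(0, 400))))
  expect_identical(s0$n_beats, 0L)
  expect_true(is.na(s0$amplitude_mean))
})

test_that("amplitude heterogeneity recovers the simulated coefficient of variation", {
  cvs <- vapply(1:60, function(s) {
    sim <- simulateBeatTrace(traceParams(amplitudeCv = 0.2, noiseSd = 0.01,
                                         timingJitterSd = 0, seed = s))
    sm <- summarizeTrace(detectBeats(sim$trace))
    sm$amplitude_sd / sm$amplitude_mean
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.2) / 0.2, 0.2)
})

test_that("heterogeneity shrinks monotonically along a variability ladder", {
  het <- vapply(c(0.2, 0.1, 0.05, 0), function(cv) {
    sim <- simulateBeatTrace(traceParams(amplitudeCv = cv, noiseSd = 0,
                                         timingJitterSd = 0, seed = 3))
    summarizeTrace(detectBeats(sim$trace))$amplitude_sd
  }, numeric(1))
  expect_true(all(diff(het) < 0))
  expect_lt(het[4], 0.01)
})
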