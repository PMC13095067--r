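test_that("noiseless pacing yields exactly the expected number of ground-truth beats", {
  sim <- simulateBeatTrace(traceParams(noiseSd = 0, timingJitterSd = 0,
                                       amplitudeCv = 0))
  expect_identical(nrow(sim$truth), 25L)
  expect_equal(sim$truth$onset_s, 0:24)
  expect_equal(sim$truth$amplitude, rep(1, 25))
  expect_false(sim$overlap)
})

test_that("zero amplitude gives a constant trace at baseline", {
  sim <- simulateBeatTrace(traceParams(amplitudeMu = 0, amplitudeCv = 0,
                                       noiseSd = 0, baseline = 2.5))
  expect_true(all(traceSamples(sim$trace) == 2.5))
})

test_that("seeded trace simulation is bit-identical and overlap is flagged", {
  p <- traceParams(seed = 13)
  expect_identical(traceSamples(simulateBeatTrace(p)$trace),
                   traceSamples(simulateBeatTrace(p)$trace))
  long <- traceParams(decayTime = 0.5, riseTime = 0.3)
  expect_true(simulateBeatTrace(long)$overlap)
})

test_that("calcium response follows the Hill closed form", {
  grid <- seq(0.3, 3.0, by = 0.3)
  d <- simulateCalciumResponse(ec50 = 0.9, hill = 2, fmax = 1.8,
                               concentrations = grid, noiseSd = 0)
  expect_equal(d$force, 1.8 * grid^2 / (0.9^2 + grid^2), tolerance = 1e-12)
  # midpoint and monotone saturation
  dm <- simulateCalciumResponse(0.9, 2, 1.8, concentrations = c(0.9, 5, 50, 500))
  expect_equal(dm$force[1], 0.9)
  expect_true(all(diff(dm$force) > 0))
  expect_lt(abs(dm$force[4] - 1.8), 1e-3)
})

test_that("trace parameter invariants are enforced", {
  expect_error(traceParams(duration = 2), "3 beats")
  expect_error(traceParams(noiseSd = -1), ">= 0")
})
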