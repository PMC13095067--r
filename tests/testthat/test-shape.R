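test_that("disk shape descriptors approach the circle limit", {
  d <- shapeDescriptors(diskMask(50, px = 0.11))
  expect_lt(abs(d$circularity - 1), 0.05)
  expect_lt(abs(d$solidity - 1), 0.02)
  expect_lt(abs(d$area - pi * 50^2 * 0.11^2) / (pi * 50^2 * 0.11^2), 0.02)
  expect_gt(d$max_diameter, 2 * sqrt(d$area / pi) * 0.98)
})

test_that("rectangle solidity and Feret diameter match closed forms", {
  m <- matrix(FALSE, 110, 30); m[6:105, 6:25] <- TRUE
  d <- shapeDescriptors(asMask(m, px = 0.11))
  expect_lt(abs(d$solidity - 1), 0.02)
  diag <- sqrt(100^2 + 20^2) * 0.11
  expect_lt(abs(d$max_diameter - diag) / diag, 0.02)
  expect_equal(d$area, 2000 * 0.11^2)
})

test_that("convex masks have solidity near 1 and circularity falls with aspect ratio", {
  circs <- vapply(c(1, 2, 3, 4), function(ar) {
    p <- sceneParams(nucleusSemiaxes = c(32, 32 / ar), imageSize = c(72, 72))
    d <- shapeDescriptors(makeNucleusMask(p))
    expect_gte(d$solidity, 0.98)
    d$circularity
  }, numeric(1))
  expect_true(all(diff(circs) < 0))
})

test_that("empty masks are rejected", {
  expect_error(asMask(matrix(FALSE, 10, 10)), "foreground")
})
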