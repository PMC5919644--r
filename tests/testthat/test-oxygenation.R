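## Reaction-diffusion oxygenation model and histogram pre-tabulation.

tp <- tomParams(gridResolution = 48L)

test_that("no consumption leaves the field at the intravascular pO2", {
  r <- solvePO2Field(0.06, 0, tp, seed = 3)
  expect_true(all(abs(r$field - tp@intravascularPO2) < 1e-6))
})

test_that("no vessels means an anoxic steady state", {
  r <- solvePO2Field(0, 1, tp, seed = 3)
  expect_true(all(r$field == 0))
})

test_that("field stays within [0, p0] and consumption lowers it", {
  r1 <- solvePO2Field(0.03, 0.5, tp, seed = 5)
  r2 <- solvePO2Field(0.03, 1, tp, seed = 5)
  expect_true(all(r1$field >= 0 & r1$field <= tp@intravascularPO2))
  m1 <- mean(r1$field[r1$vesselMask == 0])
  m2 <- mean(r2$field[r2$vesselMask == 0])
  expect_gt(m1, m2)
})

test_that("mean pO2 increases with vascular fraction (seed-averaged)", {
  mean_at <- function(vf) {
    mean(vapply(1:20, function(s) {
      r <- solvePO2Field(vf, 1, tp, seed = 100 + s)
      mean(r$field[r$vesselMask == 0])
    }, 0))
  }
  expect_gt(mean_at(0.06), mean_at(0.01))
})

test_that("histogram condensation is normalized and area-weighted", {
  f <- matrix(40, 20, 20)
  h <- condenseHistogram(f)
  expect_equal(sum(h@weights), 1, tolerance = 1e-12)
  expect_equal(h@weights[16], 1)
  ## two half-areas at distinct values -> two bins with weight 0.5
  f2 <- matrix(c(rep(0.5, 200), rep(30, 200)), 20, 20)
  h2 <- condenseHistogram(f2)
  expect_equal(sort(h2@weights[h2@weights > 0]), c(0.5, 0.5))
  expect_error(condenseHistogram(matrix(40, 2, 2), matrix(1L, 2, 2)),
               "empty extravascular")
  expect_error(condenseHistogram(matrix(-1, 2, 2)), "non-negative")
})

test_that("lookup interpolation: identity at nodes, mean midway, clamping", {
  lk <- analyticLookup()
  ## exactly on a node
  h <- lookupHistogram(lk, 0.06, 1)
  expect_equal(h@weights[16], 0.9, tolerance = 1e-12)
  ## midway between vf nodes 0.02 and 0.06 -> mean of 0.3 and 0.9
  h2 <- lookupHistogram(lk, 0.04, 0.5)
  expect_equal(h2@weights[16], 0.6, tolerance = 1e-12)
  ## clamped below/above the grid
  expect_equal(lookupHistogram(lk, -0.01, 0.5)@weights[1], 1)
  expect_equal(lookupHistogram(lk, 0.5, 0.5)@weights[16], 1)
})

test_that("lookup build produces valid, serializable histograms", {
  lk <- solverLookup()
  expect_true(validObject(lk))
  ## median pO2 non-decreasing along the vf axis at full consumption
  med <- vapply(lk@vfGrid, function(v)
    medianPO2(lookupHistogram(lk, v, 1)), 0)
  expect_true(all(diff(med) >= 0))
  ## consuming less oxygen never lowers the median
  med2 <- vapply(lk@sGrid, function(s)
    medianPO2(lookupHistogram(lk, 0.015, s)), 0)
  expect_true(all(diff(med2) <= 0))
  ## vf = 6% is well oxygenated (calibration contract)
  expect_gt(medianPO2(lookupHistogram(lk, 0.06, 1)), 10)
  ## JSON round trip
  path <- tempfile(fileext = ".json")
  writeOxygenLookup(lk, path)
  lk2 <- readOxygenLookup(path)
  expect_equal(lk2@weights, lk@weights, tolerance = 1e-12)
  expect_equal(lk2@binCenters, lk@binCenters, tolerance = 1e-12)
  expect_equal(lk2@params@consumptionRateMax, lk@params@consumptionRateMax)
})

test_that("doubling the solver resolution moves the survival-relevant histogram summary by < 2%", {
  ## the observable the histograms feed is the oxygen-averaged survival
  ## fraction; it converges much faster than the raw mean pO2, whose
  ## near-vessel values are boundary-discretization limited
  sf_of <- function(res, seeds = 3) {
    p <- tomParams(gridResolution = as.integer(res))
    mean(vapply(seq_len(seeds), function(s) {
      r <- solvePO2Field(0.03, 1, p, seed = 400 + s)
      h <- condenseHistogram(r$field, r$vesselMask)
      sum(h@weights * survivalFraction(2, h@binCenters))
    }, 0))
  }
  s112 <- sf_of(112); s224 <- sf_of(224)
  expect_lt(abs(s224 - s112) / s112, 0.02)
})
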