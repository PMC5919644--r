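## Oxygen-dependent LQ survival: closed-form checks and oracle comparisons.

lq <- lqParams()      # alpha 0.35, beta 0.035, sigmaAlpha 0.05
oerp <- oerParams()   # 2.5 / 3 / 3.28 mmHg

test_that("OER hits its anoxic, aerobic and half-slope values", {
  expect_identical(oer(0, 2.5, 3.28), 1)
  expect_identical(oer(0, 3, 3.28), 1)
  ## aerobic plateau evaluated at p = 1e6 mmHg (documented tolerance 1e-3)
  expect_equal(oer(1e6, 2.5, 3.28), 2.5, tolerance = 1e-3)
  expect_equal(oer(1e6, 3, 3.28), 3, tolerance = 1e-3)
  ## p = k sits midway through the rise: (k + k*m)/(2k) = (1 + m)/2
  expect_equal(oer(3.28, 2.5, 3.28), 1.75, tolerance = 1e-12)
  expect_error(oer(-1, 2.5, 3.28), "non-negative")
  expect_error(oer(5, 2.5, -1), "positive")
})

test_that("OER stays within [1, max] and is non-decreasing in pO2", {
  set.seed(1)
  p <- sort(c(0, 10^runif(1000, -3, 3)))
  for (m in c(2.5, 3)) {
    v <- oer(p, m, 3.28)
    expect_true(all(v >= 1 - 1e-12 & v <= m + 1e-12))
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("survival fraction matches hand-evaluated limits", {
  expect_identical(survivalFraction(0, 5, lq, oerp), 1)
  ## full oxia: exponent -> -(alpha d + beta d^2) = -0.84 at 2 Gy
  expect_equal(survivalFraction(2, 1e6, lq, oerp), exp(-0.84), tolerance = 1e-3)
  expect_equal(survivalFraction(2, 1e6, lq, oerp), 0.43171, tolerance = 1e-4)
  ## anoxia: alpha_h = 0.14, beta_h = 0.035/9
  expect_equal(survivalFraction(2, 0, lq, oerp),
               exp(-0.14 * 2 - 0.035 / 9 * 4), tolerance = 1e-12)
  expect_equal(survivalFraction(2, 0, lq, oerp), 0.74414, tolerance = 1e-4)
  expect_error(survivalFraction(-1, 5, lq, oerp), "non-negative")
})

test_that("survival is monotone: decreasing in dose, decreasing in oxygen", {
  d <- seq(0, 6, by = 0.25)
  p <- c(0, 0.5, 2, 5, 20, 1e3)
  sf <- outer(d, p, function(dd, pp) survivalFraction(dd, pp, lq, oerp))
  expect_true(all(apply(sf, 2, diff) <= 1e-14))   # in d
  expect_true(all(apply(sf, 1, diff) <= 1e-14))   # in p
})

test_that("with OER maxima at 1 the model is exactly the plain LQ", {
  o1 <- oerParams(1, 1, 3.28)
  d <- c(0.5, 2, 4); p <- c(0, 1, 100)
  for (pp in p)
    expect_equal(survivalFraction(d, pp, lq, o1),
                 exp(-lq@alpha * d - lq@beta * d^2), tolerance = 1e-14)
})

test_that("voxel survivors sum the histogram bins", {
  oxic <- oxygenHistogram(c(0, 1e6), c(0, 1))
  anx <- oxygenHistogram(c(0, 1e6), c(1, 0))
  half <- oxygenHistogram(c(0, 1e6), c(0.5, 0.5))
  expect_equal(voxelSurvivors(100, oxic, 2, lq, oerp), 43.171, tolerance = 1e-3)
  expect_identical(voxelSurvivors(0, oxic, 2, lq, oerp), 0)
  expect_equal(voxelSurvivors(100, half, 2, lq, oerp), 58.79, tolerance = 1e-3)
  expect_equal(voxelSurvivors(50, anx, 0, lq, oerp), 50)
  expect_error(voxelSurvivors(-1, oxic, 2, lq, oerp), "non-negative")
})

test_that("total survivors equals the naive double loop on random grids", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    viable <- runif(n, 0, 1e6)
    W <- matrix(runif(n * 16), n, 16); W <- W / rowSums(W)
    grid <- makeTestGrid(viable, W)
    d <- runif(n, 1.5, 2.5)
    full <- rep(NA_real_, n); full[] <- d
    plan <- new("DosePlan", doses = full,
                constraints = doseConstraints(mean(d)), objective = "uniform",
                report = list())
    brute <- 0
    for (i in seq_len(n)) for (j in 1:16)
      brute <- brute + viable[i] * W[i, j] *
        survivalFraction(d[i], grid@binCenters[j], lq, oerp)
    expect_equal(totalSurvivors(grid, plan, lq, oerp), brute,
                 tolerance = 1e-12)
  }
})

test_that("total survivors is additive and reduces to totals at zero dose", {
  grid <- makeTestGrid(c(1000, 1000), oxicRow())
  plan0 <- uniformPlan(grid, 2)
  plan0@doses[] <- 0; plan0@constraints@meanDose <- 0
  expect_equal(totalSurvivors(grid, plan0, lq, oerp), 2000)
  one <- makeTestGrid(1000, oxicRow())
  p2 <- uniformPlan(grid, 2); p1 <- uniformPlan(one, 2)
  expect_equal(totalSurvivors(grid, p2, lq, oerp),
               2 * totalSurvivors(one, p1, lq, oerp), tolerance = 1e-12)
  bad <- uniformPlan(one, 2)
  expect_error(totalSurvivors(grid, bad, lq, oerp), "mismatch")
})
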