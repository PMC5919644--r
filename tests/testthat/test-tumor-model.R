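## Tumor response model processes: closed forms, conservation, stochastics.

bio <- bioParams()
lq <- lqParams(); oerp <- oerParams()

test_that("proliferation doubles over one doubling time and respects dt = 0", {
  g <- makeTestGrid(1000, oxicRow())
  g2 <- proliferate(g, 120, bioParams(tpAccelerated = 120, tpInitial = 1200), TRUE)
  ## duringGrowth uses tpGrowth = 120 h
  expect_equal(g2@viable[1], 2000, tolerance = 1e-12)
  expect_identical(proliferate(g, 0, bio)@viable, g@viable)
})

test_that("accelerated repopulation switches the doubling time at two weeks", {
  g <- makeTestGrid(1e5, oxicRow())
  g@time <- 13 * 24
  expect_equal(proliferate(g, 24, bio)@viable[1], 1e5 * 2^(24 / 1200))
  g@time <- 15 * 24
  expect_equal(proliferate(g, 24, bio)@viable[1], 1e5 * 2^(24 / 120))
})

test_that("proliferation is capped by the voxel capacity headroom", {
  K <- 1e6 * 1.124^3
  g <- makeTestGrid(1.05 * K, oxicRow())
  g2 <- proliferate(g, 24, bioParams(), TRUE)
  expect_lte(g2@viable[1], bio@growthHeadroom * K)
})

test_that("angiogenesis doubles capillaries only under hypoxia", {
  g <- makeTestGrid(c(1e5, 1e5), rbind(anoxicRow(), oxicRow()), capillary = 1e4)
  g2 <- angiogenesis(g, 612, bio)
  expect_equal(g2@capillary[1], 2e4, tolerance = 1e-12)
  expect_equal(g2@capillary[2], 1e4)
})

test_that("dead cells resorb with the configured half time", {
  g <- makeTestGrid(0, oxicRow(), dead = 1000)
  expect_equal(resorbDead(g, 168, bio)@dead[1], 500, tolerance = 1e-12)
  expect_identical(resorbDead(g, 0, bio)@dead[1], 1000)
  two <- resorbDead(resorbDead(g, 84, bio), 84, bio)@dead[1]
  expect_equal(two, resorbDead(g, 168, bio)@dead[1], tolerance = 1e-12)
})

test_that("irradiation: zero dose is a no-op, kill conserves viable + dead", {
  g <- makeTestGrid(c(2e5, 3e5), rbind(anoxicRow(), oxicRow()), dead = 100)
  p0 <- uniformPlan(g, 2); p0@doses[] <- 0; p0@constraints@meanDose <- 0
  g0 <- irradiate(g, p0, lq, oerp, stochastic = FALSE)
  expect_equal(g0@viable, g@viable)
  p2 <- uniformPlan(g, 2)
  g2 <- irradiate(g, p2, lq, oerp, stochastic = FALSE)
  expect_equal(g2@viable + g2@dead, g@viable + g@dead, tolerance = 1e-12)
  expect_true(all(g2@viable < g@viable))
  pBad <- uniformPlan(g, 2); pBad@doses[!is.na(pBad@doses)] <- 11
  expect_error(irradiate(g, pBad, lq, oerp), "outside")
})

test_that("binomial kill reproduces the expected survivors in the mean", {
  g <- makeTestGrid(5000, anoxicRow())
  plan <- uniformPlan(g, 2)
  expected <- g@viable[1] * survivalFraction(2, 0, lq, oerp)
  set.seed(99)
  draws <- replicate(200, irradiate(g, plan, lq, oerp,
                                    stochastic = TRUE)@viable[1])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se + 1e-9)
  expect_true(all(draws == round(draws)))
})

test_that("exchange: all voxels at capacity is a fixed point", {
  K <- 1e6 * 1.124^3
  g <- makeTestGrid(rep(K, 27), oxicRow(), dims = c(3, 3, 3))
  g2 <- exchangeCells(g, bio)
  expect_equal(g2@viable, g@viable, tolerance = 1e-12)
})

test_that("exchange pushes a single overfull voxel equally to 6 empty faces", {
  K <- 1e6 * 1.124^3
  viable <- numeric(27); viable[14] <- 1.2 * K   # center of a 3x3x3 lattice
  g <- makeTestGrid(viable, oxicRow(), dims = c(3, 3, 3))
  g2 <- exchangeCells(g, bio)
  expect_equal(sum(g2@viable), sum(g@viable), tolerance = 1e-9)
  expect_equal(g2@viable[14], K, tolerance = 1e-6)
  nb <- g2@viable[c(13, 15, 11, 17, 5, 23)]
  expect_equal(nb, rep(0.2 * K / 6, 6), tolerance = 1e-6)
})

test_that("exchange conserves every compartment on random grids", {
  set.seed(11)
  K <- 1e6 * 1.124^3
  for (rep in 1:3) {
    g <- makeTestGrid(runif(64, 0, 1.1 * K), oxicRow(), dims = c(4, 4, 4),
                      dead = runif(64, 0, 0.2 * K),
                      capillary = runif(64, 0, 0.1 * K))
    g2 <- exchangeCells(g, bio)
    for (slot_ in c("viable", "dead", "capillary"))
      expect_equal(sum(slot(g2, slot_)), sum(slot(g, slot_)),
                   tolerance = 1e-9)
    expect_true(all(g2@viable >= 0 & g2@dead >= 0 & g2@capillary >= 0))
  }
})

test_that("oxygenation refresh touches exactly the tumor voxels", {
  lk <- analyticLookup()
  K <- 1e6 * 1.124^3
  viable <- c(0, 1e5, K)
  g <- makeTestGrid(viable, anoxicRow(), capillary = c(0.06, 0.001, 0.06) * K)
  g2 <- updateOxygenation(g, lk)
  expect_equal(g2@weights[1, ], g@weights[1, ])      # empty voxel skipped
  ## vf 0.06 voxel becomes mostly oxic, vf 0.001 voxel mostly anoxic
  expect_gt(g2@weights[3, 16], 0.85)
  expect_gt(g2@weights[2, 1], 0.9)
})

test_that("a voxel with more capillaries gets a higher median pO2", {
  lk <- solverLookup()
  K <- 1e6 * 1.124^3
  g <- makeTestGrid(c(K, K), oxicRow(), capillary = c(0.01, 0.05) * K)
  g2 <- updateOxygenation(g, lk)
  med <- medianPO2(g2)
  expect_gt(med[2], med[1])
})

test_that("a day step without dose or proliferation pressure leaves the grid almost invariant", {
  lk <- analyticLookup()
  K <- 1e6 * 1.124^3
  slow <- bioParams(tpInitial = 1e9, tpAccelerated = 1e9, tpGrowth = 1e9)
  g <- makeTestGrid(rep(0.5 * K, 8), oxicRow(), dims = c(2, 2, 2),
                    capillary = 0.06 * K)
  g <- updateOxygenation(g, lk)
  g2 <- stepDay(g, NULL, slow, lq, oerp, lk, stochastic = FALSE)
  expect_equal(g2@viable, g@viable, tolerance = 1e-7)
  expect_equal(g2@dead, g@dead, tolerance = 1e-7)
  expect_equal(g2@time, 24)
})

test_that("one uniform 2 Gy fraction outweighs a day of slow regrowth", {
  lk <- analyticLookup()
  K <- 1e6 * 1.124^3
  g <- makeTestGrid(rep(0.7 * K, 27), oxicRow(), dims = c(3, 3, 3),
                    capillary = 0.06 * K)
  g <- updateOxygenation(g, lk)
  g2 <- stepDay(g, uniformPlan(g, 2), bio, lq, oerp, lk, stochastic = FALSE)
  expect_lt(sum(g2@viable), sum(g@viable))
})

test_that("deterministic day steps are exactly reproducible", {
  lk <- analyticLookup()
  K <- 1e6 * 1.124^3
  g <- makeTestGrid(runif(27, 0.2, 1) * K, oxicRow(), dims = c(3, 3, 3),
                    capillary = 0.05 * K)
  g <- updateOxygenation(g, lk)
  r1 <- stepDay(g, uniformPlan(g, 2), bio, lq, oerp, lk, stochastic = FALSE)
  r2 <- stepDay(g, uniformPlan(g, 2), bio, lq, oerp, lk, stochastic = FALSE)
  expect_identical(r1@viable, r2@viable)
  expect_identical(r1@weights, r2@weights)
})

test_that("doubling time is recovered from a silent growth trajectory", {
  lk <- analyticLookup()
  K <- 1e6 * 1.124^3
  g <- makeTestGrid(1000, oxicRow(), capillary = 0.06 * K)
  g <- updateOxygenation(g, lk)
  traj <- numeric(12)
  for (d in 1:12) {
    g <- stepDay(g, NULL, bio, lq, oerp, lk, stochastic = FALSE)
    traj[d] <- g@viable[1]
  }
  fit <- lm(log2(traj) ~ seq_along(traj))
  tpHat <- 24 / coef(fit)[2]
  expect_lt(abs(tpHat - bio@tpInitial) / bio@tpInitial, 0.02)
})
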