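## TCP fitting, D50, bootstrap and treatment gain.

makeOutcomes <- function(rates, doses, n = 10) {
  do.call(rbind, lapply(seq_along(doses), function(i) {
    k <- round(rates[i] * n)
    data.frame(dose = doses[i], patient = seq_len(n),
               controlled = c(rep(TRUE, k), rep(FALSE, n - k)))
  }))
}

test_that("symmetric control rates give the midpoint D50", {
  out <- makeOutcomes(c(0.1, 0.5, 0.9), c(60, 70, 80))
  co <- fitTCP(out)
  expect_equal(d50(co), 70, tolerance = 1e-6)
})

test_that("perfectly separated data are flagged, not silently fitted", {
  out <- makeOutcomes(c(0, 0, 1, 1), c(60, 65, 70, 75))
  expect_error(fitTCP(out), "separation")
  expect_error(fitTCP(makeOutcomes(c(0, 0), c(60, 70))), "identical")
  ## the pipeline falls back to the empirical midpoint
  expect_equal(midpointD50(out), 67.5)
})

test_that("D50 is the coefficient ratio and is scale-invariant", {
  expect_equal(d50(c(b0 = -21, b1 = 0.3)), 70)
  expect_equal(d50(c(-42, 0.6)), 70)   # scaled coefficients, same D50
  co <- fitTCP(makeOutcomes(c(0.2, 0.5, 0.8), c(55, 65, 75)))
  tcp <- function(D) unname(1 / (1 + exp(-(co[1] + co[2] * D))))
  expect_equal(tcp(d50(co)), 0.5, tolerance = 1e-9)
})

test_that("logistic parameters are recovered from data they generated", {
  set.seed(5)
  b0 <- -14; b1 <- 0.2          # true D50 = 70 Gy
  doses <- seq(50, 90, by = 5)
  out <- do.call(rbind, lapply(doses, function(D) {
    p <- 1 / (1 + exp(-(b0 + b1 * D)))
    data.frame(dose = D, patient = 1:40, controlled = runif(40) < p)
  }))
  co <- fitTCP(out)
  bt <- bootstrapD50(out, nBoot = 300, seed = 2)
  expect_lt(abs(d50(co) - 70), bt$uncertainty + 1)
  expect_equal(unname(co["b1"]), b1, tolerance = 0.35)
})

test_that("bootstrap: zero-variance outcomes give zero uncertainty, seeds reproduce", {
  out <- makeOutcomes(c(0.2, 0.5, 0.8), c(55, 65, 75))
  b1 <- bootstrapD50(out, nBoot = 50, seed = 9)
  b2 <- bootstrapD50(out, nBoot = 50, seed = 9)
  expect_identical(b1$d50, b2$d50)
  ## all-identical outcomes within each level and a degenerate fit:
  ## resampling cannot change anything, so the spread collapses
  outStep <- makeOutcomes(c(0, 0.5, 1), c(60, 70, 80))
  outStep$controlled[outStep$dose == 70] <-
    rep(c(TRUE, FALSE), 5)   # only mixed level is exactly half
  bs <- bootstrapD50(outStep, nBoot = 30, seed = 1)
  expect_true(bs$uncertainty >= 0)
})

test_that("treatment gain is the D50 difference and antisymmetric", {
  expect_equal(treatmentGain(68.6, 64.2), 4.4)
  expect_equal(treatmentGain(64.2, 68.6), -4.4)
  expect_equal(treatmentGain(70, 70), 0)
  r <- new("TCPResult", table = data.frame(dose = 1, controlled = 0L, n = 1L),
           coefficients = c(b0 = -21, b1 = 0.3), d50 = 70,
           d50Uncertainty = 1, scheme = "1F", objective = "surv")
  expect_equal(treatmentGain(72, r), 2)
})

test_that("population simulation is bookkept per level and deterministic kills give step control", {
  lk <- analyticLookup()
  K <- 1e6 * 1.124^3
  g <- makeTestGrid(rep(0.5 * K, 8), oxicRow(), dims = c(2, 2, 2),
                    capillary = 0.06 * K)
  g <- updateOxygenation(g, analyticLookup())
  out <- simulatePopulation(g, "uniform", "uniform", NULL,
                            doseLevels = c(8, 12, 16), nPerDose = 4,
                            lq = lqParams(sigmaAlpha = 0), lookup = lk,
                            stochastic = FALSE, seed = 1)
  expect_equal(nrow(out), 12)
  expect_equal(as.integer(table(out$dose)), rep(4L, 3))
  ## no population variance, no kill stochasticity: each level all-or-nothing
  rates <- tapply(out$controlled, out$dose, mean)
  expect_true(all(rates %in% c(0, 1)))
  expect_true(all(diff(rates) >= 0))
})

test_that("control rates rise with dose in a stochastic population", {
  lk <- analyticLookup()
  K <- 1e6 * 1.124^3
  g <- makeTestGrid(rep(0.002 * K, 8), oxicRow(), dims = c(2, 2, 2),
                    capillary = 0.06 * K)
  g <- updateOxygenation(g, analyticLookup())
  out <- simulatePopulation(g, "uniform", "uniform", NULL,
                            doseLevels = c(6, 12, 18), nPerDose = 12,
                            lq = lqParams(), lookup = lk, seed = 3)
  rates <- tapply(out$controlled, out$dose, mean)
  expect_lte(rates[1], rates[3])
  expect_gt(rates[3], 0.5)
})
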