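## Constrained dose redistribution: gradients, oracles, feasibility.

lq <- lqParams(); oerp <- oerParams()
b <- histogramBins(40)

twoVoxelGrid <- function(viable = c(1e5, 1e5)) {
  ## voxel 1 anoxic, voxel 2 fully oxic (single-bin histograms)
  makeTestGrid(viable, rbind(anoxicRow(), oxicRow()))
}

test_that("objective gradients match central finite differences", {
  set.seed(3)
  n <- 6
  W <- matrix(runif(n * 16), n, 16); W <- W / rowSums(W)
  g <- makeTestGrid(runif(n, 1e4, 1e6), W)
  d <- runif(n, 1.6, 2.4)
  for (f in list(objectiveSurv, objectiveStd)) {
    v <- f(d, g, lq, oerp, voxels = seq_len(n), gradient = TRUE)
    gan <- attr(v, "gradient")
    gfd <- vapply(seq_len(n), function(i) {
      h <- 1e-5; dp <- d; dm <- d
      dp[i] <- d[i] + h; dm[i] <- d[i] - h
      (as.numeric(f(dp, g, lq, oerp, voxels = seq_len(n))) -
         as.numeric(f(dm, g, lq, oerp, voxels = seq_len(n)))) / (2 * h)
    }, 0)
    expect_lt(max(abs(gan - gfd) / pmax(abs(gfd), 1e-8)), 1e-6)
  }
})

test_that("survival objective: zero cells give zero, uniform beats feasible perturbations on a symmetric oxic toy", {
  g0 <- makeTestGrid(c(0, 0), rbind(oxicRow(), oxicRow()))
  expect_equal(objectiveSurv(c(1.5, 2.5), g0, lq, oerp, voxels = 1:2), 0)
  g <- makeTestGrid(c(1e5, 1e5), rbind(oxicRow(), oxicRow()))
  base <- objectiveSurv(c(2, 2), g, lq, oerp, voxels = 1:2)
  for (eps in c(0.1, 0.3, 0.5))
    expect_lt(base, objectiveSurv(c(2 - eps, 2 + eps), g, lq, oerp, voxels = 1:2))
})

test_that("heterogeneity objective: zero at identical voxels, permutation invariant, matches a 3-voxel hand computation", {
  g <- makeTestGrid(c(1e5, 1e5), rbind(oxicRow(), oxicRow()))
  expect_equal(as.numeric(objectiveStd(c(2, 2), g, lq, oerp, voxels = 1:2)), 0)
  viable <- c(1e5, 2e5, 3e5)
  W <- rbind(anoxicRow(), oxicRow(), anoxicRow())
  g3 <- makeTestGrid(viable, W)
  s <- vapply(1:3, function(i)
    voxelSurvivors(viable[i], oxygenHistogram(b$centers, W[i, ]), 2, lq, oerp), 0)
  expect_equal(as.numeric(objectiveStd(rep(2, 3), g3, lq, oerp, voxels = 1:3)),
               sd(s), tolerance = 1e-12)
  ## permutation of voxel order leaves the objective unchanged
  perm <- c(3, 1, 2)
  gp <- makeTestGrid(viable[perm], W[perm, ])
  expect_equal(as.numeric(objectiveStd(rep(2, 3), gp, lq, oerp, voxels = 1:3)),
               as.numeric(objectiveStd(rep(2, 3), g3, lq, oerp, voxels = 1:3)),
               tolerance = 1e-12)
})

test_that("uniform plan is feasible, constant and grid-independent", {
  g <- twoVoxelGrid()
  p <- uniformPlan(g, 2)
  expect_true(validObject(p))
  expect_equal(mean(p@doses, na.rm = TRUE), 2)
  g2 <- makeTestGrid(c(5, 5e5), rbind(oxicRow(), oxicRow()))
  expect_equal(doses(uniformPlan(g2, 2))[!is.na(doses(uniformPlan(g2, 2)))],
               doses(p)[!is.na(doses(p))])
})

test_that("optimizer matches exhaustive search on the two-voxel toy, both count regimes", {
  for (viable in list(c(1e5, 1e5), c(8e5, 1e5))) {
    g <- twoVoxelGrid(viable)
    plan <- optimizeDose(g, "surv")
    d1 <- seq(1.5, 2.5, by = 1e-3)
    obj <- vapply(d1, function(x)
      objectiveSurv(c(x, 4 - x), g, lq, oerp, voxels = 1:2), 0)
    best <- d1[which.min(obj)]
    expect_lt(abs(plan@doses[1] - best), 2e-3)
    expect_lte(plan@report$objective_final, min(obj) + 1e-6)
  }
})

test_that("the dose boost moves to the hypoxic voxel once hypoxic cells dominate survival", {
  ## plentiful sensitive cells: the oxic voxel has the higher marginal kill
  gEqual <- twoVoxelGrid(c(1e5, 1e5))
  pEqual <- optimizeDose(gEqual, "surv")
  expect_gt(pEqual@doses[2], pEqual@doses[1])
  ## hypoxic cells dominate (as after the first fractions of a course)
  gHyp <- twoVoxelGrid(c(8e5, 1e5))
  pHyp <- optimizeDose(gHyp, "surv")
  expect_gt(pHyp@doses[1], pHyp@doses[2])
})

test_that("homogeneous well-oxygenated tumors get the uniform plan back", {
  g <- makeTestGrid(rep(1e5, 8), oxicRow(), dims = c(2, 2, 2))
  plan <- optimizeDose(g, "surv")
  expect_lt(max(abs(plan@doses[1:8] - 2)), 1e-3)
})

test_that("KKT and augmented-Lagrangian solvers agree on random instances", {
  set.seed(17)
  for (rep in 1:3) {
    n <- 8
    W <- matrix(runif(n * 16)^3, n, 16); W <- W / rowSums(W)
    g <- makeTestGrid(runif(n, 1e4, 1e6), W)
    pk <- optimizeDose(g, "surv", method = "kkt")
    pg <- optimizeDose(g, "surv", method = "general")
    expect_lt(max(abs(pk@doses[1:n] - pg@doses[1:n])), 1e-3)
  }
})

test_that("every emitted plan satisfies the mean and box constraints", {
  set.seed(23)
  for (objective in c("surv", "std")) {
    n <- 12
    W <- matrix(runif(n * 16), n, 16); W <- W / rowSums(W)
    g <- makeTestGrid(runif(n, 1e4, 1e6), W)
    plan <- optimizeDose(g, objective)
    d <- plan@doses[1:n]
    expect_true(all(d >= 1.5 - 1e-6 & d <= 2.5 + 1e-6))
    expect_lt(abs(mean(d) - 2), 1e-6)
    expect_lte(plan@report$objective_final,
               plan@report$objective_uniform + 1e-9)
  }
})

test_that("re-optimizing a converged plan leaves the objective unchanged", {
  g <- twoVoxelGrid(c(8e5, 1e5))
  p1 <- optimizeDose(g, "surv")
  p2 <- optimizeDose(g, "surv")
  expect_lt(abs(p1@report$objective_final - p2@report$objective_final), 1e-9)
  expect_equal(p1@doses, p2@doses, tolerance = 1e-12)
})

test_that("optimization on an empty grid is an error", {
  g <- makeTestGrid(c(0, 0), rbind(oxicRow(), oxicRow()))
  expect_error(optimizeDose(g, "surv"), "viable")
})
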