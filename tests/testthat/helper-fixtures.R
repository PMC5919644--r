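## Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

## Analytic two-bin lookup: every histogram splits weight between an anoxic
## and a fully oxic bin, linearly in vf (clipped), independent of s. Lets
## grid machinery be tested without running the pO2 solver.
analyticLookup <- function() {
  if (!is.null(.fixtures$analytic)) return(.fixtures$analytic)
  b <- histogramBins(40)
  vfGrid <- c(0, 0.02, 0.06, 0.2)
  sGrid <- c(0, 1)
  oxicShare <- c(0, 0.3, 0.9, 1)      # share of the top bin per vf node
  W <- array(0, dim = c(4, 2, 16))
  for (i in 1:4) for (j in 1:2) {
    w <- numeric(16)
    w[1] <- 1 - oxicShare[i]
    w[16] <- oxicShare[i]
    W[i, j, ] <- w
  }
  lk <- new("OxygenLookup", vfGrid = vfGrid, sGrid = sGrid,
            binCenters = b$centers, weights = W, params = tomParams())
  .fixtures$analytic <- lk
  lk
}

## Small real lookup from the reaction-diffusion solver (coarse numerics).
solverLookup <- function() {
  if (!is.null(.fixtures$solver)) return(.fixtures$solver)
  params <- tomParams(gridResolution = 48L)
  lk <- buildOxygenLookup(vfGrid = c(0, 0.005, 0.015, 0.03, 0.06, 0.13, 0.3),
                          sGrid = c(0, 0.25, 0.5, 1),
                          params = params, nSeeds = 3, seed = 11)
  .fixtures$solver <- lk
  lk
}

## Reference tumor grown once per session with the solver lookup.
referenceTumor <- function() {
  if (!is.null(.fixtures$t1)) return(.fixtures$t1)
  .fixtures$t1 <- growReferenceTumor(bioParams(), solverLookup())
  .fixtures$t1
}

## Hand-built grid: dims lattice, given viable counts and per-voxel
## histogram rows (matrix with one row per voxel or a single row recycled).
makeTestGrid <- function(viable, weights, dims = NULL, voxelSide = 1.124,
                         capillary = 0, dead = 0, mu = 1e6) {
  n <- length(viable)
  if (is.null(dims)) dims <- c(n, 1L, 1L)
  stopifnot(prod(dims) == n)
  b <- histogramBins(40)
  W <- matrix(0, n, 16)
  if (is.matrix(weights)) {
    W[] <- weights[rep_len(seq_len(nrow(weights)), n), ]
  } else W[] <- matrix(weights, n, 16, byrow = TRUE)
  new("TumorGrid", dims = as.integer(dims), voxelSide = voxelSide,
      viable = as.numeric(viable), dead = rep_len(as.numeric(dead), n),
      capillary = rep_len(as.numeric(capillary), n),
      weights = W, binCenters = b$centers,
      capacity = mu * voxelSide^3, time = 0)
}

## Histogram row with all weight in the bin nearest a target pO2.
binRow <- function(p, p0 = 40) {
  b <- histogramBins(p0)
  w <- numeric(16)
  w[which.min(abs(b$centers - p))] <- 1
  w
}

## Fully oxic histogram row (top bin, center ~p0).
oxicRow <- function() { w <- numeric(16); w[16] <- 1; w }
anoxicRow <- function() { w <- numeric(16); w[1] <- 1; w }
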