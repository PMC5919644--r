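## Virtual tumor generation: grow the reference tumor T1 with the response
## model itself, then derive the uniform-profile variants T2-T4.

#' Virtual tumor specification
#'
#' Selects uniform or non-uniform radial profiles for the tumor cell density
#' rho and the vascular fraction vf. The reference geometry is a sphere of
#' roughly 2 cm diameter: a 1 cm hypoxic core plus a 0.5 cm better
#' oxygenated rim.
#'
#' @param densityProfile "nonuniform" (emergent from growth) or "uniform"
#' @param vfProfile "nonuniform" or "uniform"
#' @param uniformVf vf used for uniform profiles (6% is representative of
#'   well-oxygenated tumors)
#' @param coreDiameter hypoxic core diameter (cm)
#' @param rimWidth rim width (cm)
#' @return a list spec
#' @export
tumorSpec <- function(densityProfile = c("nonuniform", "uniform"),
                      vfProfile = c("nonuniform", "uniform"),
                      uniformVf = 0.06, coreDiameter = 1, rimWidth = 0.5) {
  densityProfile <- match.arg(densityProfile)
  vfProfile <- match.arg(vfProfile)
  if (uniformVf <= 0 || uniformVf > 0.2) stop("uniformVf must be in (0, 0.2]")
  list(densityProfile = densityProfile, vfProfile = vfProfile,
       uniformVf = uniformVf, coreDiameter = coreDiameter,
       rimWidth = rimWidth,
       diameter = coreDiameter + 2 * rimWidth)
}

## Empty host lattice: un-invaded tissue carries host vasculature only.
emptyHostGrid <- function(dims = c(23L, 23L, 23L), voxelSide = 1.124,
                          bio = bioParams(), lookup) {
  n <- prod(dims)
  nb <- length(lookup@binCenters)
  K <- bio@mu * voxelSide^3
  W <- matrix(0, n, nb); W[, nb] <- 1   # placeholder; refreshed for mask voxels
  new("TumorGrid", dims = as.integer(dims), voxelSide = voxelSide,
      viable = numeric(n), dead = numeric(n),
      capillary = rep(bio@hostVf * K, n),
      weights = W, binCenters = lookup@binCenters, capacity = K, time = 0)
}

#' Grow the reference virtual tumor (T1)
#'
#' Starting from a single cell in the central voxel of a vascularized host
#' lattice, the response-model stepper (no irradiation) is iterated until the
#' tumor holds `targetVoxels` voxels. Crowding-driven vascular collapse
#' competing with hypoxia-induced angiogenesis carves a low-vf hypoxic core,
#' while the advancing frontier leaves the rim well perfused; the cell
#' density decreases toward the border where voxels are still filling. On the
#' stop day the `targetVoxels` voxels holding the most tumor cells define the
#' tumor (trimmed frontier voxels hold negligible mass).
#'
#' @param bio a [BioParams-class]
#' @param lookup an [OxygenLookup-class]
#' @param spec a [tumorSpec()] (profiles must be "nonuniform")
#' @param dims bounding lattice dimensions
#' @param voxelSide voxel edge (mm)
#' @param targetVoxels tumor voxel count to reach (3888 = ~2 cm sphere)
#' @param maxDays growth horizon before a generation error (days)
#' @return a [TumorGrid-class] with time reset to 0 (treatment start)
#' @export
growReferenceTumor <- function(bio = bioParams(), lookup,
                               spec = tumorSpec(), dims = c(23L, 23L, 23L),
                               voxelSide = 1.124, targetVoxels = 3888L,
                               maxDays = 1500L) {
  if (spec$densityProfile != "nonuniform" || spec$vfProfile != "nonuniform")
    stop("the reference tumor is grown with nonuniform profiles; use makeVariant()")
  grid <- emptyHostGrid(dims, voxelSide, bio, lookup)
  ctr <- floor(dims / 2) + 1
  ctrIdx <- (ctr[3] - 1) * dims[1] * dims[2] + (ctr[2] - 1) * dims[1] + ctr[1]
  grid@viable[ctrIdx] <- 1
  grid <- updateOxygenation(grid, lookup)
  for (day in seq_len(maxDays)) {
    grid <- stepDay(grid, plan = NULL, bio = bio, lookup = lookup,
                    stochastic = FALSE, duringGrowth = TRUE)
    if (sum(tumorMask(grid)) >= targetVoxels) break
  }
  nMask <- sum(tumorMask(grid))
  if (nMask < targetVoxels)
    stop("tumor did not reach ", targetVoxels, " voxels within ",
         maxDays, " days (reached ", nMask, ")")
  ## trim to exactly targetVoxels, dropping the emptiest frontier voxels
  tumor <- grid@viable + grid@dead
  keep <- order(tumor, decreasing = TRUE)[seq_len(targetVoxels)]
  drop <- setdiff(which(tumor >= 1), keep)
  grid@viable[drop] <- 0
  grid@dead[drop] <- 0
  grid <- updateOxygenation(grid, lookup)
  grid@time <- 0
  grid
}

#' Derive a virtual tumor variant from the reference tumor
#'
#' Uniform-density variants set every tumor voxel to the same cell count
#' (total tumor cells of the reference divided by the voxel count, so the
#' total is preserved exactly); uniform-vf variants set the vascular fraction
#' to `spec$uniformVf` in every tumor voxel. With both profiles "nonuniform"
#' the reference is returned unchanged.
#'
#' @param t1 the reference [TumorGrid-class] from [growReferenceTumor()]
#' @param spec a [tumorSpec()]
#' @param lookup an [OxygenLookup-class] used to refresh histograms
#' @return a [TumorGrid-class]
#' @export
makeVariant <- function(t1, spec, lookup) {
  grid <- t1
  m <- which(tumorMask(grid))
  if (spec$densityProfile == "uniform") {
    tot <- sum(grid@viable[m]) + sum(grid@dead[m])
    grid@viable[m] <- tot / length(m)
    grid@dead[m] <- 0
  }
  if (spec$vfProfile == "uniform") {
    grid@capillary[m] <- spec$uniformVf * grid@capacity
  }
  updateOxygenation(grid, lookup)
}

#' Generate the four virtual tumors of the simulation studies
#'
#' T1: non-uniform density and vf (grown); T2: both uniform; T3: uniform
#' density, non-uniform vf; T4: non-uniform density, uniform vf. All four
#' hold the same total number of tumor cells.
#'
#' @inheritParams growReferenceTumor
#' @param uniformVf vf of the uniform profiles
#' @return named list of four [TumorGrid-class] objects
#' @export
virtualTumors <- function(bio = bioParams(), lookup, uniformVf = 0.06, ...) {
  t1 <- growReferenceTumor(bio, lookup, tumorSpec(), ...)
  list(
    T1 = t1,
    T2 = makeVariant(t1, tumorSpec("uniform", "uniform", uniformVf), lookup),
    T3 = makeVariant(t1, tumorSpec("uniform", "nonuniform", uniformVf), lookup),
    T4 = makeVariant(t1, tumorSpec("nonuniform", "uniform", uniformVf), lookup)
  )
}

#' Shell-averaged radial profile of density or vascular fraction
#'
#' @param grid a [TumorGrid-class]
#' @param quantity "density" (cells/mm^3) or "vf"
#' @param binWidth shell width (mm); defaults to the voxel side
#' @return data.frame with radius (shell mid, mm), mean, n (voxels)
#' @export
radialProfile <- function(grid, quantity = c("density", "vf"),
                          binWidth = grid@voxelSide) {
  quantity <- match.arg(quantity)
  m <- which(tumorMask(grid))
  if (length(m) == 0) stop("grid has no tumor voxels")
  r <- voxelRadius(grid)[m]
  val <- if (quantity == "density") {
    (grid@viable[m] + grid@dead[m]) / grid@voxelSide^3
  } else {
    vascularFraction(grid)[m]
  }
  shell <- floor(r / binWidth)
  agg <- tapply(val, shell, mean)
  cnt <- tapply(val, shell, length)
  data.frame(radius = (as.numeric(names(agg)) + 0.5) * binWidth,
             mean = as.numeric(agg), n = as.integer(cnt))
}
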