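## Tumor response model: the biological processes iterated over the
## treatment timeline on the voxel lattice.

## Face-neighbor linear indices for a lattice; 0 marks "outside". Cached.
neighborIndex <- function(dims) {
  key <- paste0("nb_", paste(dims, collapse = "x"))
  if (!is.null(.dpbnsimCache[[key]])) return(.dpbnsimCache[[key]])
  n <- prod(dims)
  idx <- arrayInd(seq_len(n), dims)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- matrix(0L, n, 6)
  for (k in 1:6) {
    tgt <- sweep(idx, 2, shifts[k, ], "+")
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= dims[1] &
      tgt[, 2] >= 1 & tgt[, 2] <= dims[2] &
      tgt[, 3] >= 1 & tgt[, 3] <= dims[3]
    lin <- rep(0L, n)
    lin[ok] <- as.integer((tgt[ok, 3] - 1) * dims[1] * dims[2] +
                            (tgt[ok, 2] - 1) * dims[1] + tgt[ok, 1])
    nb[, k] <- lin
  }
  .dpbnsimCache[[key]] <- nb
  nb
}

## Effective tumor doubling time at the grid's clock (accelerated
## repopulation switches tp two weeks into treatment).
effectiveTp <- function(time, bio, duringGrowth = FALSE) {
  if (duringGrowth) return(bio@tpGrowth)
  if (time / 24 >= bio@accelSwitchDay) bio@tpAccelerated else bio@tpInitial
}

#' Tumor cell proliferation
#'
#' Viable cells grow as viable * 2^(dt/tp); tp is the initial doubling time
#' before the accelerated-repopulation switch day and the accelerated one
#' after. Growth is space-limited: a voxel may fill up to
#' growthHeadroom * capacity (the excess is redistributed by
#' [exchangeCells()]).
#'
#' @param grid a [TumorGrid-class]
#' @param dt time step (h)
#' @param bio a [BioParams-class]
#' @param duringGrowth use the tumor-generation doubling time
#' @return the updated grid
#' @export
proliferate <- function(grid, dt, bio, duringGrowth = FALSE) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(grid)
  tp <- effectiveTp(grid@time, bio, duringGrowth)
  K <- voxelCapacity(grid)
  act <- which(grid@viable > 0)
  if (length(act) == 0) return(grid)
  v <- grid@viable[act]
  grown <- v * 2^(dt / tp)
  ceiling_ <- pmax(v, bio@growthHeadroom * K -
                     grid@dead[act] - grid@capillary[act])
  grid@viable[act] <- pmin(grown, ceiling_)
  grid
}

#' Hypoxia-induced angiogenesis
#'
#' Capillary cells double with time ta in voxels whose histogram median pO2
#' lies below the hypoxia threshold; well-oxygenated voxels are unchanged.
#'
#' @inheritParams proliferate
#' @return the updated grid
#' @export
angiogenesis <- function(grid, dt, bio) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(grid)
  act <- which(grid@viable + grid@dead > 1e-9)
  if (length(act) == 0) return(grid)
  ## median pO2 < threshold iff at least half the weight sits in bins whose
  ## centers lie below the threshold
  low <- which(grid@binCenters < bio@hypoxiaThreshold)
  lowMass <- rowSums(grid@weights[act, low, drop = FALSE])
  hyp <- act[lowMass >= 0.5]
  grid@capillary[hyp] <- grid@capillary[hyp] * 2^(dt / bio@ta)
  grid
}

#' Pressure-induced vascular collapse
#'
#' Capillaries halve with time tCollapse in tumor voxels whose occupancy
#' exceeds collapseOccupancy * capacity and whose tissue is predominantly
#' viable. Solid stress is generated by crowded *proliferating* tissue, so
#' the collapse rate scales with the current proliferation rate (the ratio
#' of the tumor-generation doubling time to the effective one): full
#' strength while a virtual tumor grows, an order of magnitude weaker under
#' the slow pre-switch proliferation of early treatment. This crowding-
#' driven vessel loss is what carves the low-vf hypoxic core out of the
#' initially well-perfused host tissue; it competes with [angiogenesis()].
#'
#' @inheritParams proliferate
#' @return the updated grid
#' @export
vascularCollapse <- function(grid, dt, bio, duringGrowth = FALSE) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(grid)
  K <- voxelCapacity(grid)
  occ <- grid@viable + grid@dead + grid@capillary
  crowd <- which(occ >= bio@collapseOccupancy * K &
                   grid@viable > 0.5 * occ &
                   grid@viable + grid@dead > 1e-9)
  rate <- min(1, bio@tpGrowth / effectiveTp(grid@time, bio, duringGrowth))
  grid@capillary[crowd] <- grid@capillary[crowd] * 2^(-dt * rate / bio@tCollapse)
  grid
}

#' Oxygen-dependent radiation kill
#'
#' Applies one fraction of the dose plan. Expected survivors per voxel follow
#' the oxygen-dependent LQ model summed over the histogram bins; realized
#' survivors are drawn as Binomial(viable, mean SF) in voxels holding fewer
#' than `stochasticThreshold` viable cells (cell-killing stochasticity
#' matters only when cell numbers are small) and kept at the expected value
#' otherwise. In expected-value mode (`stochastic = FALSE`) a voxel whose
#' expected survivors fall below one whole cell is emptied: a voxel cannot
#' hold a fraction of a cell, so sub-cell expectation tails do not linger.
#' Killed cells move from viable to dead; viable + dead is conserved.
#'
#' @param grid a [TumorGrid-class]
#' @param plan a [DosePlan-class]; mask voxels missing from the plan receive
#'   the constraint mean dose
#' @param lq an [LQParams-class]
#' @param oerp an [OERParams-class]
#' @param stochastic draw binomial survivors in small voxels
#' @param stochasticThreshold viable-cell count below which kill is binomial
#' @return the updated grid
#' @export
irradiate <- function(grid, plan, lq = lqParams(), oerp = oerParams(),
                      stochastic = TRUE, stochasticThreshold = 1e4) {
  act <- which(grid@viable > 0)
  if (length(act) == 0) return(grid)
  d <- plan@doses[act]
  d[is.na(d)] <- plan@constraints@meanDose
  if (any(d < 0) || any(d > 10)) stop("fraction dose outside [0, 10] Gy")
  sbar <- meanSurvival(d, grid@weights[act, , drop = FALSE],
                       grid@binCenters, lq, oerp)
  v <- grid@viable[act]
  surv <- v * sbar
  small <- v < stochasticThreshold
  if (any(small)) {
    if (stochastic) {
      nInt <- round(v[small])
      surv[small] <- rbinom(length(nInt), nInt, pmin(1, sbar[small]))
    } else {
      ## a voxel cannot hold a fraction of a cell: expected survivor
      ## tails below one whole cell are extinguished, larger expectations
      ## stay real-valued
      sm <- surv < 1
      surv[sm] <- 0
    }
  }
  grid@dead[act] <- grid@dead[act] + (v - surv)
  grid@viable[act] <- surv
  grid
}

#' Resorption of dead cells
#'
#' Dead cells decay exponentially with half time tr.
#'
#' @inheritParams proliferate
#' @return the updated grid
#' @export
resorbDead <- function(grid, dt, bio) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(grid)
  grid@dead <- grid@dead * 2^(-dt / bio@tr)
  grid
}

#' Spatial exchange of cells between neighboring voxels
#'
#' Two conservative moves. Voxels above capacity push their whole excess of
#' tumor cells (viable + dead, moved proportionally; vessels do not invade)
#' to face neighbors in proportion to the neighbors' free space -- active
#' invasion driving tumor growth. Tumor voxels below capacity pull a
#' fraction `pullRate` of their deficit per day from the tissue of
#' neighboring tumor voxels that are no more occupied than themselves
#' (viable, dead and capillary cells in proportion to the donor's
#' composition) -- cohesive compaction of the shrinking tumor: the sparse
#' dying boundary is absorbed into the denser interior, which refills
#' resorbed space and concentrates the vasculature of the absorbed tissue. Compaction
#' is inactive while the tumor grows (no interior deficit exists) and never
#' seeds new voxels; lattice-wide totals of each compartment are conserved.
#'
#' @param grid a [TumorGrid-class]
#' @param bio a [BioParams-class]
#' @return the updated grid
#' @export
exchangeCells <- function(grid, bio) {
  nb <- neighborIndex(grid@dims)
  res <- exchangeKernel(grid@viable, grid@dead, grid@capillary, nb,
                        voxelCapacity(grid), bio@pullRate)
  grid@viable <- res$viable
  grid@dead <- res$dead
  grid@capillary <- res$capillary
  grid
}

#' Refresh per-voxel oxygen histograms from the lookup table
#'
#' Each tumor voxel's histogram is replaced by the lookup interpolation at
#' its current vascular fraction and consuming-cell fraction; empty voxels
#' are skipped.
#'
#' @param grid a [TumorGrid-class]
#' @param lookup an [OxygenLookup-class]
#' @return the updated grid
#' @export
updateOxygenation <- function(grid, lookup) {
  act <- which(grid@viable + grid@dead > 1e-9)
  if (length(act) == 0) return(grid)
  vf <- grid@capillary[act] / grid@capacity
  s <- pmin(1, grid@viable[act] / grid@capacity)
  grid@weights[act, ] <- lookupWeightsMatrix(lookup, vf, s)
  grid
}

#' Advance the tumor one calendar day
#'
#' Applies, in order: radiation kill (if a fraction is scheduled),
#' proliferation, angiogenesis, vascular collapse, dead-cell resorption,
#' cell exchange and oxygenation refresh, then advances the clock by 24 h.
#'
#' @param grid a [TumorGrid-class]
#' @param plan a [DosePlan-class] for today's fraction, or NULL on rest days
#' @param bio a [BioParams-class]
#' @param lq an [LQParams-class]
#' @param oerp an [OERParams-class]
#' @param lookup an [OxygenLookup-class]
#' @param stochastic binomial kill in small voxels (see [irradiate()])
#' @param duringGrowth use the tumor-generation doubling time
#' @return the updated grid
#' @export
stepDay <- function(grid, plan = NULL, bio = bioParams(), lq = lqParams(),
                    oerp = oerParams(), lookup, stochastic = TRUE,
                    duringGrowth = FALSE) {
  if (!is.null(plan))
    grid <- irradiate(grid, plan, lq, oerp, stochastic = stochastic)
  grid <- proliferate(grid, 24, bio, duringGrowth)
  grid <- angiogenesis(grid, 24, bio)
  grid <- vascularCollapse(grid, 24, bio, duringGrowth)
  grid <- resorbDead(grid, 24, bio)
  grid <- exchangeCells(grid, bio)
  grid <- updateOxygenation(grid, lookup)
  grid@time <- grid@time + 24
  grid
}
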