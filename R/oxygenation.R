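## Tumor oxygenation model: microscopic pO2 fields in a voxel cross-section,
## condensed to 16-bin histograms and pre-tabulated over (vf, s).

#' Histogram bin edges and centers
#'
#' 16 bins: an explicit anoxic bin [0, 0.01) mmHg followed by 15 log-spaced
#' bins from 0.01 mmHg up to the intravascular pO2, resolving the
#' radiobiologically critical 0-10 mmHg range.
#'
#' @param p0 intravascular pO2 (mmHg)
#' @param nBins number of bins (16)
#' @return list with `edges` (nBins + 1) and `centers` (nBins)
#' @export
histogramBins <- function(p0 = 40, nBins = 16) {
  edges <- c(0, 0.01 * (p0 / 0.01)^(seq(0, nBins - 1) / (nBins - 1)))
  centers <- c(0, sqrt(edges[2:nBins] * edges[3:(nBins + 1)]))
  list(edges = edges, centers = centers)
}

## Random non-overlapping vessel disk centers on a periodic square, and the
## pixel mask they cover. Returns list(mask, nVessels).
placeVessels <- function(vf, params, rng) {
  n <- params@gridResolution
  side <- params@domainSide
  h <- side / n
  r <- params@vesselRadius
  nVessel <- round(vf * side^2 / (pi * r^2))
  mask <- matrix(0L, n, n)
  if (nVessel == 0) return(list(mask = mask, nVessels = 0L))
  centers <- matrix(NA_real_, nVessel, 2)
  placed <- 0L
  tries <- 0L
  while (placed < nVessel && tries < 200L * nVessel) {
    tries <- tries + 1L
    cand <- runif(2, 0, side)
    if (placed > 0) {
      dx <- abs(centers[seq_len(placed), 1] - cand[1])
      dy <- abs(centers[seq_len(placed), 2] - cand[2])
      dx <- pmin(dx, side - dx)
      dy <- pmin(dy, side - dy)
      if (min(dx^2 + dy^2) < (2 * r)^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  if (placed < nVessel)
    warning("could only place ", placed, " of ", nVessel, " vessels")
  centers <- centers[seq_len(placed), , drop = FALSE]
  px <- (seq_len(n) - 0.5) * h
  ## each vessel occupies the k pixels nearest its center, with k chosen so
  ## the pixelated vessel area matches pi r^2: the oxygen source area is
  ## then independent of the grid resolution (plain thresholding loses
  ## whole vessels on coarse grids and converges only linearly in h)
  k <- max(1L, round(pi * r^2 / h^2))
  for (v in seq_len(placed)) {
    dx <- abs(px - centers[v, 1]); dx <- pmin(dx, side - dx)
    dy <- abs(px - centers[v, 2]); dy <- pmin(dy, side - dy)
    d2 <- outer(dx^2, dy^2, "+")
    hit <- order(d2)[seq_len(k)]
    mask[hit] <- 1L
  }
  list(mask = mask, nVessels = placed)
}

#' Solve the steady-state microscopic pO2 field of a voxel
#'
#' Reaction-diffusion steady state on a 2-D periodic cross-section (parallel
#' vessels reduce the 3-D problem to 2-D): oxygen diffuses from randomly
#' placed vessel disks clamped at the intravascular pO2 and is consumed by
#' viable cells following Michaelis-Menten kinetics
#' M(p) = Mmax * s * p / (p + km), with s the consuming-cell volume fraction.
#'
#' @param vf vascular fraction in [0, 0.5]
#' @param s consuming-cell volume fraction in [0, 1] (1 - dead fraction at
#'   full packing)
#' @param params a [TOMParams-class]
#' @param seed integer seed for vessel placement
#' @param tol convergence tolerance on the max update (mmHg)
#' @param maxIter maximum SOR sweeps
#' @return list with `field` (matrix, mmHg), `vesselMask` (0/1 matrix),
#'   `iterations`
#' @export
solvePO2Field <- function(vf, s, params = tomParams(), seed = 1,
                          tol = 1e-3, maxIter = 50000L) {
  if (vf < 0 || vf > 0.5) stop("vf must be in [0, 0.5]")
  if (s < 0 || s > 1) stop("s must be in [0, 1]")
  n <- params@gridResolution
  p0 <- params@intravascularPO2
  set.seed(seed)
  vp <- placeVessels(vf, params, NULL)
  consumption <- params@consumptionRateMax * s
  if (vp$nVessels == 0) {
    ## no source: with any consumption the steady state is anoxic; without
    ## consumption the (degenerate) field is taken as anoxic too
    field <- matrix(0, n, n)
    return(list(field = field, vesselMask = vp$mask, iterations = 0L))
  }
  init <- matrix(p0, n, n)
  h <- params@domainSide / n
  field <- solvePO2SOR(init, vp$mask, h, params@diffusivity, consumption,
                       params@km, p0, as.integer(maxIter), tol, 1.9)
  if (attr(field, "residual") > tol)
    stop("pO2 solver did not converge: residual ",
         format(attr(field, "residual")), " mmHg after ", maxIter, " sweeps")
  list(field = field, vesselMask = vp$mask,
       iterations = attr(field, "iterations"))
}

#' Condense a pO2 field into a 16-bin histogram
#'
#' Area-weighted histogram over the extravascular pixels only.
#'
#' @param field pO2 matrix (mmHg)
#' @param vesselMask 0/1 matrix of vessel pixels (excluded); NULL for none
#' @param p0 intravascular pO2 defining the bin grid (mmHg)
#' @param nBins number of bins
#' @return an [OxygenHistogram-class]
#' @export
condenseHistogram <- function(field, vesselMask = NULL, p0 = 40, nBins = 16) {
  if (any(field < 0)) stop("field values must be non-negative")
  vals <- if (is.null(vesselMask)) as.numeric(field) else field[vesselMask == 0]
  if (length(vals) == 0) stop("empty extravascular region")
  b <- histogramBins(p0, nBins)
  idx <- findInterval(vals, b$edges, rightmost.closed = TRUE, all.inside = TRUE)
  w <- tabulate(idx, nbins = nBins) / length(vals)
  oxygenHistogram(b$centers, w)
}

#' Pre-tabulate oxygen histograms over vascular and consuming fractions
#'
#' Solves the microscopic pO2 field at every (vf, s) grid node, averaging
#' histogram weights over several random vessel placements, and stores the
#' result for fast interpolation during tumor simulation. The same vessel
#' layouts are reused across the s axis of one vf node.
#'
#' @param vfGrid strictly increasing vascular fractions (may start at 0)
#' @param sGrid strictly increasing consuming fractions
#' @param params a [TOMParams-class]
#' @param nSeeds vessel placements averaged per node
#' @param seed base seed
#' @param verbose print progress
#' @return an [OxygenLookup-class]
#' @export
buildOxygenLookup <- function(vfGrid, sGrid, params = tomParams(),
                              nSeeds = 8, seed = 1, verbose = FALSE) {
  if (length(vfGrid) == 0 || length(sGrid) == 0) stop("grids must be non-empty")
  p0 <- params@intravascularPO2
  b <- histogramBins(p0)
  nb <- length(b$centers)
  W <- array(0, dim = c(length(vfGrid), length(sGrid), nb))
  valSum <- numeric(nb); valN <- numeric(nb)
  for (i in seq_along(vfGrid)) {
    vf <- vfGrid[i]
    acc <- matrix(0, length(sGrid), nb)
    for (sd in seq_len(nSeeds)) {
      for (j in seq_along(sGrid)) {
        res <- tryCatch(
          solvePO2Field(vf, sGrid[j], params, seed = seed + 1000L * sd + i),
          error = function(e) stop("pO2 solve failed at vf=", vf, ", s=",
                                   sGrid[j], ": ", conditionMessage(e)))
        hg <- condenseHistogram(res$field, res$vesselMask, p0)
        acc[j, ] <- acc[j, ] + hg@weights
        vals <- if (length(res$vesselMask)) res$field[res$vesselMask == 0]
                else as.numeric(res$field)
        bi <- findInterval(vals, b$edges, rightmost.closed = TRUE,
                           all.inside = TRUE)
        valSum <- valSum + vapply(seq_len(nb),
                                  function(k) sum(vals[bi == k]), 0)
        valN <- valN + tabulate(bi, nb)
      }
    }
    W[i, , ] <- acc / nSeeds
    if (verbose) message("lookup node vf=", vf, " done")
  }
  ## effective bin centers: area-weighted mean pO2 of the field values that
  ## fell into each bin over all solves (the geometric center of a wide log
  ## bin understates the oxygenation of nearly uniform well-oxygenated
  ## fields); empty bins keep their nominal centers
  centers <- ifelse(valN > 0, valSum / pmax(valN, 1), b$centers)
  centers[1] <- 0                      # anoxic bin stays at 0
  if (any(diff(centers) <= 0)) centers <- b$centers
  new("OxygenLookup", vfGrid = vfGrid, sGrid = sGrid,
      binCenters = centers, weights = W, params = params)
}

## Bilinear interpolation of histogram weights for vectors of (vf, s),
## clipped to the grid range and renormalized. Returns an n x nbin matrix.
lookupWeightsMatrix <- function(lookup, vf, s) {
  gv <- lookup@vfGrid; gs <- lookup@sGrid
  nv <- length(gv); ns <- length(gs); nb <- length(lookup@binCenters)
  vfc <- pmin(pmax(vf, gv[1]), gv[nv])
  sc <- pmin(pmax(s, gs[1]), gs[ns])
  iv <- if (nv > 1) findInterval(vfc, gv, all.inside = TRUE) else rep(1L, length(vfc))
  is <- if (ns > 1) findInterval(sc, gs, all.inside = TRUE) else rep(1L, length(sc))
  fv <- if (nv > 1) (vfc - gv[iv]) / (gv[iv + 1L] - gv[iv]) else rep(0, length(vfc))
  fs <- if (ns > 1) (sc - gs[is]) / (gs[is + 1L] - gs[is]) else rep(0, length(sc))
  ivp <- pmin(iv + 1L, nv); isp <- pmin(is + 1L, ns)
  M <- matrix(lookup@weights, nrow = nv * ns, ncol = nb)
  row <- function(a, b) (b - 1L) * nv + a
  W <- (1 - fv) * (1 - fs) * M[row(iv, is), , drop = FALSE] +
    fv * (1 - fs) * M[row(ivp, is), , drop = FALSE] +
    (1 - fv) * fs * M[row(iv, isp), , drop = FALSE] +
    fv * fs * M[row(ivp, isp), , drop = FALSE]
  W / rowSums(W)
}

#' Retrieve the oxygen histogram for a voxel state
#'
#' Bilinear interpolation of stored histogram weights between neighboring
#' (vf, s) grid nodes, renormalized to sum 1; queries outside the grid are
#' clipped to its range.
#'
#' @param lookup an [OxygenLookup-class]
#' @param vf vascular fraction
#' @param s consuming-cell fraction
#' @return an [OxygenHistogram-class]
#' @export
lookupHistogram <- function(lookup, vf, s) {
  W <- lookupWeightsMatrix(lookup, vf, s)
  oxygenHistogram(lookup@binCenters, W[1, ])
}

#' Serialize / restore an oxygen lookup as JSON
#'
#' @param lookup an [OxygenLookup-class]
#' @param path file path
#' @return `readOxygenLookup` returns the restored [OxygenLookup-class]
#' @export
writeOxygenLookup <- function(lookup, path) {
  p <- lookup@params
  obj <- list(
    vfGrid = lookup@vfGrid, sGrid = lookup@sGrid,
    binCenters = lookup@binCenters,
    weights = as.numeric(lookup@weights),
    dim = dim(lookup@weights),
    params = list(intravascularPO2 = p@intravascularPO2,
                  vesselRadius = p@vesselRadius,
                  consumptionRateMax = p@consumptionRateMax, km = p@km,
                  diffusivity = p@diffusivity, domainSide = p@domainSide,
                  gridResolution = p@gridResolution))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOxygenLookup
#' @export
readOxygenLookup <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pp <- obj$params
  params <- tomParams(pp$intravascularPO2, pp$vesselRadius,
                      pp$consumptionRateMax, pp$km, pp$diffusivity,
                      pp$domainSide, pp$gridResolution)
  new("OxygenLookup", vfGrid = as.numeric(obj$vfGrid),
      sGrid = as.numeric(obj$sGrid), binCenters = as.numeric(obj$binCenters),
      weights = array(obj$weights, dim = obj$dim), params = params)
}

.dpbnsimCache <- new.env(parent = emptyenv())

#' Default oxygen lookup table
#'
#' Builds (once per session, then cached) the lookup used by the simulation
#' studies: vascular fractions 0-0.30, consuming fractions 0-1, default
#' [tomParams()]. With `quality = "coarse"` a lighter table (smaller solver
#' grid, fewer seeds) is built; useful for quick exploration.
#'
#' @param params a [TOMParams-class]
#' @param quality "standard" or "coarse"
#' @param seed base seed for vessel placements
#' @return an [OxygenLookup-class]
#' @export
defaultOxygenLookup <- function(params = tomParams(),
                                quality = c("standard", "coarse"), seed = 1) {
  quality <- match.arg(quality)
  key <- paste0("lookup_", quality, "_", seed, "_",
                paste(signif(c(params@intravascularPO2, params@vesselRadius,
                               params@consumptionRateMax, params@km,
                               params@diffusivity, params@domainSide,
                               params@gridResolution), 8), collapse = "_"))
  if (!is.null(.dpbnsimCache[[key]])) return(.dpbnsimCache[[key]])
  vfGrid <- c(0, 0.005, 0.01, 0.015, 0.02, 0.03, 0.045, 0.06,
              0.09, 0.13, 0.20, 0.30)
  sGrid <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  if (quality == "coarse") {
    params@gridResolution <- max(48L, params@gridResolution %/% 2L)
    nSeeds <- 3
  } else nSeeds <- 8
  lk <- buildOxygenLookup(vfGrid, sGrid, params, nSeeds = nSeeds, seed = seed)
  .dpbnsimCache[[key]] <- lk
  lk
}
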