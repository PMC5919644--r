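#' @import methods
#' @importFrom stats rbinom rnorm runif glm binomial coef fitted aggregate
#'   optim quantile sd setNames
#' @importFrom utils head tail write.csv
#' @useDynLib dpbnsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## Parameter value classes
## ---------------------------------------------------------------------------

#' Linear-quadratic radiosensitivity parameters
#'
#' Fully oxic radiosensitivities of the LQ model together with the
#' population standard deviation of alpha used for inter-patient variability.
#' The hypoxic parameters are derived quantities: \code{alpha_h = alpha/OERam}
#' and \code{beta_h = beta/OERbm^2} (see [hypoxicAlpha()]).
#'
#' @slot alpha fully oxic linear radiosensitivity (1/Gy)
#' @slot beta fully oxic quadratic radiosensitivity (1/Gy^2)
#' @slot sigmaAlpha population SD of alpha (1/Gy)
#' @export
setClass("LQParams", representation(
  alpha = "numeric", beta = "numeric", sigmaAlpha = "numeric"
))

setValidity("LQParams", function(object) {
  if (length(object@alpha) != 1 || object@alpha <= 0) return("alpha must be a single positive number")
  if (length(object@beta) != 1 || object@beta <= 0) return("beta must be a single positive number")
  if (length(object@sigmaAlpha) != 1 || object@sigmaAlpha < 0) return("sigmaAlpha must be >= 0")
  TRUE
})

#' Oxygen enhancement ratio parameters
#'
#' Maximum OER values reached under aerobic conditions for the linear and
#' quadratic LQ components, and the half-effect slope constant k (mmHg).
#'
#' @slot oerAlphaMax maximum OER for alpha (dimensionless, >= 1)
#' @slot oerBetaMax maximum OER for beta (dimensionless, >= 1)
#' @slot k pO2 at which the OER reaches the midpoint of its range (mmHg)
#' @export
setClass("OERParams", representation(
  oerAlphaMax = "numeric", oerBetaMax = "numeric", k = "numeric"
))

setValidity("OERParams", function(object) {
  if (object@oerAlphaMax < 1) return("oerAlphaMax must be >= 1")
  if (object@oerBetaMax < 1) return("oerBetaMax must be >= 1")
  if (object@k <= 0) return("k must be > 0")
  TRUE
})

#' Biological parameters of the tumor response model
#'
#' Doubling/half times are in hours; the simulation clock advances in whole
#' days. \code{accelSwitchDay} is the treatment day after which the
#' accelerated-repopulation doubling time replaces the initial one.
#'
#' @slot tpInitial tumor doubling time at treatment start (h)
#' @slot tpAccelerated doubling time after accelerated repopulation onset (h)
#' @slot accelSwitchDay days from treatment start at which tp switches
#' @slot ta capillary cell doubling time for angiogenesis (h)
#' @slot tr half time of dead cell resorption (h)
#' @slot mu average/maximum packing cell density (cells/mm^3)
#' @slot tpGrowth doubling time used while growing virtual tumors (h)
#' @slot hypoxiaThreshold median pO2 below which angiogenesis triggers (mmHg)
#' @slot tCollapse capillary halving time under crowding (h)
#' @slot collapseOccupancy occupancy fraction above which vessels collapse
#' @slot pullRate daily fraction of a voxel's deficit refilled by exchange
#' @slot growthHeadroom proliferation allowed up to headroom * capacity
#' @slot hostVf vascular fraction of un-invaded host tissue
#' @export
setClass("BioParams", representation(
  tpInitial = "numeric", tpAccelerated = "numeric", accelSwitchDay = "numeric",
  ta = "numeric", tr = "numeric", mu = "numeric",
  tpGrowth = "numeric", hypoxiaThreshold = "numeric",
  tCollapse = "numeric", collapseOccupancy = "numeric",
  pullRate = "numeric", growthHeadroom = "numeric", hostVf = "numeric"
))

setValidity("BioParams", function(object) {
  vals <- c(object@tpInitial, object@tpAccelerated, object@ta, object@tr,
            object@mu, object@tpGrowth, object@tCollapse)
  if (any(vals <= 0)) return("all time constants and mu must be positive")
  if (object@tpAccelerated > object@tpInitial)
    return("tpAccelerated must be <= tpInitial")
  if (object@pullRate < 0 || object@pullRate > 1) return("pullRate must be in [0, 1]")
  if (object@growthHeadroom < 1) return("growthHeadroom must be >= 1")
  if (object@hostVf < 0 || object@hostVf >= 0.5) return("hostVf must be in [0, 0.5)")
  TRUE
})

#' Tumor oxygenation model parameters
#'
#' Parameters of the 2-D reaction-diffusion steady state solved in a voxel
#' cross-section with parallel randomly placed vessels.
#'
#' @slot intravascularPO2 pO2 clamped inside vessels (mmHg)
#' @slot vesselRadius capillary radius (um)
#' @slot consumptionRateMax Michaelis-Menten maximum consumption at full
#'   viable-cell density (mmHg/s)
#' @slot km consumption half-saturation constant (mmHg)
#' @slot diffusivity oxygen diffusivity (um^2/s)
#' @slot domainSide side of the square cross-section (um)
#' @slot gridResolution finite-difference points per side
#' @export
setClass("TOMParams", representation(
  intravascularPO2 = "numeric", vesselRadius = "numeric",
  consumptionRateMax = "numeric", km = "numeric", diffusivity = "numeric",
  domainSide = "numeric", gridResolution = "integer"
))

setValidity("TOMParams", function(object) {
  if (any(c(object@intravascularPO2, object@vesselRadius, object@km,
            object@diffusivity, object@domainSide) <= 0))
    return("all TOM parameters must be positive")
  if (object@consumptionRateMax < 0) return("consumptionRateMax must be >= 0")
  if (object@gridResolution < 8) return("gridResolution must be >= 8")
  if (object@domainSide <= 4 * object@vesselRadius)
    return("domainSide must be much larger than vesselRadius")
  TRUE
})

## ---------------------------------------------------------------------------
## Oxygen histogram and lookup
## ---------------------------------------------------------------------------

#' 16-bin discrete pO2 distribution of a voxel
#'
#' @slot binCenters representative pO2 of each bin (mmHg), non-negative and
#'   strictly increasing
#' @slot weights fraction of extravascular volume (equivalently, of cells) in
#'   each bin; non-negative, summing to 1
#' @export
setClass("OxygenHistogram", representation(
  binCenters = "numeric", weights = "numeric"
))

setValidity("OxygenHistogram", function(object) {
  if (length(object@binCenters) != length(object@weights))
    return("binCenters and weights must have the same length")
  if (any(object@weights < -1e-12)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1 (tol 1e-9)")
  if (any(object@binCenters < 0)) return("binCenters must be non-negative")
  if (any(diff(object@binCenters) <= 0)) return("binCenters must be strictly increasing")
  TRUE
})

#' Pre-tabulated oxygen histograms over vascular and consuming fractions
#'
#' Histograms are pre-computed on a (vf, s) grid, where vf is the vascular
#' fraction of the tissue and s the volume fraction of consuming (viable)
#' cells, and retrieved by bilinear interpolation.
#'
#' @slot vfGrid strictly increasing vascular fractions
#' @slot sGrid strictly increasing consuming-cell fractions
#' @slot binCenters shared bin centers (mmHg)
#' @slot weights array [vf, s, bin] of histogram weights
#' @slot params the [TOMParams] used to build the table
#' @export
setClass("OxygenLookup", representation(
  vfGrid = "numeric", sGrid = "numeric", binCenters = "numeric",
  weights = "array", params = "TOMParams"
))

setValidity("OxygenLookup", function(object) {
  d <- dim(object@weights)
  if (length(d) != 3) return("weights must be a 3-d array")
  if (d[1] != length(object@vfGrid) || d[2] != length(object@sGrid) ||
      d[3] != length(object@binCenters))
    return("weights dimensions must match vfGrid, sGrid, binCenters")
  if (any(diff(object@vfGrid) <= 0)) return("vfGrid must be strictly increasing")
  if (any(diff(object@sGrid) <= 0)) return("sGrid must be strictly increasing")
  s <- apply(object@weights, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-6)) return("every stored histogram must sum to 1")
  if (any(object@weights < -1e-12)) return("histogram weights must be non-negative")
  TRUE
})

## ---------------------------------------------------------------------------
## Tumor grid
## ---------------------------------------------------------------------------

#' 3-D voxel lattice of tumor compartments
#'
#' Per-voxel cell counts are stored as flat numeric vectors over the full
#' bounding lattice; per-voxel pO2 histograms as an n-voxel x 16 weight
#' matrix. The tumor mask is derived: voxels holding at least one tumor cell
#' (viable + dead >= 1). Normal (host) cells are inert filler and are not
#' simulated; [normalCells()] reports capacity minus the tracked compartments.
#'
#' @slot dims lattice dimensions (3 integers)
#' @slot voxelSide voxel edge length (mm)
#' @slot viable viable tumor cells per voxel
#' @slot dead dead tumor cells per voxel
#' @slot capillary capillary cells per voxel
#' @slot weights histogram weight matrix (nvoxel x nbin)
#' @slot binCenters histogram bin centers (mmHg)
#' @slot capacity packing capacity of a voxel (cells; mu * voxelSide^3)
#' @slot time hours since treatment start (negative during generation)
#' @export
setClass("TumorGrid", representation(
  dims = "integer", voxelSide = "numeric",
  viable = "numeric", dead = "numeric", capillary = "numeric",
  weights = "matrix", binCenters = "numeric", capacity = "numeric",
  time = "numeric"
))

setValidity("TumorGrid", function(object) {
  n <- prod(object@dims)
  if (length(object@dims) != 3) return("dims must have length 3")
  if (length(object@viable) != n || length(object@dead) != n ||
      length(object@capillary) != n)
    return("compartment vectors must have prod(dims) elements")
  if (nrow(object@weights) != n || ncol(object@weights) != length(object@binCenters))
    return("weights must be nvoxel x nbin")
  if (any(object@viable < 0) || any(object@dead < 0) || any(object@capillary < 0))
    return("cell counts must be non-negative")
  if (object@voxelSide <= 0) return("voxelSide must be positive")
  if (length(object@capacity) != 1 || object@capacity <= 0)
    return("capacity must be a single positive number")
  TRUE
})

## ---------------------------------------------------------------------------
## Dose plans and constraints
## ---------------------------------------------------------------------------

#' Dose redistribution constraints
#'
#' @slot meanDose prescribed mean dose per fraction (Gy)
#' @slot dMin minimum voxel dose (Gy)
#' @slot dMax maximum voxel dose (Gy)
#' @export
setClass("DoseConstraints", representation(
  meanDose = "numeric", dMin = "numeric", dMax = "numeric"
))

setValidity("DoseConstraints", function(object) {
  if (!(object@dMin <= object@meanDose && object@meanDose <= object@dMax))
    return("must satisfy dMin <= meanDose <= dMax")
  if (object@dMin < 0) return("dMin must be >= 0")
  TRUE
})

#' Per-voxel fractional dose map
#'
#' Doses are stored over the full lattice with NA outside the planned mask.
#'
#' @slot doses voxel doses (Gy), NA where not planned
#' @slot constraints the [DoseConstraints] the plan satisfies
#' @slot objective one of "surv", "std", "uniform"
#' @slot report solver diagnostics (iterations, objective, residuals)
#' @export
setClass("DosePlan", representation(
  doses = "numeric", constraints = "DoseConstraints",
  objective = "character", report = "list"
))

setValidity("DosePlan", function(object) {
  d <- object@doses[!is.na(object@doses)]
  if (length(d) == 0) return("plan must cover at least one voxel")
  cn <- object@constraints
  if (any(d < cn@dMin - 1e-6) || any(d > cn@dMax + 1e-6))
    return("doses violate box constraints (tol 1e-6)")
  if (abs(mean(d) - cn@meanDose) > 1e-6)
    return("mean dose violates the mean constraint (tol 1e-6)")
  if (!object@objective %in% c("surv", "std", "uniform"))
    return("objective must be 'surv', 'std' or 'uniform'")
  TRUE
})

## ---------------------------------------------------------------------------
## Schedules and outcome
## ---------------------------------------------------------------------------

#' Fractionation calendar and adaptive optimization scheme
#'
#' Day 0 is the first Monday; fractions are delivered weekdays only. Plans
#' computed at the optimization fractions persist until replaced; beyond the
#' scheme's adaptation window every fraction is uniform 2 Gy.
#'
#' @slot scheme one of "uniform", "1F", "2F", "3F", "FBF3W", "FBF4W"
#' @slot nFractions number of fractions
#' @slot fractionDays calendar day of each fraction
#' @slot optimizationFractions fraction indices at which a plan is recomputed
#' @slot windowEnd last fraction still covered by an optimized plan
#' @export
setClass("TreatmentSchedule", representation(
  scheme = "character", nFractions = "integer", fractionDays = "integer",
  optimizationFractions = "integer", windowEnd = "integer"
))

setValidity("TreatmentSchedule", function(object) {
  if (length(object@fractionDays) != object@nFractions)
    return("fractionDays must have nFractions entries")
  if (any(object@fractionDays %% 7 >= 5))
    return("fractions must not fall on weekends")
  if (length(object@optimizationFractions) &&
      (min(object@optimizationFractions) < 1 ||
       max(object@optimizationFractions) > object@nFractions))
    return("optimizationFractions must lie in 1..nFractions")
  TRUE
})

#' Tumor control probability result
#'
#' @slot table per-dose-level data.frame (dose, controlled, n)
#' @slot coefficients logistic coefficients (b0, b1)
#' @slot d50 dose at 50% control probability (Gy)
#' @slot d50Uncertainty bootstrap uncertainty, 2 SD / coverage k = 2 (Gy)
#' @slot scheme adaptive scheme label
#' @slot objective objective-function label
#' @export
setClass("TCPResult", representation(
  table = "data.frame", coefficients = "numeric", d50 = "numeric",
  d50Uncertainty = "numeric", scheme = "character", objective = "character"
))

setValidity("TCPResult", function(object) {
  tb <- object@table
  if (!all(c("dose", "controlled", "n") %in% names(tb)))
    return("table must have columns dose, controlled, n")
  if (any(tb$controlled > tb$n)) return("controlled must be <= n")
  TRUE
})
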