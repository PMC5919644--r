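## Constructors with the study's default parameter values (head & neck).

#' LQ radiosensitivity parameters
#'
#' Defaults are the head-and-neck values used throughout the package:
#' alpha = 0.35/Gy, beta = 0.035/Gy^2, sigmaAlpha = 0.05/Gy.
#'
#' @param alpha fully oxic alpha (1/Gy)
#' @param beta fully oxic beta (1/Gy^2)
#' @param sigmaAlpha population SD of alpha (1/Gy)
#' @return an [LQParams-class] object
#' @examples
#' lqParams()
#' lqParams(alpha = 0.3)
#' @export
lqParams <- function(alpha = 0.35, beta = 0.035, sigmaAlpha = 0.05) {
  new("LQParams", alpha = alpha, beta = beta, sigmaAlpha = sigmaAlpha)
}

#' Oxygen enhancement ratio parameters
#'
#' Defaults: maximum OER of 2.5 for alpha and 3 for beta, slope constant
#' k = 3.28 mmHg.
#'
#' @param oerAlphaMax maximum OER for alpha
#' @param oerBetaMax maximum OER for beta
#' @param k slope constant (mmHg)
#' @return an [OERParams-class] object
#' @export
oerParams <- function(oerAlphaMax = 2.5, oerBetaMax = 3, k = 3.28) {
  new("OERParams", oerAlphaMax = oerAlphaMax, oerBetaMax = oerBetaMax, k = k)
}

#' Biological parameters of the tumor response model
#'
#' Defaults: doubling time 1200 h at treatment start switching to 120 h after
#' two weeks (accelerated repopulation), capillary doubling 612 h, dead-cell
#' resorption half time 168 h, packing density 1e6 cells/mm^3. The remaining
#' arguments parameterize the reconstructed spatial processes (vascular
#' collapse under crowding, rate-limited cell exchange, host vasculature);
#' see the methods vignette for their rationale.
#'
#' @param tpInitial,tpAccelerated,accelSwitchDay tumor proliferation doubling
#'   times (h) and the switch day of accelerated repopulation
#' @param ta capillary doubling time (h)
#' @param tr dead-cell resorption half time (h)
#' @param mu packing cell density (cells/mm^3)
#' @param tpGrowth doubling time used while growing virtual tumors (h)
#' @param hypoxiaThreshold median pO2 triggering angiogenesis (mmHg)
#' @param tCollapse capillary halving time under crowding (h)
#' @param collapseOccupancy occupancy fraction above which vessels collapse
#' @param pullRate daily fraction of a voxel deficit refilled by exchange
#' @param growthHeadroom proliferation ceiling as a multiple of capacity
#' @param hostVf vascular fraction of un-invaded host tissue
#' @return a [BioParams-class] object
#' @export
bioParams <- function(tpInitial = 1200, tpAccelerated = 120, accelSwitchDay = 14,
                      ta = 612, tr = 168, mu = 1e6,
                      tpGrowth = 120, hypoxiaThreshold = 5,
                      tCollapse = 400, collapseOccupancy = 0.9,
                      pullRate = 1, growthHeadroom = 1.1, hostVf = 0.06) {
  new("BioParams", tpInitial = tpInitial, tpAccelerated = tpAccelerated,
      accelSwitchDay = accelSwitchDay, ta = ta, tr = tr, mu = mu,
      tpGrowth = tpGrowth, hypoxiaThreshold = hypoxiaThreshold,
      tCollapse = tCollapse, collapseOccupancy = collapseOccupancy,
      pullRate = pullRate, growthHeadroom = growthHeadroom, hostVf = hostVf)
}

#' Tumor oxygenation model parameters
#'
#' Defaults describe a 1124 um voxel cross-section perfused by 10 um parallel
#' vessels at 40 mmHg, oxygen diffusivity 2000 um^2/s and Michaelis-Menten
#' consumption with km = 2.5 mmHg. The maximum consumption rate (8 mmHg/s at
#' full viable-cell density) is the single calibrated scalar: it is chosen so
#' that a 6% vascular fraction is well oxygenated (median pO2 well above
#' 10 mmHg, so the oxygen effect there is marginal) while sub-1% vascular
#' fractions remain radiobiologically hypoxic.
#'
#' @param intravascularPO2 vessel pO2 (mmHg)
#' @param vesselRadius capillary radius (um)
#' @param consumptionRateMax maximum consumption at full density (mmHg/s)
#' @param km half-saturation pO2 (mmHg)
#' @param diffusivity oxygen diffusivity (um^2/s)
#' @param domainSide cross-section side (um)
#' @param gridResolution finite-difference points per side
#' @return a [TOMParams-class] object
#' @export
tomParams <- function(intravascularPO2 = 40, vesselRadius = 10,
                      consumptionRateMax = 8, km = 2.5, diffusivity = 2000,
                      domainSide = 1124, gridResolution = 112L) {
  new("TOMParams", intravascularPO2 = intravascularPO2,
      vesselRadius = vesselRadius, consumptionRateMax = consumptionRateMax,
      km = km, diffusivity = diffusivity, domainSide = domainSide,
      gridResolution = as.integer(gridResolution))
}

#' Dose redistribution constraints
#'
#' Defaults: mean 2 Gy per fraction with voxel doses within +/-25% of the
#' prescription (1.5 to 2.5 Gy).
#'
#' @param meanDose prescribed mean fraction dose (Gy)
#' @param dMin,dMax voxel dose box (Gy)
#' @return a [DoseConstraints-class] object
#' @export
doseConstraints <- function(meanDose = 2, dMin = 1.5, dMax = 2.5) {
  new("DoseConstraints", meanDose = meanDose, dMin = dMin, dMax = dMax)
}

#' Single-voxel oxygen histogram
#'
#' @param binCenters pO2 bin centers (mmHg)
#' @param weights bin weights summing to 1
#' @return an [OxygenHistogram-class] object
#' @examples
#' oxygenHistogram(c(0, 5, 40), c(0.2, 0.3, 0.5))
#' @export
oxygenHistogram <- function(binCenters, weights) {
  new("OxygenHistogram", binCenters = as.numeric(binCenters),
      weights = as.numeric(weights))
}

#' Derived hypoxic radiosensitivities
#'
#' \code{alpha_h = alpha / OERalpha_max} and
#' \code{beta_h = beta / OERbeta_max^2}.
#'
#' @param lq an [LQParams-class] object
#' @param oer an [OERParams-class] object
#' @return hypoxic alpha (1/Gy) or beta (1/Gy^2)
#' @export
hypoxicAlpha <- function(lq, oer) lq@alpha / oer@oerAlphaMax

#' @rdname hypoxicAlpha
#' @export
hypoxicBeta <- function(lq, oer) lq@beta / oer@oerBetaMax^2
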