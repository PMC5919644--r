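## Oxygen-dependent linear-quadratic survival.

#' Oxygen enhancement ratio
#'
#' OER(p) = (k + p * oerMax) / (p + k): equals 1 in anoxia and saturates at
#' oerMax at high pO2, with half of the range reached at p = k.
#'
#' @param p oxygen partial pressure (mmHg), vectorized
#' @param oerMax maximum OER (>= 1)
#' @param k slope constant (mmHg, > 0)
#' @return OER values in [1, oerMax]
#' @examples
#' oer(0, 2.5, 3.28)      # anoxic limit: 1
#' oer(1e6, 2.5, 3.28)    # aerobic limit: ~2.5
#' @export
oer <- function(p, oerMax, k) {
  if (any(p < 0)) stop("pO2 must be non-negative")
  if (k <= 0) stop("k must be positive")
  if (oerMax < 1) stop("oerMax must be >= 1")
  (k + p * oerMax) / (p + k)
}

#' Oxygen-dependent cell survival fraction
#'
#' SF = exp(-alpha_h * OER_alpha(p) * d - beta_h * (OER_beta(p) * d)^2), the
#' LQ model with the OERs modulating the hypoxic radiosensitivities
#' alpha_h = alpha/OERalphaMax, beta_h = beta/OERbetaMax^2. At high pO2 the
#' exponent reduces to the fully oxic -alpha*d - beta*d^2; in anoxia the
#' hypoxic parameters apply unmodulated.
#'
#' @param d dose (Gy), vectorized (recycled against p)
#' @param p pO2 (mmHg), vectorized
#' @param lq an [LQParams-class]
#' @param oerp an [OERParams-class]
#' @return survival fraction in (0, 1]
#' @examples
#' survivalFraction(2, 1e6, lqParams(), oerParams())  # fully oxic 2 Gy
#' survivalFraction(2, 0,   lqParams(), oerParams())  # anoxic 2 Gy
#' @export
survivalFraction <- function(d, p, lq = lqParams(), oerp = oerParams()) {
  if (any(d < 0)) stop("dose must be non-negative")
  oa <- oer(p, oerp@oerAlphaMax, oerp@k)
  ob <- oer(p, oerp@oerBetaMax, oerp@k)
  ah <- hypoxicAlpha(lq, oerp)
  bh <- hypoxicBeta(lq, oerp)
  exp(-ah * oa * d - bh * (ob * d)^2)
}

## Survival fractions for each (voxel dose, bin center) pair.
## d: length-n vector; centers: length-nb vector -> n x nb matrix.
survivalMatrix <- function(d, centers, lq, oerp) {
  oa <- oer(centers, oerp@oerAlphaMax, oerp@k)
  ob <- oer(centers, oerp@oerBetaMax, oerp@k)
  ah <- hypoxicAlpha(lq, oerp)
  bh <- hypoxicBeta(lq, oerp)
  ## exponent_{ij} = -ah*oa_j*d_i - bh*ob_j^2*d_i^2
  exp(-outer(d, ah * oa) - outer(d^2, bh * ob^2))
}

#' Expected surviving cells in one voxel
#'
#' Sums viable * weight_j * SF(d, p_j) over the 16 histogram bins.
#'
#' @param viable viable cell count (>= 0)
#' @param hist an [OxygenHistogram-class]
#' @param d fraction dose (Gy)
#' @param lq an [LQParams-class]
#' @param oerp an [OERParams-class]
#' @return expected surviving cell count (<= viable; = viable at d = 0)
#' @export
voxelSurvivors <- function(viable, hist, d, lq = lqParams(), oerp = oerParams()) {
  if (viable < 0) stop("viable must be non-negative")
  stopifnot(is(hist, "OxygenHistogram"))
  sf <- survivalFraction(d, hist@binCenters, lq, oerp)
  viable * sum(hist@weights * sf)
}

## Mean survival fraction per voxel for a dose vector (internal, vectorized):
## rowSums(weights * SF-matrix). W is nvox x nb over the given voxels.
meanSurvival <- function(d, W, centers, lq, oerp) {
  rowSums(W * survivalMatrix(d, centers, lq, oerp))
}

#' Expected surviving cells over the whole tumor
#'
#' The survival bookkeeping C_surv: the double sum over tumor voxels and
#' their histogram bins of cells times the oxygen-dependent survival
#' fraction. Linear in the per-voxel viable counts.
#'
#' @param grid a [TumorGrid-class]
#' @param plan a [DosePlan-class] covering the tumor mask (voxels of the mask
#'   missing from the plan receive the constraint mean dose)
#' @param lq an [LQParams-class]
#' @param oerp an [OERParams-class]
#' @return expected total surviving cell count
#' @export
totalSurvivors <- function(grid, plan, lq = lqParams(), oerp = oerParams()) {
  if (length(plan@doses) != length(grid@viable))
    stop("plan and grid have mismatched lattice sizes")
  m <- which(tumorMask(grid) & grid@viable > 0)
  if (length(m) == 0) return(0)
  d <- plan@doses[m]
  d[is.na(d)] <- plan@constraints@meanDose
  sbar <- meanSurvival(d, grid@weights[m, , drop = FALSE], grid@binCenters,
                       lq, oerp)
  sum(grid@viable[m] * sbar)
}
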