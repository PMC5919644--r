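## TCP curves, logistic D50 with bootstrap uncertainty, treatment gain.

#' Simulate a virtual patient population over dose levels
#'
#' Dose levels are realized by increasing the number of 2 Gy fractions. Each
#' virtual patient draws an intrinsic radiosensitivity alpha from
#' Normal(alphaMean, alphaSd) (truncated below at `alphaFloor`; use
#' alphaSd = 0 for the fixed-alpha population), receives the pre-computed
#' plans of the scheme, and is controlled iff no tumor cell survived at the
#' end of the course.
#'
#' @param grid pre-treatment [TumorGrid-class]
#' @param scheme adaptive scheme label
#' @param objective "uniform", "surv" or "std"
#' @param plans pre-computed plans from the mean-alpha trajectory (NULL for
#'   uniform treatment)
#' @param doseLevels fraction counts defining the dose levels
#' @param nPerDose patients per dose level
#' @param lq an [LQParams-class]: alpha is the population mean, sigmaAlpha
#'   the population SD (set 0 for fixed-alpha populations)
#' @param oerp,bio,lookup,constraints model components
#' @param alphaFloor truncation floor for drawn alphas (1/Gy)
#' @param stochastic binomial cell-killing stochasticity (default); set
#'   FALSE for expected-value kill
#' @param seed base seed; every patient derives an independent stream
#' @return data.frame: nFractions, dose (Gy), patient, alpha, controlled
#' @export
simulatePopulation <- function(grid, scheme, objective, plans, doseLevels,
                               nPerDose = 30, lq = lqParams(),
                               oerp = oerParams(), bio = bioParams(), lookup,
                               constraints = doseConstraints(),
                               alphaFloor = 0.05, stochastic = TRUE,
                               seed = 1) {
  if (nPerDose < 2) stop("nPerDose must be >= 2")
  if (any(diff(doseLevels) <= 0)) stop("doseLevels must be strictly increasing")
  rows <- vector("list", length(doseLevels) * nPerDose)
  r <- 0L
  for (li in seq_along(doseLevels)) {
    nf <- doseLevels[li]
    schedule <- treatmentSchedule(scheme, nf)
    for (pt in seq_len(nPerDose)) {
      ## patient seed independent of the level ordering so that the same
      ## patient index draws the same alpha and kill stream at every level
      set.seed(seed + 7919L * li + pt)
      a <- if (lq@sigmaAlpha > 0)
        max(alphaFloor, rnorm(1, lq@alpha, lq@sigmaAlpha)) else lq@alpha
      plq <- lqParams(alpha = a, beta = lq@beta, sigmaAlpha = 0)
      res <- runTreatment(grid, schedule, objective, constraints, plq, oerp,
                          bio, lookup, stochastic = stochastic, plans = plans)
      r <- r + 1L
      rows[[r]] <- data.frame(nFractions = nf,
                              dose = constraints@meanDose * nf,
                              patient = pt, alpha = a,
                              controlled = res$controlled)
    }
  }
  do.call(rbind, rows)
}

#' Fit the logistic TCP model
#'
#' Maximum-likelihood univariate logistic regression of the control
#' indicator on the total mean dose: P(control) = 1/(1 + exp(-(b0 + b1 D))).
#' Perfectly separated data (all-control above some dose, none below, with
#' no mixed level) are flagged as non-identifiable rather than silently
#' fitted.
#'
#' @param outcomes data.frame with columns `dose` (Gy) and `controlled`
#'   (logical or 0/1)
#' @return named coefficients c(b0, b1)
#' @export
fitTCP <- function(outcomes) {
  y <- as.numeric(outcomes$controlled)
  if (all(y == 0) || all(y == 1))
    stop("TCP fit is non-identifiable: all outcomes identical")
  fit <- suppressWarnings(glm(y ~ dose, data = outcomes, family = binomial()))
  p <- fitted(fit)
  if (all(p < 1e-8 | p > 1 - 1e-8))
    stop("TCP fit is non-identifiable: perfect separation")
  setNames(coef(fit), c("b0", "b1"))
}

#' D50 from logistic coefficients c(b0, b1): -b0/b1.
#' @param object coefficient vector c(b0, b1)
#' @param ... unused
#' @rdname accessors
#' @export
setMethod("d50", "numeric", function(object, ...) {
  unname(-object[1] / object[2])
})

## Fallback D50 when the logistic fit is non-identifiable: linear
## interpolation of the empirical control rate across 0.5.
midpointD50 <- function(outcomes) {
  agg <- aggregate(controlled ~ dose, outcomes, function(x) mean(as.numeric(x)))
  agg <- agg[order(agg$dose), ]
  rate <- agg$controlled; dose <- agg$dose
  if (all(rate >= 0.5)) return(min(dose))
  if (all(rate < 0.5)) return(max(dose))
  i <- which(rate >= 0.5)[1]
  d0 <- dose[i - 1]; d1 <- dose[i]
  r0 <- rate[i - 1]; r1 <- rate[i]
  d0 + (0.5 - r0) / (r1 - r0) * (d1 - d0)
}

## D50 of an outcome table, falling back to the midpoint estimator when the
## logistic fit is non-identifiable. Returns list(d50, coef, separated).
d50FromOutcomes <- function(outcomes) {
  co <- tryCatch(fitTCP(outcomes), error = function(e) NULL)
  if (is.null(co))
    list(d50 = midpointD50(outcomes), coef = c(b0 = NA_real_, b1 = NA_real_),
         separated = TRUE)
  else list(d50 = d50(co), coef = co, separated = FALSE)
}

#' Bootstrap uncertainty of D50
#'
#' Patients are resampled with replacement within each dose level, the
#' logistic model refitted, and the uncertainty reported as two standard
#' deviations of the bootstrap D50 distribution (coverage factor k = 2).
#'
#' @param outcomes per-patient outcome data.frame (see [simulatePopulation()])
#' @param nBoot bootstrap replicates
#' @param seed RNG seed
#' @return list: `uncertainty` (2 SD, Gy), `d50` (bootstrap draws)
#' @export
bootstrapD50 <- function(outcomes, nBoot = 1000, seed = 1) {
  set.seed(seed)
  levels_ <- split(seq_len(nrow(outcomes)), outcomes$dose)
  draws <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    idx <- unlist(lapply(levels_, function(ii) ii[sample.int(length(ii),
                                                             replace = TRUE)]))
    draws[b] <- d50FromOutcomes(outcomes[idx, ])$d50
  }
  list(uncertainty = 2 * sd(draws), d50 = draws)
}

#' Full TCP analysis of a simulated population
#'
#' Control rates per level, logistic fit (with midpoint fallback for
#' separated data), D50 and its bootstrap uncertainty.
#'
#' @param outcomes per-patient outcome data.frame
#' @param scheme,objective labels stored in the result
#' @param nBoot bootstrap replicates (0 to skip)
#' @param seed RNG seed for the bootstrap
#' @return a [TCPResult-class]
#' @export
tcpAnalysis <- function(outcomes, scheme = "uniform", objective = "uniform",
                        nBoot = 1000, seed = 1) {
  tab <- aggregate(cbind(controlled = as.numeric(controlled)) ~ dose,
                   outcomes, sum)
  tab$n <- as.integer(table(outcomes$dose)[as.character(tab$dose)])
  est <- d50FromOutcomes(outcomes)
  unc <- if (nBoot > 0) bootstrapD50(outcomes, nBoot, seed)$uncertainty else NA_real_
  new("TCPResult", table = tab[, c("dose", "controlled", "n")],
      coefficients = est$coef, d50 = est$d50, d50Uncertainty = unc,
      scheme = scheme, objective = objective)
}

#' Treatment gain of dose painting over the uniform treatment
#'
#' gain = D50(conventional uniform) - D50(DPBN); positive values mean the
#' painted treatment controls the tumor at a lower dose.
#'
#' @param d50Conv D50 of the uniform treatment (Gy, or a [TCPResult-class])
#' @param d50Dpbn D50 of the painted treatment (Gy, or a [TCPResult-class])
#' @return gain (Gy)
#' @export
treatmentGain <- function(d50Conv, d50Dpbn) {
  g <- function(x) if (is(x, "TCPResult")) x@d50 else x
  g(d50Conv) - g(d50Dpbn)
}
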