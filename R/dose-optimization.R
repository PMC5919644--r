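## Constrained per-fraction dose redistribution: minimize expected survival
## (OF_surv) or the spatial heterogeneity of survival (OF_std) under a fixed
## 2 Gy mean and a +/-25% voxel dose box.

## Per-voxel ingredients for the objectives, cached per call site:
## A = viable_i * w_ij, a_j = alpha_h * OERalpha_j, b_j = beta_h * OERbeta_j^2.
survTerms <- function(grid, lq, oerp, voxels) {
  centers <- grid@binCenters
  list(
    A = grid@viable[voxels] * grid@weights[voxels, , drop = FALSE],
    a = hypoxicAlpha(lq, oerp) * oer(centers, oerp@oerAlphaMax, oerp@k),
    b = hypoxicBeta(lq, oerp) * oer(centers, oerp@oerBetaMax, oerp@k)^2,
    viable = grid@viable[voxels]
  )
}

## Expected survivors per voxel and derivative wrt the voxel dose.
survivorsAndDeriv <- function(d, tm, deriv = TRUE) {
  E <- exp(-outer(d, tm$a) - outer(d^2, tm$b))
  s <- rowSums(tm$A * E)
  if (!deriv) return(list(s = s))
  ds <- -rowSums(tm$A * E * outer(rep(1, length(d)), tm$a) +
                   tm$A * E * 2 * outer(d, tm$b))
  list(s = s, ds = ds)
}

#' Survival objective (OF_surv) and its gradient
#'
#' The expected number of surviving tumor cells summed over voxels and
#' histogram bins, as a function of the per-voxel dose vector.
#'
#' @param d dose vector over the tumor voxels (Gy)
#' @param grid a [TumorGrid-class]
#' @param lq an [LQParams-class]
#' @param oerp an [OERParams-class]
#' @param voxels lattice indices the doses refer to (default: tumor mask)
#' @param gradient also return the analytic gradient
#' @return objective value, with attribute "gradient" when requested
#' @export
objectiveSurv <- function(d, grid, lq = lqParams(), oerp = oerParams(),
                          voxels = which(tumorMask(grid)), gradient = FALSE) {
  tm <- survTerms(grid, lq, oerp, voxels)
  r <- survivorsAndDeriv(d, tm, deriv = gradient)
  out <- sum(r$s)
  if (gradient) attr(out, "gradient") <- r$ds
  out
}

#' Heterogeneity objective (OF_std) and its gradient
#'
#' The standard deviation over tumor voxels of the expected surviving cell
#' count.
#'
#' @inheritParams objectiveSurv
#' @return objective value, with attribute "gradient" when requested
#' @export
objectiveStd <- function(d, grid, lq = lqParams(), oerp = oerParams(),
                         voxels = which(tumorMask(grid)), gradient = FALSE) {
  tm <- survTerms(grid, lq, oerp, voxels)
  r <- survivorsAndDeriv(d, tm, deriv = gradient)
  n <- length(r$s)
  stdev <- sd(r$s)
  if (gradient) {
    g <- if (is.na(stdev) || stdev < 1e-12) rep(0, n) else
      (r$s - mean(r$s)) / ((n - 1) * stdev) * r$ds
    attr(stdev, "gradient") <- g
  }
  stdev
}

#' Uniform dose plan
#'
#' @param grid a [TumorGrid-class]
#' @param dose fraction dose (Gy)
#' @param constraints a [DoseConstraints-class] (meanDose forced to `dose`)
#' @return a [DosePlan-class] tagged "uniform"
#' @export
uniformPlan <- function(grid, dose = 2, constraints = doseConstraints()) {
  constraints@meanDose <- dose
  d <- rep(NA_real_, length(grid@viable))
  d[tumorMask(grid)] <- dose
  new("DosePlan", doses = d, constraints = constraints,
      objective = "uniform", report = list())
}

## Separable KKT solver for OF_surv. The objective is a sum of per-voxel
## convex terms, so at the optimum every non-clamped voxel equates its
## marginal kill m_i(d_i) = -dC_i/dd_i to the mean-dose multiplier lambda.
## m_i is positive and decreasing in d, hence d_i(lambda) is found by a
## safeguarded Newton iteration and lambda by bisection on the mean dose.
kktSolveSurv <- function(grid, constraints, lq, oerp, voxels) {
  tm <- survTerms(grid, lq, oerp, voxels)
  lo <- constraints@dMin; hi <- constraints@dMax; mu <- constraints@meanDose
  n <- length(voxels)
  marginal <- function(d) {
    E <- exp(-outer(d, tm$a) - outer(d^2, tm$b))
    lin <- outer(rep(1, n), tm$a) + 2 * outer(d, tm$b)
    m <- rowSums(tm$A * E * lin)
    dm <- rowSums(tm$A * E * (2 * outer(rep(1, n), tm$b) - lin^2))
    list(m = m, dm = dm)
  }
  dOf <- function(lam) {
    d <- rep(mu, n)
    for (it in 1:9) {
      md <- marginal(d)
      step <- (md$m - lam) / pmin(md$dm, -1e-12)
      d <- pmin(pmax(d - step, lo), hi)
    }
    md <- marginal(d)
    d[md$m < lam & d <= lo + 1e-9] <- lo
    d[md$m > lam & d >= hi - 1e-9] <- hi
    d
  }
  mHi <- marginal(rep(lo, n))$m
  lamLo <- 0; lamHi <- max(mHi) * 1.001 + 1e-9
  for (it in 1:60) {
    lam <- (lamLo + lamHi) / 2
    d <- dOf(lam)
    g <- mean(d) - mu
    if (abs(g) < 1e-8) break
    ## m decreases with dose, so raising lambda lowers every d_i(lambda):
    ## increase lambda while the mean is above target
    if (g > 0) lamLo <- lam else lamHi <- lam
  }
  ## exact mean by a tiny uniform shift of the interior voxels
  interior <- d > lo + 1e-7 & d < hi - 1e-7
  if (any(interior)) {
    d[interior] <- d[interior] + (mu - mean(d)) * n / sum(interior)
    d <- pmin(pmax(d, lo), hi)
  }
  list(d = d, lambda = lam, iterations = it)
}

## Augmented-Lagrangian solver with box-constrained L-BFGS-B inner solves;
## handles both objectives and arbitrary starts.
augLagSolve <- function(fn, d0, constraints, maxOuter = 12) {
  lo <- constraints@dMin; hi <- constraints@dMax; mu <- constraints@meanDose
  n <- length(d0)
  ## scale so the inner objective is O(1): L-BFGS-B's relative stopping
  ## rule then resolves per-voxel doses to well below 1e-3 Gy
  fscale <- max(abs(as.numeric(fn(d0, gradient = FALSE))), 1)
  lam <- 0; rho <- 10
  d <- d0
  for (outer_ in seq_len(maxOuter)) {
    obj <- function(x) {
      v <- as.numeric(fn(x, gradient = FALSE)) / fscale
      h <- mean(x) - mu
      v + lam * h + rho / 2 * h^2
    }
    grd <- function(x) {
      v <- fn(x, gradient = TRUE)
      h <- mean(x) - mu
      attr(v, "gradient") / fscale + (lam + rho * h) / n
    }
    fit <- optim(d, obj, grd, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 1000, factr = 10, pgtol = 0))
    d <- fit$par
    h <- mean(d) - mu
    if (abs(h) < 1e-10 && outer_ > 1) break
    lam <- lam + rho * h
    rho <- rho * 10
  }
  ## final feasibility polish
  interior <- d > lo + 1e-7 & d < hi - 1e-7
  if (any(interior) && abs(mean(d) - mu) > 0) {
    d[interior] <- d[interior] + (mu - mean(d)) * n / sum(interior)
    d <- pmin(pmax(d, lo), hi)
  }
  d
}

#' Optimize the per-fraction dose distribution
#'
#' Solves the constrained redistribution problem for the current tumor
#' state: minimize OF_surv (expected surviving cells) or OF_std (their
#' spatial standard deviation) subject to a fixed mean dose and voxel dose
#' box. OF_surv is separable and convex over the box and is solved by a dual
#' KKT method (`method = "kkt"`, the default); a general augmented-Lagrangian
#' solver with analytic gradients (`method = "general"`) handles OF_std,
#' using multi-starts because that objective is non-convex. If the solver
#' fails to beat the uniform plan, the uniform plan is returned with a
#' warning (never a silently infeasible plan).
#'
#' @param grid a [TumorGrid-class] with at least one viable tumor voxel
#' @param objective "surv" or "std"
#' @param constraints a [DoseConstraints-class]
#' @param lq an [LQParams-class] (the population-mean radiosensitivity)
#' @param oerp an [OERParams-class]
#' @param method "auto" (kkt for surv, general for std), "kkt" or "general"
#' @param nStarts multi-starts for the std objective
#' @param seed seed for the multi-start perturbations
#' @return a [DosePlan-class]
#' @export
optimizeDose <- function(grid, objective = c("surv", "std"),
                         constraints = doseConstraints(),
                         lq = lqParams(), oerp = oerParams(),
                         method = c("auto", "kkt", "general"),
                         nStarts = 5, seed = 1) {
  objective <- match.arg(objective)
  method <- match.arg(method)
  voxels <- which(tumorMask(grid))
  if (length(voxels) == 0 || sum(grid@viable[voxels]) <= 0)
    stop("grid has no viable tumor voxels")
  n <- length(voxels)
  mu <- constraints@meanDose
  fn <- if (objective == "surv") {
    function(x, gradient = FALSE) objectiveSurv(x, grid, lq, oerp, voxels, gradient)
  } else {
    function(x, gradient = FALSE) objectiveStd(x, grid, lq, oerp, voxels, gradient)
  }
  fUnif <- as.numeric(fn(rep(mu, n)))
  report <- list(method = method, objective_uniform = fUnif)
  d <- tryCatch({
    if (objective == "surv" && method %in% c("auto", "kkt")) {
      r <- kktSolveSurv(grid, constraints, lq, oerp, voxels)
      report$lambda <- r$lambda
      r$d
    } else if (objective == "surv") {
      augLagSolve(fn, rep(mu, n), constraints)
    } else {
      ## non-convex: uniform start plus seeded perturbations, keep the best,
      ## breaking ties toward the plan closest to uniform
      set.seed(seed)
      best <- NULL; bestVal <- Inf; bestDist <- Inf
      for (k in seq_len(nStarts)) {
        d0 <- if (k == 1) rep(mu, n) else {
          x <- rep(mu, n) + runif(n, -0.25, 0.25) * (constraints@dMax - constraints@dMin)
          x <- pmin(pmax(x, constraints@dMin), constraints@dMax)
          x + (mu - mean(x))
        }
        cand <- augLagSolve(fn, d0, constraints)
        val <- as.numeric(fn(cand))
        dist <- sqrt(sum((cand - mu)^2))
        if (val < bestVal - 1e-12 ||
            (abs(val - bestVal) <= 1e-12 && dist < bestDist)) {
          best <- cand; bestVal <- val; bestDist <- dist
        }
      }
      best
    }
  }, error = function(e) {
    warning("dose optimization failed (", conditionMessage(e),
            "); falling back to the uniform plan")
    rep(mu, n)
  })
  fOpt <- as.numeric(fn(d))
  if (fOpt > fUnif + 1e-9) {
    warning("optimized plan did not improve on uniform; using uniform plan")
    d <- rep(mu, n)
    fOpt <- fUnif
  }
  report$objective_final <- fOpt
  report$mean_residual <- mean(d) - mu
  full <- rep(NA_real_, length(grid@viable))
  full[voxels] <- d
  new("DosePlan", doses = full, constraints = constraints,
      objective = objective, report = report)
}
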