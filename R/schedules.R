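## Fractionation calendars and the adaptive optimization schemes.

#' Weekday fractionation calendar
#'
#' One daily fraction with two-day weekend breaks, starting on a Monday
#' (day 0): five fractions per seven-day week.
#'
#' @param nFractions number of fractions
#' @return integer calendar-day index of each fraction
#' @examples
#' buildCalendar(6)   # sixth fraction on day 7, the next Monday
#' @export
buildCalendar <- function(nFractions) {
  f <- seq_len(nFractions) - 1L
  as.integer(f %% 5L + 7L * (f %/% 5L))
}

#' Fractions at which a new dose distribution is optimized
#'
#' 1F optimizes once at the start; 2F at the start and after 2 weeks
#' (fraction 11); 3F additionally after 3 weeks (fraction 16); FBF3W/FBF4W
#' before every fraction of the first 3/4 weeks. Beyond the scheme's window
#' (fraction 15 for FBF3W, 20 otherwise) all fractions are uniform 2 Gy.
#'
#' @param scheme "uniform", "1F", "2F", "3F", "FBF3W" or "FBF4W"
#' @param nFractions number of fractions
#' @return integer fraction indices (empty for "uniform")
#' @export
optimizationFractions <- function(scheme, nFractions) {
  fr <- switch(scheme,
               uniform = integer(0),
               "1F" = 1L,
               "2F" = c(1L, 11L),
               "3F" = c(1L, 11L, 16L),
               FBF3W = seq_len(15L),
               FBF4W = seq_len(20L),
               stop("unknown scheme: ", scheme))
  fr[fr <= nFractions]
}

## Last fraction still covered by an optimized plan.
schemeWindowEnd <- function(scheme, nFractions) {
  w <- switch(scheme, uniform = 0L, FBF3W = 15L, 20L)
  min(w, nFractions)
}

#' Treatment schedule
#'
#' @param scheme adaptive scheme label (see [optimizationFractions()])
#' @param nFractions number of 2 Gy fractions
#' @return a [TreatmentSchedule-class]
#' @export
treatmentSchedule <- function(scheme = "uniform", nFractions = 35L) {
  nFractions <- as.integer(nFractions)
  new("TreatmentSchedule", scheme = scheme, nFractions = nFractions,
      fractionDays = buildCalendar(nFractions),
      optimizationFractions = as.integer(optimizationFractions(scheme, nFractions)),
      windowEnd = as.integer(schemeWindowEnd(scheme, nFractions)))
}

#' Simulate one treatment course
#'
#' Iterates [stepDay()] over the calendar. At each optimization fraction of
#' the scheme a new plan is computed from the current tumor state (with the
#' population-mean radiosensitivity); optimized plans persist until replaced
#' and every fraction beyond the scheme's window is uniform 2 Gy. When
#' `plans` is supplied (pre-computed on the mean-radiosensitivity
#' trajectory), no optimization is performed and those plans are delivered.
#'
#' @param grid starting [TumorGrid-class]
#' @param schedule a [TreatmentSchedule-class]
#' @param objective "uniform", "surv" or "std"
#' @param constraints a [DoseConstraints-class]
#' @param lq an [LQParams-class] (this patient's radiosensitivity)
#' @param oerp an [OERParams-class]
#' @param bio a [BioParams-class]
#' @param lookup an [OxygenLookup-class]
#' @param stochastic binomial kill in small voxels
#' @param plans named list of [DosePlan-class], names = optimization fraction
#'   indices, as returned in `$plans`; NULL to optimize inline
#' @param planLq radiosensitivity used for inline optimization (defaults to
#'   the population mean)
#' @param coreDiameter diameter (cm) of the core tracked in the trajectory
#' @param keepFinalGrid return the end-of-treatment grid
#' @return list: `trajectory` (data.frame day, fraction, totalViable,
#'   totalDead, coreVf, plan), `plans`, `controlled` (no tumor cell
#'   survived), `totalDose` (Gy), optionally `finalGrid`
#' @export
runTreatment <- function(grid, schedule, objective = "uniform",
                         constraints = doseConstraints(), lq = lqParams(),
                         oerp = oerParams(), bio = bioParams(), lookup,
                         stochastic = TRUE, plans = NULL, planLq = lqParams(),
                         coreDiameter = 1, keepFinalGrid = FALSE) {
  nF <- schedule@nFractions
  days <- schedule@fractionDays
  lastDay <- max(days)
  fracOfDay <- setNames(seq_len(nF), days)
  core <- coreMask(grid, coreDiameter)
  recordedPlans <- if (is.null(plans)) list() else plans
  unif <- uniformPlan(grid, constraints@meanDose, constraints)
  current <- unif
  currentLabel <- "uniform"
  traj <- data.frame(day = 0:lastDay, fraction = NA_integer_,
                     totalViable = NA_real_, totalDead = NA_real_,
                     coreVf = NA_real_, plan = NA_character_)
  extinct <- FALSE
  for (day in 0:lastDay) {
    fr <- fracOfDay[as.character(day)]
    plan <- NULL
    if (!is.na(fr) && !extinct) {
      if (objective == "uniform" || fr > schedule@windowEnd) {
        plan <- unif
        currentLabel <- "uniform"
      } else {
        key <- as.character(fr)
        if (!is.null(plans)) {
          if (!is.null(plans[[key]])) {
            current <- plans[[key]]
            currentLabel <- paste0(objective, "@", key)
          }
        } else if (fr %in% schedule@optimizationFractions) {
          current <- optimizeDose(grid, objective, constraints, planLq, oerp)
          recordedPlans[[key]] <- current
          currentLabel <- paste0(objective, "@", key)
        }
        plan <- current
      }
    } else if (!is.na(fr) && extinct) {
      currentLabel <- "uniform"
    }
    if (!extinct) {
      grid <- stepDay(grid, plan, bio, lq, oerp, lookup,
                      stochastic = stochastic)
      if (sum(grid@viable) == 0) extinct <- TRUE
    } else {
      grid@dead <- grid@dead * 2^(-24 / bio@tr)
      grid@time <- grid@time + 24
    }
    i <- day + 1L
    traj$fraction[i] <- if (is.na(fr)) NA_integer_ else fr
    traj$totalViable[i] <- sum(grid@viable)
    traj$totalDead[i] <- sum(grid@dead)
    vf <- vascularFraction(grid)
    inCore <- core & (grid@viable + grid@dead > 1e-9)
    traj$coreVf[i] <- if (any(inCore)) mean(vf[inCore]) else NA_real_
    traj$plan[i] <- if (is.na(fr)) NA_character_ else currentLabel
  }
  out <- list(trajectory = traj, plans = recordedPlans,
              controlled = sum(grid@viable) < 1,
              totalDose = constraints@meanDose * nF)
  if (keepFinalGrid) out$finalGrid <- grid
  out
}

#' Reoxygenation index of a treatment trajectory
#'
#' The maximum rise of the core-averaged vascular fraction above its
#' pre-treatment value.
#'
#' @param result a [runTreatment()] result
#' @return vf rise (dimensionless)
#' @export
reoxygenationIndex <- function(result) {
  v <- result$trajectory$coreVf
  v <- v[!is.na(v)]
  max(v) - v[1]
}
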