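## Configuration and experiment driver binding the pipeline stages.

#' Default experiment configuration
#'
#' A nested list holding every tunable of the pipeline, pre-filled with the
#' study defaults (LQ/OER/biology parameter table, oxygenation model, dose
#' constraints, schemes and population settings). Serializable to YAML with
#' [writeConfig()].
#'
#' @return a named list
#' @export
defaultConfig <- function() {
  list(
    lq = list(alpha = 0.35, beta = 0.035, sigmaAlpha = 0.05),
    oer = list(oerAlphaMax = 2.5, oerBetaMax = 3, k = 3.28),
    bio = list(tpInitial = 1200, tpAccelerated = 120, accelSwitchDay = 14,
               ta = 612, tr = 168, mu = 1e6, tpGrowth = 120,
               hypoxiaThreshold = 5, tCollapse = 400,
               collapseOccupancy = 0.9, pullRate = 1,
               growthHeadroom = 1.1, hostVf = 0.06),
    tom = list(intravascularPO2 = 40, vesselRadius = 10,
               consumptionRateMax = 8, km = 2.5, diffusivity = 2000,
               domainSide = 1124, gridResolution = 112),
    constraints = list(meanDose = 2, dMin = 1.5, dMax = 2.5),
    tumor = list(dims = c(23, 23, 23), voxelSide = 1.124,
                 targetVoxels = 3888, uniformVf = 0.06),
    population = list(nPerDose = 30, doseLevels = c(20, 23, 26, 29, 32, 35, 38, 41),
                      alphaFloor = 0.05, nBoot = 1000),
    run = list(tumors = "T1", schemes = "uniform", objective = "surv",
               lookupQuality = "standard", seed = 1)
  )
}

## parameter-object builders from a validated config
configLQ <- function(cfg) do.call(lqParams, cfg$lq)
configOER <- function(cfg) do.call(oerParams, cfg$oer)
configBio <- function(cfg) do.call(bioParams, cfg$bio)
configTOM <- function(cfg) do.call(tomParams, cfg$tom)
configConstraints <- function(cfg) do.call(doseConstraints, cfg$constraints)

#' Validate an experiment configuration
#'
#' Rejects unknown keys, checks ranges (through the parameter class
#' validators) and ordering constraints, and returns the checked config.
#'
#' @param config a config list (see [defaultConfig()])
#' @return the validated config, with defaults filled for missing keys
#' @export
validateConfig <- function(config) {
  def <- defaultConfig()
  unknownTop <- setdiff(names(config), names(def))
  if (length(unknownTop))
    stop("unknown config keys: ", paste(unknownTop, collapse = ", "))
  for (sec in names(config)) {
    unknown <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(unknown))
      stop("unknown keys in '", sec, "': ", paste(unknown, collapse = ", "))
    def[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  cfg <- def
  ## class validators enforce the parameter invariants
  configLQ(cfg); configOER(cfg); configBio(cfg); configTOM(cfg)
  configConstraints(cfg)
  if (any(diff(cfg$population$doseLevels) <= 0))
    stop("population$doseLevels must be strictly increasing")
  bad <- setdiff(cfg$run$schemes, c("uniform", "1F", "2F", "3F", "FBF3W", "FBF4W"))
  if (length(bad)) stop("unknown schemes: ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$run$tumors, c("T1", "T2", "T3", "T4"))
  if (length(bad)) stop("unknown tumors: ", paste(bad, collapse = ", "))
  if (!cfg$run$objective %in% c("uniform", "surv", "std"))
    stop("run$objective must be uniform, surv or std")
  cfg
}

#' Read / write a configuration as YAML
#'
#' @param path file path
#' @param config a config list
#' @return `readConfig` returns the validated config list
#' @export
readConfig <- function(path) validateConfig(yaml::read_yaml(path))

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run a full dose-painting experiment
#'
#' Executes the pipeline for every requested tumor and scheme: build (or
#' reuse the cached) oxygen lookup, generate the virtual tumors, pre-compute
#' the adaptive plans on the mean-radiosensitivity trajectory, simulate the
#' patient population over the dose levels and fit the TCP model. Results
#' (per-day trajectories, per-level control tables, D50 summary) are
#' returned and, when `outputDir` is given, written as CSV/JSON together
#' with a copy of the config; each output records the config's MD5 hash.
#'
#' @param config a config list (validated with [validateConfig()])
#' @param outputDir directory for CSV/JSON outputs (NULL: return only)
#' @param lookup optionally a pre-built [OxygenLookup-class]
#' @param tumors optionally pre-built tumors (list as from [virtualTumors()])
#' @return list: `tcp` (named list of [TCPResult-class]), `gains` (Gy,
#'   relative to each tumor's uniform treatment when available),
#'   `trajectories`, `configHash`
#' @export
runExperiment <- function(config = defaultConfig(), outputDir = NULL,
                          lookup = NULL, tumors = NULL) {
  cfg <- validateConfig(config)
  lq <- configLQ(cfg); oerp <- configOER(cfg); bio <- configBio(cfg)
  cn <- configConstraints(cfg)
  seed <- cfg$run$seed
  cfgFile <- tempfile(fileext = ".yaml")
  writeConfig(cfg, cfgFile)
  cfgHash <- unname(tools::md5sum(cfgFile))
  if (is.null(lookup))
    lookup <- defaultOxygenLookup(configTOM(cfg), cfg$run$lookupQuality, seed)
  if (is.null(tumors))
    tumors <- virtualTumors(bio, lookup, cfg$tumor$uniformVf,
                            dims = cfg$tumor$dims,
                            voxelSide = cfg$tumor$voxelSide,
                            targetVoxels = cfg$tumor$targetVoxels)
  levels_ <- cfg$population$doseLevels
  tcp <- list(); trajectories <- list(); gains <- list()
  for (tu in cfg$run$tumors) {
    grid <- tumors[[tu]]
    uniD50 <- NULL
    for (sc in cfg$run$schemes) {
      obj <- if (sc == "uniform") "uniform" else cfg$run$objective
      key <- paste(tu, sc, obj, sep = "_")
      plans <- NULL
      if (sc != "uniform") {
        plansRun <- runTreatment(grid, treatmentSchedule(sc, max(levels_)),
                                 obj, cn, lq, oerp, bio, lookup,
                                 stochastic = FALSE, planLq = lq)
        plans <- plansRun$plans
        trajectories[[paste0(key, "_meanAlpha")]] <- plansRun$trajectory
      } else {
        uniRun <- runTreatment(grid, treatmentSchedule(sc, max(levels_)),
                               "uniform", cn, lq, oerp, bio, lookup,
                               stochastic = FALSE)
        trajectories[[paste0(key, "_meanAlpha")]] <- uniRun$trajectory
      }
      out <- simulatePopulation(grid, sc, obj, plans, levels_,
                                cfg$population$nPerDose, lq, oerp, bio,
                                lookup, cn, cfg$population$alphaFloor,
                                seed = seed)
      tcp[[key]] <- tcpAnalysis(out, sc, obj, cfg$population$nBoot, seed)
      if (sc == "uniform") uniD50 <- tcp[[key]]@d50
      else if (!is.null(uniD50))
        gains[[key]] <- treatmentGain(uniD50, tcp[[key]]@d50)
    }
  }
  res <- list(tcp = tcp, gains = gains, trajectories = trajectories,
              configHash = cfgHash)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    file.copy(cfgFile, file.path(outputDir, "config.yaml"), overwrite = TRUE)
    for (key in names(trajectories)) {
      tr <- trajectories[[key]]
      tr$configHash <- cfgHash
      utils::write.csv(tr, file.path(outputDir, paste0("trajectory_", key, ".csv")),
                       row.names = FALSE)
    }
    summ <- lapply(names(tcp), function(k) {
      x <- tcp[[k]]
      list(tumor_scheme_objective = k, d50 = x@d50,
           d50_uncertainty = x@d50Uncertainty,
           gain = if (!is.null(gains[[k]])) gains[[k]] else NA,
           configHash = cfgHash)
    })
    jsonlite::write_json(summ, file.path(outputDir, "tcp_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tabs <- do.call(rbind, lapply(names(tcp), function(k)
      cbind(run = k, tcp[[k]]@table, configHash = cfgHash)))
    utils::write.csv(tabs, file.path(outputDir, "tcp_levels.csv"),
                     row.names = FALSE)
  }
  res
}
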