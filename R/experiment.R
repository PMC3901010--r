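#' @include AllClasses.R
NULL

#' Default experiment configuration
#'
#' Nested list of every model and analysis parameter with its default
#' value: cell membrane constants, band-cell population parameters,
#' random-walk parameters, and analysis options (bin sizes, filter
#' bands, shuffle and bin counts, window length). `cell$Vt` may be the
#' string `"auto"` to derive the threshold from `cell$tauGL` via
#' [thresholdForTau()].
#'
#' @return a named nested list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    cell = list(tauGL = 0.1, EL = -67, Vt = -56, dt = 0.002),
    bands = list(thetaHz = 6, beta = 0.002, gain = 30, a = 4, T = 1,
                 GI = 100,
                 phiOffset = seq(0, 300, by = 60),
                 phiPreferred = seq(0, 300, by = 60)),
    walk = list(stepSize = 1.7, momentum = 0.999, reverseFactor = 0.6,
                arenaHalfWidth = 100, initialStep = c(0.35, 0.35)),
    trajectory = list(type = "random_walk", duration = 2000,
                      start = c(-100, 0), end = c(100, 0), speed = 5,
                      path = ""),
    analysis = list(classBinSize = 5, fieldBinSize = 1, smoothSd = 5,
                    nShuffles = 1000, nBins = 8, window = 1,
                    dcBand = c(0.1, 3), thetaBand = c(5, 10))
  )
}

#' Read an experiment configuration file
#'
#' Reads a YAML key/value file with the sections of [defaultConfig()].
#' Unspecified keys keep their defaults; unknown keys raise an error
#' (typo protection). An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path, or `NULL`/missing file for pure defaults.
#' @return the merged configuration list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  mergeConfig(cfg, user, "")
}

mergeConfig <- function(def, user, prefix) {
  if (!is.list(user)) stop("malformed config section '", prefix, "'")
  for (key in names(user)) {
    if (!key %in% names(def))
      stop("unknown config key '", paste0(prefix, key), "'")
    if (is.list(def[[key]])) {
      def[[key]] <- mergeConfig(def[[key]], user[[key]],
                                paste0(prefix, key, "$"))
    } else {
      val <- user[[key]]
      if (is.numeric(def[[key]]) && !is.numeric(val))
        stop("config key '", paste0(prefix, key), "' must be numeric")
      def[[key]] <- val
    }
  }
  def
}

configBands <- function(cfg) {
  b <- cfg$bands
  bandParams(phiOffset = b$phiOffset, phiPreferred = b$phiPreferred,
             omegaB = 2 * pi * b$thetaHz, beta = b$beta, gain = b$gain,
             a = b$a, T = b$T, GI = b$GI)
}

configCell <- function(cfg) {
  cc <- cfg$cell
  vt <- cc$Vt
  if (identical(vt, "auto")) vt <- thresholdForTau(cc$tauGL * 1000)
  cellParams(tauGL = cc$tauGL, EL = cc$EL, Vt = vt, dt = cc$dt)
}

configTrajectory <- function(cfg) {
  tj <- cfg$trajectory
  switch(tj$type,
    random_walk = {
      w <- cfg$walk
      randomWalk(tj$duration, stepSize = w$stepSize,
                 momentum = w$momentum, reverseFactor = w$reverseFactor,
                 arenaHalfWidth = w$arenaHalfWidth, dt = cfg$cell$dt,
                 initialStep = w$initialStep, seed = cfg$seed)
    },
    straight_line = straightLineTrajectory(tj$start, tj$end,
                                           speed = tj$speed,
                                           dt = cfg$cell$dt),
    file = readTrajectory(tj$path, targetDt = cfg$cell$dt),
    stop("unknown trajectory type '", tj$type, "'")
  )
}

#' Run a full simulation and analysis experiment
#'
#' Generates (or loads) the trajectory, simulates the grid cell,
#' classifies fields, decomposes the membrane potential into DC-shift
#' and theta-envelope series, and computes the headline statistics
#' (amplitude differences, gridness, phase precession). When `outDir`
#' is given, writes `trajectory.csv`, `trace.csv`, `spikes.csv`,
#' `rate_map.csv`, `classification.csv`, `amplitudes.csv` and
#' `summary.json` (the summary embeds the full configuration and seed,
#' so identical configurations reproduce identical outputs).
#'
#' @param config configuration list from [readConfig()] /
#'   [defaultConfig()].
#' @param outDir optional output directory, created if needed.
#' @return (invisibly) a list with the component objects and a `summary`
#'   list of scalar results.
#' @export
runExperiment <- function(config = defaultConfig(), outDir = NULL) {
  set.seed(config$seed)
  bands <- configBands(config)
  params <- configCell(config)
  an <- config$analysis
  message("trajectory: ", config$trajectory$type)
  traj <- configTrajectory(config)
  message("simulate: ", length(traj@t), " samples")
  trace <- simulateGridCell(traj, bands, params)
  message("classify: ", an$nShuffles, " shuffles")
  null <- shuffleNull(traj, trace@spike, binSize = an$classBinSize,
                      nShuffles = an$nShuffles, seed = config$seed)
  cls <- classifyFields(null)
  hasBoth <- all(c("in_field", "out_of_field") %in%
                   sampleLabels(cls))
  amp <- amplitudeSeries(trace, if (hasBoth) cls else NULL,
                         dcBand = an$dcBand, thetaBand = an$thetaBand)
  delta <- if (hasBoth) deltaAmplitudes(amp, cls) else
    c(dc = NA_real_, mpo = NA_real_)
  rm5 <- rateMap(traj, trace@spike, binSize = an$classBinSize)
  gridness <- tryCatch(gridnessScore(rm5)$score, error = function(e) {
    warning(conditionMessage(e))
    NA_real_
  })
  prec <- tryCatch(
    precessionAnalysis(trace, traj,
                       mode = if (config$trajectory$type ==
                                    "straight_line")
                         "position" else "pass_index"),
    error = function(e) NULL)
  summary <- list(
    seed = config$seed,
    nSamples = length(traj@t),
    meanSpeed = mean(traj@speed),
    nSpikeSamples = sum(trace@spike),
    deltaAmpDC = unname(delta[["dc"]]),
    deltaAmpMPO = unname(delta[["mpo"]]),
    gridness = gridness,
    precessionRho = if (is.null(prec)) NA_real_ else prec@rho,
    precessionP = if (is.null(prec)) NA_real_ else prec@p,
    config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTrajectory(traj, file.path(outDir, "trajectory.csv"))
    utils::write.csv(as.data.frame(trace),
                     file.path(outDir, "trace.csv"), row.names = FALSE)
    utils::write.csv(data.frame(t = spikeTimes(trace)),
                     file.path(outDir, "spikes.csv"),
                     row.names = FALSE)
    utils::write.csv(rm5@rate, file.path(outDir, "rate_map.csv"),
                     row.names = FALSE)
    utils::write.csv(cls@label,
                     file.path(outDir, "classification.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(t = amp@t, dc_shift = amp@dcShift,
                 mpo_envelope = amp@mpoEnvelope),
      file.path(outDir, "amplitudes.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(traj = traj, trace = trace, classification = cls,
                 amplitudes = amp, rateMap = rm5, precession = prec,
                 summary = summary))
}
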