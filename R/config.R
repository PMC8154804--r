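#' Run configuration for the staged workflow
#'
#' Bundles every parameter of a reproducible run: cohort design, artifact
#' model, preprocessing variants, quantification grid, fit settings, the
#' mandatory seed and the output directory. Serialized to YAML by
#' [writeRunConfig()]; all randomness of a run derives from `seed`.
#'
#' @param seed integer seed (mandatory).
#' @param outputDir where stage outputs are written.
#' @param cohort a [cohortSpec()].
#' @param artifacts an [artifactSpec()].
#' @param region resonance table region (`"hippocampus"` or `"pcc"`).
#' @param variants variant labels to process.
#' @param grid a [gridSpec()].
#' @param nsDiff,nsOff,beta fit settings used by the quantify stage.
#' @return a classed configuration list.
#' @export
runConfig <- function(seed, outputDir = "mrs_run",
                      cohort = cohortSpec(seed = seed),
                      artifacts = artifactSpec(),
                      region = "hippocampus",
                      variants = standardVariants(TRUE),
                      grid = gridSpec(),
                      nsDiff = 3L, nsOff = 4L, beta = 1500) {
  if (missing(seed)) stop("seed is mandatory")
  cohort$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), outputDir = outputDir, cohort = cohort,
         artifacts = artifacts, region = region, variants = variants,
         grid = grid, nsDiff = as.integer(nsDiff), nsOff = as.integer(nsOff),
         beta = beta),
    class = "RunConfig"
  )
}

# scalar-only view of a config, suitable for YAML and hashing
.configAsList <- function(config) {
  ch <- config$cohort
  list(
    seed = config$seed, outputDir = config$outputDir,
    region = config$region, variants = config$variants,
    nsDiff = config$nsDiff, nsOff = config$nsOff, beta = config$beta,
    cohort = list(
      nSubjects = ch$nSubjects, nMeasurements = ch$nMeasurements,
      nOn = ch$nOn, nOff = ch$nOff, nCoils = ch$nCoils,
      betweenSubjectCv = ch$betweenSubjectCv, noiseSd = ch$noiseSd,
      waterAmplitude = ch$waterAmplitude,
      residualWaterFraction = ch$residualWaterFraction,
      nPoints = ch$axis@nPoints, dwellTime = ch$axis@dwellTime,
      transmitterFrequency = ch$axis@transmitterFrequency,
      referencePpm = ch$axis@referencePpm),
    artifacts = config$artifacts[c("phaseDriftSd", "frequencyDriftSd",
                                   "eddyAmplitude", "eddyTimeConstant")],
    grid = list(betaValues = config$grid$betaValues,
                nsValues = config$grid$nsValues)
  )
}

#' Stable hash of a run configuration
#'
#' Covers every scientific parameter of the run; the output directory is
#' excluded so that identical analyses written to different locations
#' share a hash.
#'
#' @param config a [runConfig()].
#' @return character hash.
#' @export
configHash <- function(config) {
  l <- .configAsList(config)
  l$outputDir <- NULL
  rlang::hash(l)
}

#' @rdname runConfig
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("seed", "cohort", "artifacts", "grid"))
    if (is.null(y[[k]])) stop("config is missing field ", k)
  ch <- y$cohort
  runConfig(
    seed = y$seed, outputDir = y$outputDir, region = y$region,
    variants = unlist(y$variants),
    cohort = cohortSpec(
      nSubjects = ch$nSubjects, nMeasurements = ch$nMeasurements,
      nOn = ch$nOn, nOff = ch$nOff, nCoils = ch$nCoils,
      betweenSubjectCv = ch$betweenSubjectCv, noiseSd = ch$noiseSd,
      waterAmplitude = ch$waterAmplitude,
      residualWaterFraction = ch$residualWaterFraction,
      axis = spectralAxis(ch$nPoints, ch$dwellTime, ch$transmitterFrequency,
                          ch$referencePpm),
      seed = y$seed),
    artifacts = artifactSpec(
      phaseDriftSd = y$artifacts$phaseDriftSd,
      frequencyDriftSd = y$artifacts$frequencyDriftSd,
      eddyAmplitude = y$artifacts$eddyAmplitude,
      eddyTimeConstant = y$artifacts$eddyTimeConstant),
    grid = gridSpec(unlist(y$grid$betaValues), unlist(y$grid$nsValues)),
    nsDiff = y$nsDiff, nsOff = y$nsOff, beta = y$beta
  )
}
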