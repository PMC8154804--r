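## Staged workflow behind the command-line entry point. Each stage reads
## and writes documented file products under config$outputDir and logs the
## seed and configuration hash, so every numeric output is reproducible
## from (config, seed).

.stageLog <- function(config, stage, ...) {
  message(sprintf("[%s] seed=%d hash=%s %s", stage, config$seed,
                  configHash(config), paste0(...)))
}

#' Simulate stage: write a synthetic cohort to disk
#'
#' Simulates the configured cohort, coil-combines each measurement and
#' writes one jMRUI text file per measurement (water reference followed by
#' the interleaved transients, edit states recorded in the header), plus a
#' tab-separated ground-truth table and a YAML manifest carrying the
#' configuration hash.
#'
#' @param config a [runConfig()].
#' @return invisibly, the output directory.
#' @export
runSimulateStage <- function(config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  .stageLog(config, "simulate", "starting")
  cohort <- simulateCohort(config$cohort,
                           defaultResonanceTable(config$region),
                           config$artifacts)
  simDir <- file.path(config$outputDir, "simulated")
  dir.create(simDir, showWarnings = FALSE)
  for (key in names(cohort$sets)) {
    s <- cohort$sets[[key]]
    sc <- if (nCoils(s) > 1L) combineCoils(s, estimateCoilWeights(s)) else s
    sig <- lapply(seq_len(nTransients(sc)), function(j) transientFid(sc, j))
    writeJmrui(sig, sc@axis, file.path(simDir, paste0(key, ".txt")),
               signalNames = editStates(sc),
               extraInfo = c(ConfigHash = configHash(config),
                             Subject = sc@subjectId,
                             Measurement = as.character(sc@measurementIndex)))
  }
  utils::write.table(cohort$manifest,
                     file.path(config$outputDir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(configHash = configHash(config), seed = config$seed,
         measurements = names(cohort$sets)),
    file.path(config$outputDir, "manifest.yaml"))
  .stageLog(config, "simulate", "wrote ", length(cohort$sets),
            " measurements")
  invisible(config$outputDir)
}

# read one simulated measurement back as a single-coil TransientSet
.readSimulatedSet <- function(path) {
  doc <- readJmrui(path)
  n <- doc$axis@nPoints
  data <- array(0i, dim = c(n, 1L, length(doc$signals)))
  for (j in seq_along(doc$signals)) data[, 1L, j] <- doc$signals[[j]]
  info <- doc$header[["AdditionalInfo"]]
  getField <- function(key, default) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    if (length(m)) sub(paste0(key, "="), "", m) else default
  }
  transientSet(data, doc$signalNames, doc$axis,
               subjectId = getField("Subject", "S?"),
               measurementIndex = as.integer(getField("Measurement", "1")))
}

#' Preprocess stage: run the configured variants on the simulated cohort
#'
#' Reads every measurement written by [runSimulateStage()], runs all
#' configured preprocessing variants and writes one off/diff/water jMRUI
#' file per (measurement, variant).
#'
#' @param config a [runConfig()].
#' @return invisibly, the directory of processed pairs.
#' @export
runPreprocessStage <- function(config) {
  simDir <- file.path(config$outputDir, "simulated")
  files <- list.files(simDir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no simulated measurements under ", simDir)
  outDir <- file.path(config$outputDir, "processed")
  dir.create(outDir, showWarnings = FALSE)
  .stageLog(config, "preprocess", length(files), " measurements")
  for (f in files) {
    set <- .readSimulatedSet(f)
    pairs <- processMeasurement(set, config$variants)
    key <- sub("\\.txt$", "", basename(f))
    for (v in names(pairs)) {
      exportProcessedPair(pairs[[v]], file.path(
        outDir, sprintf("%s__%s.txt", key, gsub("\\+", "-", v))))
    }
  }
  invisible(outDir)
}

#' Quantify stage: fit every processed pair at the configured parameters
#'
#' @param config a [runConfig()].
#' @return invisibly, the path of the results table (`results.tsv`:
#'   subject, measurement, variant, ns pair, beta, ratio, GABA CRLB%,
#'   NAA FWHM, SNR).
#' @export
runQuantifyStage <- function(config) {
  procDir <- file.path(config$outputDir, "processed")
  files <- list.files(procDir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no processed pairs under ", procDir)
  .stageLog(config, "quantify", length(files), " pairs")
  resonances <- defaultResonanceTable(config$region)
  rows <- NULL
  for (f in files) {
    pair <- importProcessedPair(f)
    key <- strsplit(sub("\\.txt$", "", basename(f)), "__")[[1]]
    q <- quantifyPair(pair, resonances, beta = config$beta,
                      nsDiff = config$nsDiff, nsOff = config$nsOff)
    rows <- rbind(rows, data.frame(
      measurement = key[1], variant = gsub("-", "+", key[2]),
      nsDiff = config$nsDiff, nsOff = config$nsOff, beta = config$beta,
      ratio = q$ratio, gabaCrlbPercent = q$gabaCrlb,
      fwhmHz = q$fwhm$hz, snrOff = q$snrOff, snrDiff = q$snrDiff))
  }
  out <- file.path(config$outputDir, "results.tsv")
  utils::write.table(rows, out, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Report stage: full in-memory variant comparison and optimization
#'
#' Simulates the configured cohort and runs [comparePipelines()] over the
#' configured grid, writing the report files via [writeReport()].
#'
#' @param config a [runConfig()].
#' @param verbose print progress.
#' @return the [OptimizationReport-class], invisibly.
#' @export
runReportStage <- function(config, verbose = TRUE) {
  .stageLog(config, "report", "starting")
  cohort <- simulateCohort(config$cohort,
                           defaultResonanceTable(config$region),
                           config$artifacts)
  report <- comparePipelines(cohort, config$grid, config$variants,
                             verbose = verbose)
  writeReport(report, file.path(config$outputDir, "report"))
  .stageLog(config, "report", "done")
  invisible(report)
}
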