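## End-to-end variant comparison: preprocess a cohort under every variant,
## quantify over the parameter grid, assemble the cohort table and run both
## optimization steps.

#' Quantify one processed pair at a single parameter setting
#'
#' Fits the difference and edit-off signals with their respective bases and
#' returns the GABA+/tCr ratio together with the quality metrics.
#'
#' @param pair a [ProcessedPair-class].
#' @param resonances resonance table defining the bases.
#' @param beta Gaussian-damping start value (1/s^2).
#' @param nsDiff,nsOff FID start points for the two fits.
#' @param waterRemoval band-stop the residual-water region of the
#'   difference signal before fitting (see [removeWaterBand()]); the
#'   difference basis then carries no water entry.
#' @param ... further [fitConfig()] fields.
#' @return list with `ratio`, `diffFit`, `offFit`, `fwhm` (list hz/ppm),
#'   `snrOff`, `snrDiff`, `gabaCrlb` (CRLB% of the GABA entry).
#' @export
quantifyPair <- function(pair, resonances = defaultResonanceTable(),
                         beta = 500, nsDiff = 1L, nsOff = 1L,
                         waterRemoval = TRUE, ...) {
  stopifnot(is(pair, "ProcessedPair"))
  axis <- pair@offFid@axis
  offBasis <- makeBasisSet(resonances, axis, "off")
  diffBasis <- makeBasisSet(resonances, axis, "diff",
                            extraEntries = if (waterRemoval) "NAA"
                                           else c("NAA", "h2o"))
  diffIn <- if (waterRemoval) removeWaterBand(pair@diffFid) else pair@diffFid
  offFit <- fitSpectrum(pair@offFid, offBasis,
                        fitConfig(ns = nsOff, beta = beta, ...))
  diffFit <- fitSpectrum(diffIn, diffBasis,
                         fitConfig(ns = nsDiff, beta = beta, ...))
  list(
    ratio = gabaTcrRatio(diffFit, offFit),
    diffFit = diffFit, offFit = offFit,
    fwhm = fwhmNaa(offFit),
    snrOff = snrNaa(offFit, pair@offFid),
    # the difference spectrum has no NAA (it cancels in the subtraction), so
    # its SNR is assessed on the dominant edited resonance at 3.0 ppm
    snrDiff = snrNaa(diffFit, diffIn, peakSpanPpm = c(2.8, 3.2)),
    gabaCrlb = crlbPercent(diffFit)[["GABA"]]
  )
}

#' Ratio grid of one processed pair
#'
#' Because the difference fit depends only on `nsDiff` and the edit-off fit
#' only on `nsOff`, the full pair grid costs one difference fit and one
#' off fit per ns value; ratios for all pairs are their outer combination.
#'
#' @param pair a [ProcessedPair-class].
#' @param offBasis,diffBasis prebuilt [BasisSet-class] objects.
#' @param beta Gaussian-damping start value.
#' @param nsValues FID start points.
#' @param waterRemoval as in [quantifyPair()]; the supplied `diffBasis`
#'   should match (no water entry when `TRUE`).
#' @param ... further [fitConfig()] fields.
#' @return list with `ratio` (matrix `nsDiff x nsOff`, dimnames the ns
#'   values), `gabaAmp`, `gabaCrlb`, `tcrAmp` (per-ns vectors).
#' @export
ratioGrid <- function(pair, offBasis, diffBasis, beta, nsValues,
                      waterRemoval = TRUE, ...) {
  gabaAmp <- gabaCrlb <- tcrAmp <- stats::setNames(
    numeric(length(nsValues)), nsValues)
  mmAmp <- gabaAmp
  diffIn <- if (waterRemoval) removeWaterBand(pair@diffFid) else pair@diffFid
  l1 <- function(basis, entry) basis@coeffL1[match(entry, basis@entryNames)]
  for (i in seq_along(nsValues)) {
    dFit <- fitSpectrum(diffIn, diffBasis,
                        fitConfig(ns = nsValues[i], beta = beta, ...))
    gabaAmp[i] <- amplitudes(dFit)[["GABA"]] * l1(diffBasis, "GABA")
    mmAmp[i] <- if ("MM30" %in% names(amplitudes(dFit)))
      amplitudes(dFit)[["MM30"]] * l1(diffBasis, "MM30") else 0
    gabaCrlb[i] <- crlbPercent(dFit)[["GABA"]]
    oFit <- fitSpectrum(pair@offFid, offBasis,
                        fitConfig(ns = nsValues[i], beta = beta, ...))
    tcrAmp[i] <- amplitudes(oFit)[["tCr30"]] * l1(offBasis, "tCr30")
  }
  tcrAmp[tcrAmp <= 0] <- NA_real_   # failed edit-off fit: no denominator
  ratio <- outer(gabaAmp + mmAmp, tcrAmp, "/")
  dimnames(ratio) <- list(nsDiff = nsValues, nsOff = nsValues)
  list(ratio = ratio, gabaAmp = gabaAmp + mmAmp, gabaCrlb = gabaCrlb,
       tcrAmp = tcrAmp)
}

#' Variant comparison and quantification-parameter optimization report
#'
#' @slot chosenBeta selected Gaussian-damping start value.
#' @slot chosenNs named integer vector `c(diff = , off = )`.
#' @slot cohortTable per (subject, measurement, variant, beta, ns pair)
#'   ratios.
#' @slot mcovTable mean intra-session CoV per (variant, beta, ns pair).
#' @slot covSummary per-variant intra/inter CoV at the optimum.
#' @slot decile per-variant first-decile mean CoV over the ns grid.
#' @slot quality mean NAA FWHM / SNR of the optimal variant.
#' @slot grid the [gridSpec()] used.
#' @exportClass OptimizationReport
setClass("OptimizationReport",
  representation(
    chosenBeta = "numeric", chosenNs = "integer",
    cohortTable = "data.frame", mcovTable = "data.frame",
    covSummary = "data.frame", decile = "data.frame",
    quality = "list", grid = "list"
  )
)

setMethod("show", "OptimizationReport", function(object) {
  cat("OptimizationReport\n")
  cat(sprintf("  chosen beta_s: %g 1/s^2; chosen n_s: diff %d, off %d\n",
              object@chosenBeta, object@chosenNs[["diff"]],
              object@chosenNs[["off"]]))
  cat(sprintf("  quality (optimal variant %s): NAA FWHM %.1f Hz (%.3f ppm), SNR off %.1f / diff %.1f\n",
              object@quality$variant, object@quality$fwhmHz,
              object@quality$fwhmPpm, object@quality$snrOff,
              object@quality$snrDiff))
  cat("  per-variant CoV at the optimum (%):\n")
  s <- object@covSummary
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-12s intra %5.1f  inter %5.1f +- %.1f\n",
                s$variant[i], 100 * s$mcovIntra[i], 100 * s$mcovInter[i],
                100 * s$interError[i]))
})

# mean intra-session CoV for each (variant, beta, ns pair) of a cohort table
.mcovFromTable <- function(tab, nMeasurements) {
  keys <- unique(tab[, c("variant", "beta", "nsDiff", "nsOff")])
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- tab[tab$variant == k$variant & tab$beta == k$beta &
                 tab$nsDiff == k$nsDiff & tab$nsOff == k$nsOff, ]
    out <- rbind(out, data.frame(
      k, mcovIntra = mCovIntra(sub, nMeasurements), row.names = NULL))
  }
  out
}

#' Compare preprocessing variants over the quantification parameter grid
#'
#' Runs the full analysis on a simulated (or otherwise assembled) cohort:
#' coil combination, every preprocessing variant, linear-combination
#' quantification over the parameter grid, the two optimization steps
#' (beta first, then the ns pair), the per-variant CoV summary at the
#' optimum and the first-decile grid summary.
#'
#' @param cohort result of [simulateCohort()], or a list with elements
#'   `sets` (multi-coil [TransientSet-class] list), `spec` and
#'   `resonances`.
#' @param grid a [gridSpec()]; the full default grid is expensive, reduced
#'   grids are recommended for interactive use.
#' @param variants variant labels to compare (must include `"SR"` and
#'   `"ECC+SR+DAS"` for the beta step and the six standard routines for
#'   the ns step; defaults comply).
#' @param srWindow spectral-registration misfit window (s).
#' @param verbose print progress.
#' @return an [OptimizationReport-class].
#' @export
comparePipelines <- function(cohort, grid = gridSpec(),
                             variants = standardVariants(TRUE),
                             srWindow = 0.4, verbose = FALSE) {
  resonances <- cohort$resonances
  spec <- cohort$spec
  axis <- spec$axis
  offBasis <- makeBasisSet(resonances, axis, "off")
  diffBasis <- makeBasisSet(resonances, axis, "diff", extraEntries = "NAA")
  nsVals <- grid$nsValues
  nMeas <- spec$nMeasurements

  say <- function(...) if (verbose) message(...)
  say("preprocessing ", length(cohort$sets), " measurements, ",
      length(variants), " variants")
  pairs <- lapply(cohort$sets, function(s) {
    sc <- if (nCoils(s) > 1L) combineCoils(s, estimateCoilWeights(s)) else s
    processMeasurement(sc, variants, srWindow = srWindow)
  })
  meta <- do.call(rbind, lapply(cohort$sets, function(s) data.frame(
    subject = s@subjectId, measurement = s@measurementIndex)))

  gridRows <- function(variantSel, betas) {
    out <- NULL
    for (v in variantSel) for (b in betas) {
      say("  grid: ", v, " beta ", b)
      for (i in seq_along(pairs)) {
        rg <- ratioGrid(pairs[[i]][[v]], offBasis, diffBasis, b, nsVals)
        df <- expand.grid(nsDiff = nsVals, nsOff = nsVals)
        df$ratio <- as.vector(rg$ratio)
        out <- rbind(out, data.frame(
          subject = meta$subject[i], measurement = meta$measurement[i],
          variant = v, beta = b, df, row.names = NULL))
      }
    }
    out
  }

  # step 1: beta on the standard and advanced routines
  betaVariants <- intersect(c("SR", "ECC+SR+DAS"), variants)
  tab1 <- gridRows(betaVariants, grid$betaValues)
  mcov1 <- .mcovFromTable(tab1, nMeas)
  stepBeta <- optimizeBeta(mcov1, grid, betaVariants)
  chosenBeta <- stepBeta$beta
  say("chosen beta: ", chosenBeta)

  # step 2: ns pair on all requested variants at the chosen beta
  tab2 <- gridRows(variants, chosenBeta)
  mcov2 <- .mcovFromTable(tab2, nMeas)
  nsVariants <- intersect(standardVariants(), variants)
  stepNs <- optimizeStartPoints(
    mcov2[mcov2$variant %in% nsVariants, , drop = FALSE], grid, nsVariants)
  chosenNs <- c(diff = as.integer(stepNs$nsDiff),
                off = as.integer(stepNs$nsOff))
  say("chosen ns pair: ", chosenNs[1], "/", chosenNs[2])

  # per-variant CoV at the optimum
  covSummary <- NULL
  for (v in variants) {
    sub <- tab2[tab2$variant == v & tab2$nsDiff == chosenNs[["diff"]] &
                  tab2$nsOff == chosenNs[["off"]], ]
    ci <- covInter(sub)
    covSummary <- rbind(covSummary, data.frame(
      variant = v, mcovIntra = mCovIntra(sub, nMeas),
      mcovInter = ci$mean, interError = ci$error))
  }
  dec <- decileSummary(mcov2)

  # quality metrics of the inter-CoV-optimal non-plain variant
  nonPlain <- covSummary[covSummary$variant != "plain", ]
  bestVariant <- nonPlain$variant[which.min(nonPlain$mcovInter)]
  fw <- sn <- sd2 <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    q <- quantifyPair(pairs[[i]][[bestVariant]], resonances,
                      beta = chosenBeta,
                      nsDiff = chosenNs[["diff"]], nsOff = chosenNs[["off"]])
    fw[i] <- q$fwhm$hz; sn[i] <- q$snrOff; sd2[i] <- q$snrDiff
  }
  quality <- list(variant = bestVariant, fwhmHz = mean(fw),
                  fwhmPpm = hzToPpm(mean(fw), axis), snrOff = mean(sn),
                  snrDiff = mean(sd2))

  new("OptimizationReport",
    chosenBeta = chosenBeta, chosenNs = chosenNs,
    cohortTable = rbind(tab1, tab2), mcovTable = rbind(mcov1, mcov2),
    covSummary = covSummary, decile = dec, quality = quality,
    grid = unclass(grid))
}

#' Write an optimization report to tab-separated files
#'
#' Writes `cohort_table.tsv`, `mcov_table.tsv`, `cov_summary.tsv`,
#' `decile.tsv` and a human-readable `report.txt` into `dir`.
#'
#' @param report an [OptimizationReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "OptimizationReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cohort_table.tsv", "mcov_table.tsv",
                            "cov_summary.tsv", "decile.tsv", "report.txt"))
  utils::write.table(report@cohortTable, paths[1], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report@mcovTable, paths[2], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report@covSummary, paths[3], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report@decile, paths[4], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sink(paths[5]); show(report); sink()
  invisible(paths)
}

#' Read back a cohort table written by [writeReport()]
#'
#' @param path path to `cohort_table.tsv`.
#' @return the cohort table data.frame.
#' @export
readCohortTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
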