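#' Preprocessing pipeline variant
#'
#' One of the preprocessing routines applied between coil combination and
#' quantification: optional eddy-current compensation (ECC), optional
#' spectral registration (SR) and an optional on/off alignment before
#' subtraction (difference-artifact suppression, DAS, or difference
#' optimization, DO). DAS/DO are only defined on top of SR. The `"plain"`
#' variant (none of the three) is the straight-averaging baseline.
#'
#' @slot ecc logical, apply eddy-current compensation.
#' @slot sr logical, apply spectral registration.
#' @slot dasMode `"none"`, `"das"` or `"do"`.
#' @exportClass PipelineVariant
setClass("PipelineVariant",
  representation(ecc = "logical", sr = "logical", dasMode = "character")
)

setValidity("PipelineVariant", function(object) {
  msg <- character()
  if (!object@dasMode %in% c("none", "das", "do"))
    msg <- c(msg, "dasMode must be 'none', 'das' or 'do'")
  if (object@dasMode != "none" && !object@sr)
    msg <- c(msg, "DAS/DO require spectral registration")
  if (length(msg)) msg else TRUE
})

#' @rdname PipelineVariant-class
#' @param ecc,sr logical flags.
#' @param dasMode `"none"`, `"das"` or `"do"`.
#' @return a [PipelineVariant-class].
#' @export
pipelineVariant <- function(ecc = FALSE, sr = TRUE, dasMode = "none") {
  new("PipelineVariant", ecc = ecc, sr = sr, dasMode = dasMode)
}

#' Parse a variant label such as `"ECC+SR+DAS"`
#'
#' Recognized labels: `"plain"`, `"SR"`, `"ECC+SR"`, `"SR+DAS"`,
#' `"ECC+SR+DAS"`, `"SR+DO"`, `"ECC+SR+DO"`.
#'
#' @param label character label.
#' @return a [PipelineVariant-class].
#' @export
parseVariant <- function(label) {
  if (identical(label, "plain"))
    return(pipelineVariant(FALSE, FALSE, "none"))
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  bad <- setdiff(parts, c("ECC", "SR", "DAS", "DO"))
  if (length(bad)) stop("unknown variant component: ", paste(bad, collapse = ", "))
  pipelineVariant(
    ecc = "ECC" %in% parts, sr = "SR" %in% parts,
    dasMode = if ("DAS" %in% parts) "das" else if ("DO" %in% parts) "do"
              else "none"
  )
}

#' @rdname PipelineVariant-class
#' @param x a `PipelineVariant`.
#' @return `variantLabel`: the canonical label string.
#' @export
variantLabel <- function(x) {
  if (!x@sr && !x@ecc && x@dasMode == "none") return("plain")
  paste(c(if (x@ecc) "ECC", if (x@sr) "SR",
          switch(x@dasMode, das = "DAS", do = "DO", NULL)), collapse = "+")
}

setMethod("show", "PipelineVariant", function(object) {
  cat("PipelineVariant:", variantLabel(object), "\n")
})

#' The six tested preprocessing variants (optionally with the baseline)
#'
#' @param includePlain include the straight-averaging `"plain"` baseline.
#' @return character vector of variant labels.
#' @export
standardVariants <- function(includePlain = FALSE) {
  v <- c("SR", "ECC+SR", "SR+DAS", "ECC+SR+DAS", "SR+DO", "ECC+SR+DO")
  if (includePlain) c("plain", v) else v
}

#' Preprocessed output of one measurement under one variant
#'
#' @slot offFid averaged edit-off [Fid-class].
#' @slot diffFid on-minus-off difference [Fid-class].
#' @slot waterFid coil-combined water reference [Fid-class].
#' @slot variant the [PipelineVariant-class] that produced the pair.
#' @slot alignment per-transient spectral registration results (data.frame,
#'   empty when SR was not applied).
#' @exportClass ProcessedPair
setClass("ProcessedPair",
  representation(
    offFid = "Fid", diffFid = "Fid", waterFid = "Fid",
    variant = "PipelineVariant", alignment = "data.frame"
  )
)

setValidity("ProcessedPair", function(object) {
  ax <- object@offFid@axis
  if (!identical(ax, object@diffFid@axis) ||
      !identical(ax, object@waterFid@axis))
    return("off, diff and water FIDs must share one axis")
  TRUE
})

setMethod("show", "ProcessedPair", function(object) {
  cat("ProcessedPair (", variantLabel(object@variant), "): ",
      length(object@offFid), " points\n", sep = "")
})

#' @describeIn ProcessedPair-class averaged edit-off signal.
#' @param x,object a `ProcessedPair`.
#' @export
offFid <- function(x) x@offFid

#' @describeIn ProcessedPair-class difference signal.
#' @export
diffFid <- function(x) x@diffFid

#' @describeIn ProcessedPair-class water reference.
#' @export
pairWater <- function(x) x@waterFid

#' @describeIn ProcessedPair-class the producing variant.
#' @export
pairVariant <- function(x) x@variant

# Apply ECC to every transient of a single-coil set using its own water
# reference.
.applyEccSet <- function(set, thresholdFactor = 5) {
  w <- waterFid(set)
  out <- set@data
  for (j in seq_len(nTransients(set))) {
    out[, 1L, j] <- eddyCurrentCorrect(transientFid(set, j), w,
                                       thresholdFactor)@samples
  }
  transientSet(out, set@editState, set@axis, set@subjectId,
               set@measurementIndex)
}

#' Run one preprocessing variant on a coil-combined measurement
#'
#' Ordered application on a single-coil [TransientSet-class]:
#' eddy-current compensation per transient (if `ecc`), spectral
#' registration to the edit-off mean (if `sr`), state averaging, then DAS
#' or DO on the averages (if requested), and finally
#' `diff = onAvg - offAvg`.
#'
#' @param set a single-coil [TransientSet-class] (see [combineCoils()]).
#' @param variant a [PipelineVariant-class] or a label accepted by
#'   [parseVariant()].
#' @param srMode,srWindow passed to [spectralRegister()].
#' @param spanPpm alignment window for DAS/DO.
#' @return a [ProcessedPair-class].
#' @export
runPipeline <- function(set, variant = "ECC+SR+DAS",
                        srMode = "off_mean", srWindow = 0.4,
                        spanPpm = c(2.8, 3.5)) {
  stopifnot(is(set, "TransientSet"), nCoils(set) == 1L)
  if (is.character(variant)) variant <- parseVariant(variant)
  water <- waterFid(set)
  if (variant@ecc) {
    set <- .applyEccSet(set)
    water <- waterFid(set)
  }
  alignment <- data.frame()
  if (variant@sr) {
    sr <- spectralRegister(set, mode = srMode, window = srWindow)
    set <- sr$set
    alignment <- sr$alignment
  }
  onAvg <- stateMean(set, "on")
  offAvg <- stateMean(set, "off")
  if (variant@dasMode == "das") {
    al <- dasAlign(onAvg, offAvg, spanPpm)
    onAvg <- al$onAvg
  } else if (variant@dasMode == "do") {
    al <- doAlign(onAvg, offAvg, spanPpm)
    onAvg <- al$onAvg
  }
  new("ProcessedPair",
    offFid = offAvg, diffFid = onAvg - offAvg, waterFid = water,
    variant = variant, alignment = alignment
  )
}

#' Run several variants on one measurement, sharing intermediate work
#'
#' ECC and spectral registration results are shared between variants that
#' use them, so running all seven variants costs roughly two registrations.
#'
#' @param set a single-coil [TransientSet-class].
#' @param variants character vector of variant labels.
#' @inheritParams runPipeline
#' @return named list of [ProcessedPair-class] objects.
#' @export
processMeasurement <- function(set, variants = standardVariants(TRUE),
                               srMode = "off_mean", srWindow = 0.4,
                               spanPpm = c(2.8, 3.5)) {
  stopifnot(is(set, "TransientSet"), nCoils(set) == 1L)
  parsed <- lapply(variants, parseVariant)
  needEcc <- any(vapply(parsed, function(v) v@ecc, logical(1)))
  eccSet <- if (needEcc) .applyEccSet(set) else NULL
  cache <- list()
  avgFor <- function(ecc, sr) {
    key <- paste0(ecc, "_", sr)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- if (ecc) eccSet else set
    alignment <- data.frame()
    if (sr) {
      reg <- spectralRegister(s, mode = srMode, window = srWindow)
      s <- reg$set
      alignment <- reg$alignment
    }
    res <- list(on = stateMean(s, "on"), off = stateMean(s, "off"),
                water = waterFid(s), alignment = alignment)
    cache[[key]] <<- res
    res
  }
  out <- list()
  for (i in seq_along(parsed)) {
    v <- parsed[[i]]
    base <- avgFor(v@ecc, v@sr)
    onAvg <- base$on
    if (v@dasMode == "das") onAvg <- dasAlign(onAvg, base$off, spanPpm)$onAvg
    if (v@dasMode == "do") onAvg <- doAlign(onAvg, base$off, spanPpm)$onAvg
    out[[variants[i]]] <- new("ProcessedPair",
      offFid = base$off, diffFid = onAvg - base$off, waterFid = base$water,
      variant = v, alignment = base$alignment)
  }
  out
}
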