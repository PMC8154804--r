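## Plain-text jMRUI reader/writer. The widespread ASCII dialect is
## supported: a key/value header block followed by per-signal sections of
## four columns (signal real/imag, FFT real/imag). Binary jMRUI files are
## out of scope.

.JMRUI_REQUIRED <- c("PointsInDataset", "DatasetsInFile", "SamplingInterval",
                     "TransmitterFrequency")

#' Write signals to a jMRUI text file
#'
#' Header fields follow the jMRUI conventions: `SamplingInterval` in
#' milliseconds, `TransmitterFrequency` in Hz. The carrier reference (ppm)
#' and optional signal names/states are stored in `AdditionalInfo` and
#' recovered by [readJmrui()]. Samples are printed with nine significant
#' digits.
#'
#' @param signals a list of complex vectors / [Fid-class] objects, or a
#'   complex matrix with one signal per column.
#' @param axis the shared [SpectralAxis-class].
#' @param path output file.
#' @param signalNames optional character vector stored with the file.
#' @param extraInfo optional named character vector merged into
#'   `AdditionalInfo`.
#' @return invisibly, `path`.
#' @export
writeJmrui <- function(signals, axis, path, signalNames = NULL,
                       extraInfo = NULL) {
  if (is(signals, "Fid")) signals <- list(signals)
  if (is.matrix(signals))
    signals <- lapply(seq_len(ncol(signals)), function(j) signals[, j])
  signals <- lapply(signals, function(s)
    if (is(s, "Fid")) s@samples else as.complex(s))
  if (!length(signals) || any(lengths(signals) == 0L))
    stop("zero-length signal rejected")
  if (any(lengths(signals) != axis@nPoints))
    stop("all signals must have nPoints(axis) samples")
  nsig <- length(signals)

  info <- c(ReferencePpm = format(axis@referencePpm))
  if (!is.null(signalNames))
    info <- c(info, SignalNames = paste(signalNames, collapse = ","))
  if (!is.null(extraInfo)) info <- c(info, extraInfo)
  infoStr <- paste(sprintf("%s=%s", names(info), unname(info)),
                   collapse = "; ")

  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("jMRUI Data Textfile")
  w("")
  w("Filename: %s", basename(path))
  w("")
  w("PointsInDataset: %d", axis@nPoints)
  w("DatasetsInFile: %d", nsig)
  w("SamplingInterval: %.9E", axis@dwellTime * 1e3)
  w("ZeroOrderPhase: 0E0")
  w("BeginTime: 0E0")
  w("TransmitterFrequency: %.9E", axis@transmitterFrequency * 1e6)
  w("MagneticField: 7E0")
  w("TypeOfNucleus: 1E0")
  w("NameOfPatient: ")
  w("DateOfExperiment: ")
  w("Spectrometer: ")
  w("AdditionalInfo: %s", infoStr)
  w("")
  w("Signal and FFT")
  w("sig(real)\tsig(imag)\tfft(real)\tfft(imag)")
  for (k in seq_len(nsig)) {
    w("Signal %d out of %d in file", k, nsig)
    s <- signals[[k]]
    sp <- stats::fft(s)
    rows <- sprintf("%.8E\t%.8E\t%.8E\t%.8E", Re(s), Im(s), Re(sp), Im(sp))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a jMRUI text file
#'
#' @param path file written by [writeJmrui()] or a compatible tool.
#' @return list with `signals` (list of complex vectors), `axis`
#'   (reconstructed [SpectralAxis-class]), `signalNames` (or `NULL`) and
#'   `header` (named character of all key/value fields).
#' @export
readJmrui <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdrEnd <- grep("^Signal and FFT", lines)
  if (!length(hdrEnd)) stop("format error: missing 'Signal and FFT' marker")
  hdrLines <- grep("^[A-Za-z][A-Za-z0-9]*:", lines[seq_len(hdrEnd[1])],
                   value = TRUE)
  keys <- sub(":.*$", "", hdrLines)
  vals <- trimws(sub("^[^:]*:", "", hdrLines))
  header <- stats::setNames(vals, keys)
  for (k in .JMRUI_REQUIRED)
    if (!k %in% keys || header[[k]] == "")
      stop("format error: missing mandatory header key ", k)

  n <- as.integer(header[["PointsInDataset"]])
  nsig <- as.integer(header[["DatasetsInFile"]])
  dt <- as.numeric(header[["SamplingInterval"]]) * 1e-3
  tf <- as.numeric(header[["TransmitterFrequency"]]) * 1e-6
  if (!is.finite(dt) || dt <= 0)
    stop("format error: SamplingInterval must be positive")

  refPpm <- 4.7
  signalNames <- NULL
  if ("AdditionalInfo" %in% keys) {
    kv <- strsplit(strsplit(header[["AdditionalInfo"]], ";\\s*")[[1]], "=")
    kv <- kv[lengths(kv) == 2L]
    add <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    if ("ReferencePpm" %in% names(add))
      refPpm <- as.numeric(add[["ReferencePpm"]])
    if ("SignalNames" %in% names(add))
      signalNames <- strsplit(add[["SignalNames"]], ",")[[1]]
  }
  axis <- spectralAxis(n, dt, tf, refPpm)

  marks <- grep("^Signal [0-9]+ out of", lines)
  if (length(marks) != nsig)
    stop("format error: expected ", nsig, " signal sections, found ",
         length(marks))
  signals <- vector("list", nsig)
  for (k in seq_len(nsig)) {
    block <- lines[(marks[k] + 1L):(marks[k] + n)]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 4, byrow = TRUE)
    signals[[k]] <- complex(real = m[, 1], imaginary = m[, 2])
  }
  list(signals = signals, axis = axis, signalNames = signalNames,
       header = header)
}

#' Export a processed pair as jMRUI text
#'
#' Writes the edit-off, difference and water signals of a
#' [ProcessedPair-class] as three signals, tagged with their names and the
#' producing variant.
#'
#' @param pair a [ProcessedPair-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
exportProcessedPair <- function(pair, path) {
  stopifnot(is(pair, "ProcessedPair"))
  writeJmrui(list(pair@offFid, pair@diffFid, pair@waterFid),
             pair@offFid@axis, path,
             signalNames = c("off", "diff", "water"),
             extraInfo = c(Variant = variantLabel(pair@variant)))
}

#' Import a processed pair written by [exportProcessedPair()]
#'
#' @param path jMRUI file with signals named off, diff, water.
#' @return a [ProcessedPair-class].
#' @export
importProcessedPair <- function(path) {
  doc <- readJmrui(path)
  nm <- doc$signalNames
  if (is.null(nm) || !all(c("off", "diff", "water") %in% nm))
    stop("file does not contain off/diff/water signals")
  variant <- doc$header["AdditionalInfo"]
  vlab <- unname(regmatches(variant, regexpr("Variant=[^;]+", variant)))
  v <- if (length(vlab)) parseVariant(unname(sub("Variant=", "", vlab)))
       else pipelineVariant(FALSE, FALSE, "none")
  new("ProcessedPair",
    offFid = fid(doc$signals[[match("off", nm)]], doc$axis),
    diffFid = fid(doc$signals[[match("diff", nm)]], doc$axis),
    waterFid = fid(doc$signals[[match("water", nm)]], doc$axis),
    variant = v, alignment = data.frame())
}
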