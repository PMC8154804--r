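#' A single complex free induction decay
#'
#' A `Fid` couples one complex time-domain signal to its [SpectralAxis-class].
#' The discrete Fourier transform of the samples, reordered to ascending
#' chemical shift, is the spectrum ([fidSpectrum()]); the round trip through
#' [spectrumToFid()] is exact up to floating point.
#'
#' @slot samples complex vector, one value per axis point.
#' @slot axis the [SpectralAxis-class] the samples live on.
#' @exportClass Fid
setClass("Fid",
  representation(samples = "complex", axis = "SpectralAxis")
)

setValidity("Fid", function(object) {
  msg <- character()
  if (length(object@samples) != object@axis@nPoints)
    msg <- c(msg, "length(samples) must equal nPoints(axis)")
  if (any(!is.finite(Re(object@samples))) || any(!is.finite(Im(object@samples))))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an FID
#'
#' @param samples complex (or numeric) vector of time-domain samples.
#' @param axis a [SpectralAxis-class] matching `length(samples)`.
#' @return a [Fid-class].
#' @export
fid <- function(samples, axis) {
  new("Fid", samples = as.complex(samples), axis = axis)
}

#' @describeIn Fid-class the complex samples.
#' @param x,object a `Fid`.
#' @export
samples <- function(x) x@samples

#' @describeIn Fid-class the spectral axis.
#' @export
fidAxis <- function(x) x@axis

setMethod("show", "Fid", function(object) {
  cat("Fid:", length(object@samples), "complex samples, max |s| =",
    signif(max(Mod(object@samples)), 4), "\n")
  show(object@axis)
})

setMethod("length", "Fid", function(x) length(x@samples))

setMethod("Arith", signature("Fid", "Fid"), function(e1, e2) {
  stopifnot(length(e1@samples) == length(e2@samples))
  fid(callGeneric(e1@samples, e2@samples), e1@axis)
})

setMethod("Arith", signature("Fid", "numeric"), function(e1, e2) {
  fid(callGeneric(e1@samples, e2), e1@axis)
})

setMethod("Arith", signature("numeric", "Fid"), function(e1, e2) {
  fid(callGeneric(e1, e2@samples), e2@axis)
})

#' Spectrum of an FID
#'
#' DFT of the time-domain samples, returned in ascending chemical shift
#' order together with the ppm scale. No apodization or zero-filling is
#' applied.
#'
#' @param x a [Fid-class].
#' @return a list with elements `ppm` (ascending) and `y` (complex
#'   intensities at those shifts).
#' @export
fidSpectrum <- function(x) {
  stopifnot(is(x, "Fid"))
  sp <- stats::fft(x@samples)
  ppm <- offsetHzToPpm(.fftOffsetHz(x@axis), x@axis)
  ord <- order(ppm)
  list(ppm = ppm[ord], y = sp[ord])
}

#' @rdname fidSpectrum
#' @param y complex spectrum in the bin order produced by [fidSpectrum()].
#' @param axis the corresponding [SpectralAxis-class].
#' @export
spectrumToFid <- function(y, axis) {
  ppm <- offsetHzToPpm(.fftOffsetHz(axis), axis)
  ord <- order(ppm)
  raw <- complex(length.out = axis@nPoints)
  raw[ord] <- y
  fid(stats::fft(raw, inverse = TRUE) / axis@nPoints, axis)
}

#' Band-limit an FID to a chemical shift window
#'
#' Transforms to the frequency domain, zeroes every bin outside
#' `[spanPpm[1], spanPpm[2]]` and transforms back. Used to restrict the
#' difference-artifact alignment to the 2.8-3.5 ppm region.
#'
#' @param x a [Fid-class].
#' @param spanPpm length-2 numeric, chemical shift window (ppm).
#' @return a band-limited [Fid-class] on the same axis.
#' @export
bandLimitFid <- function(x, spanPpm) {
  stopifnot(is(x, "Fid"), length(spanPpm) == 2L)
  spanPpm <- sort(spanPpm)
  ppm <- offsetHzToPpm(.fftOffsetHz(x@axis), x@axis)
  if (spanPpm[1] > max(ppm) || spanPpm[2] < min(ppm))
    stop("spanPpm lies outside the spectral window")
  sp <- stats::fft(x@samples)
  sp[ppm < spanPpm[1] | ppm > spanPpm[2]] <- 0 + 0i
  fid(stats::fft(sp, inverse = TRUE) / x@axis@nPoints, x@axis)
}

#' Apply a phase / frequency modulation to an FID
#'
#' Multiplies the samples by `exp(i * phase + 2i * pi * freqHz * t)`, the
#' elementary correction used by spectral registration and the
#' difference-artifact alignments.
#'
#' @param x a [Fid-class].
#' @param phase zero-order phase in radians.
#' @param freqHz frequency shift in Hz.
#' @return the modulated [Fid-class].
#' @export
phaseShiftFid <- function(x, phase = 0, freqHz = 0) {
  t <- timeScale(x@axis)
  fid(x@samples * exp(1i * phase + 2i * pi * freqHz * t), x@axis)
}

#' Remove the residual-water band from an FID
#'
#' Zeroes every spectral bin inside `spanPpm` and transforms back: a simple
#' band-stop residual water removal. Subtraction artifacts of the large
#' residual water line carry arbitrary phase and cannot be represented by a
#' non-negative basis amplitude, so difference spectra are water-filtered
#' before quantification.
#'
#' @param x a [Fid-class].
#' @param spanPpm chemical shift window to remove (ppm).
#' @return the filtered [Fid-class].
#' @export
removeWaterBand <- function(x, spanPpm = c(4.2, 5.2)) {
  stopifnot(is(x, "Fid"))
  ppm <- offsetHzToPpm(.fftOffsetHz(x@axis), x@axis)
  sp <- stats::fft(x@samples)
  sp[ppm > min(spanPpm) & ppm < max(spanPpm)] <- 0 + 0i
  fid(stats::fft(sp, inverse = TRUE) / x@axis@nPoints, x@axis)
}
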