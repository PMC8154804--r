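#' @import methods
NULL

#' Spectral axis of an FID / spectrum pair
#'
#' A `SpectralAxis` fixes the time and frequency coordinates shared by all
#' signals of one acquisition: number of complex samples, dwell time,
#' transmitter (carrier) frequency and the chemical shift assigned to the
#' carrier. Sample `k` (0-based) of an FID sits at `t = k * dwellTime`; the
#' spectral width is `1 / dwellTime`. Chemical shift follows the standard MRS
#' display convention: the carrier (zero frequency offset) is at
#' `referencePpm` (water, 4.7 ppm by default) and ppm increases as the
#' frequency offset decreases.
#'
#' @slot nPoints integer, number of complex samples (at least 64).
#' @slot dwellTime sampling interval in seconds.
#' @slot transmitterFrequency carrier frequency in MHz.
#' @slot referencePpm chemical shift (ppm) assigned to the carrier.
#'
#' @examples
#' ax <- spectralAxis(2048, 1 / 4000)
#' spectralWidth(ax)
#' range(ppmScale(ax))
#' @name SpectralAxis-class
#' @aliases SpectralAxis
#' @exportClass SpectralAxis
setClass("SpectralAxis",
  representation(
    nPoints = "integer",
    dwellTime = "numeric",
    transmitterFrequency = "numeric",
    referencePpm = "numeric"
  )
)

setValidity("SpectralAxis", function(object) {
  msg <- character()
  if (length(object@nPoints) != 1L || is.na(object@nPoints) ||
      object@nPoints < 64L)
    msg <- c(msg, "nPoints must be a single integer >= 64")
  if (length(object@dwellTime) != 1L || !is.finite(object@dwellTime) ||
      object@dwellTime <= 0)
    msg <- c(msg, "dwellTime must be a single positive number (seconds)")
  if (length(object@transmitterFrequency) != 1L ||
      !is.finite(object@transmitterFrequency) ||
      object@transmitterFrequency <= 0)
    msg <- c(msg, "transmitterFrequency must be positive (MHz)")
  if (length(object@referencePpm) != 1L || !is.finite(object@referencePpm))
    msg <- c(msg, "referencePpm must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a spectral axis
#'
#' @param nPoints number of complex samples (>= 64). Default 4096.
#' @param dwellTime sampling interval in seconds; the spectral width is its
#'   reciprocal. Default `1/4000` (4 kHz spectral width).
#' @param transmitterFrequency carrier frequency in MHz. Default 297.2, the
#'   proton frequency at 7 T.
#' @param referencePpm chemical shift assigned to the carrier; water at
#'   4.7 ppm by default.
#' @return a [SpectralAxis-class] object.
#' @export
spectralAxis <- function(nPoints = 4096L, dwellTime = 1 / 4000,
                         transmitterFrequency = 297.2, referencePpm = 4.7) {
  new("SpectralAxis",
    nPoints = as.integer(nPoints), dwellTime = as.numeric(dwellTime),
    transmitterFrequency = as.numeric(transmitterFrequency),
    referencePpm = as.numeric(referencePpm)
  )
}

#' @describeIn SpectralAxis-class number of complex samples.
#' @param object,x a `SpectralAxis`.
#' @export
nPoints <- function(x) x@nPoints

#' @describeIn SpectralAxis-class sampling interval (s).
#' @export
dwellTime <- function(x) x@dwellTime

#' @describeIn SpectralAxis-class carrier frequency (MHz).
#' @export
transmitterFrequency <- function(x) x@transmitterFrequency

#' @describeIn SpectralAxis-class chemical shift of the carrier (ppm).
#' @export
referencePpm <- function(x) x@referencePpm

#' @describeIn SpectralAxis-class spectral width `1/dwellTime` (Hz).
#' @export
spectralWidth <- function(x) 1 / x@dwellTime

#' @describeIn SpectralAxis-class time of each FID sample (s), starting at 0.
#' @export
timeScale <- function(x) (seq_len(x@nPoints) - 1) * x@dwellTime

# Frequency offset (Hz) of each DFT bin in fft() output order:
# bin k (0-based) has frequency k/(n*dt) for k < n/2 and k/(n*dt) - sw above.
.fftOffsetHz <- function(axis) {
  n <- axis@nPoints
  k <- seq_len(n) - 1
  f <- k / (n * axis@dwellTime)
  f[k >= n / 2] <- f[k >= n / 2] - spectralWidth(axis)
  f
}

#' @describeIn SpectralAxis-class chemical shift (ppm) of each DFT bin,
#'   ascending.
#' @export
ppmScale <- function(x) sort(offsetHzToPpm(.fftOffsetHz(x), x))

setMethod("show", "SpectralAxis", function(object) {
  cat("SpectralAxis:", object@nPoints, "points, dwell",
    signif(object@dwellTime * 1e3, 4), "ms (sw",
    signif(spectralWidth(object), 5), "Hz),",
    object@transmitterFrequency, "MHz, carrier at",
    object@referencePpm, "ppm\n")
})

#' Convert a width or offset between Hz and ppm
#'
#' A width of `w` Hz corresponds to `w / f0` ppm where `f0` is the
#' transmitter frequency in MHz; `ppmToHz` is the exact inverse. These
#' convert *widths* (or frequency differences) and carry no carrier offset.
#'
#' @param widthHz width or frequency difference in Hz.
#' @param axis a [SpectralAxis-class].
#' @return width in ppm (`hzToPpm`) or Hz (`ppmToHz`).
#' @examples
#' ax <- spectralAxis()
#' hzToPpm(23.1, ax)   # ~0.078 ppm at 297.2 MHz
#' @export
hzToPpm <- function(widthHz, axis) {
  stopifnot(is(axis, "SpectralAxis"))
  if (axis@transmitterFrequency <= 0)
    stop("invalid axis: non-positive transmitter frequency")
  if (any(widthHz < 0)) stop("widthHz must be >= 0")
  widthHz / axis@transmitterFrequency
}

#' @rdname hzToPpm
#' @param widthPpm width in ppm.
#' @export
ppmToHz <- function(widthPpm, axis) {
  stopifnot(is(axis, "SpectralAxis"))
  if (axis@transmitterFrequency <= 0)
    stop("invalid axis: non-positive transmitter frequency")
  widthPpm * axis@transmitterFrequency
}

#' Map chemical shift positions to carrier frequency offsets
#'
#' Under the display convention used throughout (carrier at `referencePpm`,
#' ppm decreasing with increasing frequency offset), a resonance at `ppm`
#' sits at offset `(referencePpm - ppm) * f0` Hz from the carrier.
#'
#' @param ppm chemical shift position(s).
#' @param axis a [SpectralAxis-class].
#' @return frequency offset(s) in Hz.
#' @export
ppmToOffsetHz <- function(ppm, axis) {
  (axis@referencePpm - ppm) * axis@transmitterFrequency
}

#' @rdname ppmToOffsetHz
#' @param offsetHz frequency offset(s) in Hz.
#' @export
offsetHzToPpm <- function(offsetHz, axis) {
  axis@referencePpm - offsetHz / axis@transmitterFrequency
}
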