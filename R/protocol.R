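#' Acquisition protocol of an edited MRS measurement
#'
#' Bundles the sequence-level numbers that enter simple acquisition
#' arithmetic: repetition and echo time, the transient counts making up one
#' measurement (water reference, dummy excitations, edit-on, edit-off),
#' pulse bandwidths, editing frequencies and voxel dimensions.
#'
#' @slot tr repetition time (s).
#' @slot te echo time (s).
#' @slot nWaterRef,nDummy,nOn,nOff transient counts (>= 0).
#' @slot excitationBandwidth,refocusingBandwidth pulse bandwidths (kHz).
#' @slot editingOnPpm,editingOffPpm editing pulse positions (ppm).
#' @slot voxelDimensions length-3 numeric, voxel edge lengths (cm).
#' @exportClass SequenceProtocol
setClass("SequenceProtocol",
  representation(
    tr = "numeric", te = "numeric",
    nWaterRef = "integer", nDummy = "integer",
    nOn = "integer", nOff = "integer",
    excitationBandwidth = "numeric", refocusingBandwidth = "numeric",
    editingOnPpm = "numeric", editingOffPpm = "numeric",
    voxelDimensions = "numeric"
  )
)

setValidity("SequenceProtocol", function(object) {
  msg <- character()
  counts <- c(object@nWaterRef, object@nDummy, object@nOn, object@nOff)
  if (any(counts < 0L)) msg <- c(msg, "all transient counts must be >= 0")
  if (object@tr < 0) msg <- c(msg, "tr must be >= 0")
  if (object@excitationBandwidth <= 0 || object@refocusingBandwidth <= 0)
    msg <- c(msg, "pulse bandwidths must be > 0")
  if (length(object@voxelDimensions) != 3L || any(object@voxelDimensions <= 0))
    msg <- c(msg, "voxelDimensions must be 3 positive lengths (cm)")
  if (length(msg)) msg else TRUE
})

#' Construct a sequence protocol
#'
#' Defaults describe a 7 T MEGA-sLASER protocol: TR 7 s, TE 74 ms, one
#' water reference, 4 dummies, 32 edit-on and 32 edit-off transients,
#' 3.3 kHz excitation and 16.8 kHz refocusing bandwidth, editing pulses at
#' 1.9 (on) and 7.5 ppm (off), a 2 x 2 x 5 cm hippocampal voxel.
#'
#' @param tr,te repetition / echo time (s).
#' @param nWaterRef,nDummy,nOn,nOff transient counts.
#' @param excitationBandwidth,refocusingBandwidth bandwidths in kHz.
#' @param editingOnPpm,editingOffPpm editing frequencies (ppm).
#' @param voxelDimensions voxel edges in cm.
#' @return a [SequenceProtocol-class].
#' @export
sequenceProtocol <- function(tr = 7, te = 0.074,
                             nWaterRef = 1L, nDummy = 4L, nOn = 32L, nOff = 32L,
                             excitationBandwidth = 3.3,
                             refocusingBandwidth = 16.8,
                             editingOnPpm = 1.9, editingOffPpm = 7.5,
                             voxelDimensions = c(2, 2, 5)) {
  new("SequenceProtocol",
    tr = tr, te = te,
    nWaterRef = as.integer(nWaterRef), nDummy = as.integer(nDummy),
    nOn = as.integer(nOn), nOff = as.integer(nOff),
    excitationBandwidth = excitationBandwidth,
    refocusingBandwidth = refocusingBandwidth,
    editingOnPpm = editingOnPpm, editingOffPpm = editingOffPpm,
    voxelDimensions = as.numeric(voxelDimensions)
  )
}

setMethod("show", "SequenceProtocol", function(object) {
  cat(sprintf(
    "SequenceProtocol: TR %.3g s, TE %.3g s, %d water / %d dummy / %d on / %d off\n",
    object@tr, object@te, object@nWaterRef, object@nDummy,
    object@nOn, object@nOff))
  cat(sprintf("  editing %.3g / %.3g ppm; voxel %s cm (%.4g ml)\n",
    object@editingOnPpm, object@editingOffPpm,
    paste(object@voxelDimensions, collapse = " x "),
    voxelVolume(object)))
})

#' Total acquisition time of one measurement
#'
#' `tr * (nWaterRef + nDummy + nOn + nOff)`; with the default protocol this
#' is 7 * 69 = 483 s, i.e. 8:03 min.
#'
#' @param protocol a [SequenceProtocol-class].
#' @return duration in seconds.
#' @export
acquisitionDuration <- function(protocol) {
  stopifnot(is(protocol, "SequenceProtocol"))
  protocol@tr * (protocol@nWaterRef + protocol@nDummy +
                   protocol@nOn + protocol@nOff)
}

#' Voxel volume in millilitres
#'
#' @param protocol a [SequenceProtocol-class].
#' @return product of the voxel edges (cm) in ml.
#' @export
voxelVolume <- function(protocol) prod(protocol@voxelDimensions)

#' Chemical shift displacement error
#'
#' Fractional displacement of the selected voxel between two resonances
#' separated by `spanPpm`, for a selective pulse of the given bandwidth:
#' `spanPpm * f0(MHz) / (bandwidthKhz * 1000)`. For a 1.1 ppm span at
#' 297.2 MHz this gives ~2% at 16.8 kHz (refocusing) and ~10% at 3.3 kHz
#' (excitation).
#'
#' @param bandwidthKhz pulse bandwidth in kHz (> 0).
#' @param spanPpm chemical shift separation in ppm (>= 0).
#' @param axis a [SpectralAxis-class] supplying the transmitter frequency.
#' @return displacement as a fraction of the voxel size.
#' @export
chemicalShiftDisplacement <- function(bandwidthKhz, spanPpm, axis) {
  stopifnot(is(axis, "SpectralAxis"))
  if (any(bandwidthKhz <= 0))
    stop("invalid protocol: pulse bandwidth must be > 0")
  if (any(spanPpm < 0)) stop("spanPpm must be >= 0")
  (spanPpm * axis@transmitterFrequency) / (bandwidthKhz * 1000)
}

#' Symmetry center of the editing frequencies
#'
#' Arithmetic mean of the edit-on and edit-off pulse positions; a protocol
#' with pulses placed symmetrically about water returns the water position
#' (e.g. 1.9 and 7.5 ppm give 4.7 ppm).
#'
#' @param onPpm,offPpm editing pulse positions (ppm).
#' @return center position (ppm).
#' @export
editingSymmetryCenter <- function(onPpm, offPpm) {
  stopifnot(is.finite(onPpm), is.finite(offPpm))
  (onPpm + offPpm) / 2
}
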