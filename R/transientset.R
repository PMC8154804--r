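#' Multi-coil, multi-transient raw unit of one measurement
#'
#' A `TransientSet` holds every FID of one spectroscopy measurement as a
#' complex array of dimension (points, coils, transients), an edit state per
#' transient (`"on"`, `"off"` or `"water_reference"`), and the shared
#' [SpectralAxis-class]. Dummy excitations are discarded upstream and never
#' appear here. A valid set has at least one water reference and equal
#' numbers of edit-on and edit-off transients.
#'
#' @slot data complex array `(nPoints, nCoils, nTransients)`.
#' @slot editState character vector, one state per transient.
#' @slot subjectId character scalar.
#' @slot measurementIndex integer, which repeated measurement (1-based).
#' @slot axis the shared [SpectralAxis-class].
#' @exportClass TransientSet
setClass("TransientSet",
  representation(
    data = "array",
    editState = "character",
    subjectId = "character",
    measurementIndex = "integer",
    axis = "SpectralAxis"
  )
)

.VALID_STATES <- c("on", "off", "water_reference")

setValidity("TransientSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a (points, coils, transients) array")
  if (d[1] != object@axis@nPoints)
    msg <- c(msg, "first data dimension must equal nPoints(axis)")
  if (d[3] != length(object@editState))
    msg <- c(msg, "editState must have one entry per transient")
  if (!all(object@editState %in% .VALID_STATES))
    msg <- c(msg, "editState entries must be 'on', 'off' or 'water_reference'")
  if (sum(object@editState == "water_reference") < 1L)
    msg <- c(msg, "at least one water_reference transient is required")
  if (sum(object@editState == "on") != sum(object@editState == "off"))
    msg <- c(msg, "equal numbers of edit-on and edit-off transients required")
  if (!is.complex(object@data))
    msg <- c(msg, "data must be complex")
  if (length(msg)) msg else TRUE
})

#' Construct a transient set
#'
#' @param data complex array `(points, coils, transients)`.
#' @param editState character vector of per-transient states (`"on"`,
#'   `"off"`, `"water_reference"`).
#' @param axis shared [SpectralAxis-class].
#' @param subjectId subject label.
#' @param measurementIndex repeated-measurement index (1-based).
#' @return a [TransientSet-class].
#' @export
transientSet <- function(data, editState, axis, subjectId = "S1",
                         measurementIndex = 1L) {
  new("TransientSet",
    data = data, editState = as.character(editState), axis = axis,
    subjectId = as.character(subjectId),
    measurementIndex = as.integer(measurementIndex)
  )
}

#' @describeIn TransientSet-class number of receive coils.
#' @param x,object a `TransientSet`.
#' @export
nCoils <- function(x) dim(x@data)[2]

#' @describeIn TransientSet-class number of transients (incl. water).
#' @export
nTransients <- function(x) dim(x@data)[3]

#' @describeIn TransientSet-class per-transient edit states.
#' @export
editStates <- function(x) x@editState

#' @describeIn TransientSet-class the shared spectral axis.
#' @export
setAxis <- function(x) x@axis

#' Extract one transient as a [Fid-class]
#'
#' @param x a [TransientSet-class].
#' @param transient transient index.
#' @param coil coil index (default 1; sets produced by [combineCoils()]
#'   have a single coil).
#' @return a [Fid-class].
#' @export
transientFid <- function(x, transient, coil = 1L) {
  fid(x@data[, coil, transient], x@axis)
}

#' Water reference FID of a single-coil set
#'
#' @param x a coil-combined (single-coil) [TransientSet-class].
#' @return the first water-reference transient as a [Fid-class].
#' @export
waterFid <- function(x) {
  stopifnot(nCoils(x) == 1L)
  w <- which(x@editState == "water_reference")[1]
  transientFid(x, w)
}

#' Average the transients in one edit state
#'
#' @param x a single-coil [TransientSet-class].
#' @param state `"on"` or `"off"`.
#' @return the mean [Fid-class] over transients in that state.
#' @export
stateMean <- function(x, state = c("off", "on")) {
  state <- match.arg(state)
  stopifnot(nCoils(x) == 1L)
  idx <- which(x@editState == state)
  if (!length(idx)) stop("no transients in state ", state)
  m <- x@data[, 1L, idx, drop = FALSE]
  fid(rowMeans(matrix(m, nrow = dim(x@data)[1])), x@axis)
}

setMethod("show", "TransientSet", function(object) {
  tab <- table(factor(object@editState, levels = .VALID_STATES))
  cat(sprintf(
    "TransientSet: subject %s, measurement %d; %d coil(s); %s on / %s off / %s water\n",
    object@subjectId, object@measurementIndex, nCoils(object),
    tab[["on"]], tab[["off"]], tab[["water_reference"]]))
  show(object@axis)
})
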