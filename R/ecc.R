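#' Eddy-current compensation by water-reference phase deconvolution
#'
#' Removes the time-dependent phase measured on the coil-combined
#' water-unsuppressed FID from a metabolite FID:
#' `corrected(t) = fid(t) * exp(-i * phi_w(t))`, with `phi_w` the unwrapped
#' phase of the water signal. Because residual eddy currents impose the same
#' multiplicative phase on the water reference and the water-suppressed
#' transients of a measurement, the correction cancels that phase exactly in
#' the noise-free case.
#'
#' Once the water magnitude decays below `thresholdFactor` times the noise
#' s.d. (estimated from the final 10% of the water FID) the phase estimate
#' is no longer reliable; from the first such sample on, `phi_w` is held
#' constant at its last reliable value.
#'
#' @param x the [Fid-class] to correct.
#' @param water the coil-combined water reference [Fid-class] on the same
#'   axis.
#' @param thresholdFactor magnitude threshold in noise s.d. units.
#' @return the corrected [Fid-class].
#' @export
eddyCurrentCorrect <- function(x, water, thresholdFactor = 5) {
  stopifnot(is(x, "Fid"), is(water, "Fid"))
  if (length(x) != length(water))
    stop("fid and water reference must share one axis")
  w <- water@samples
  if (all(Mod(w) == 0)) stop("water reference is all zero")
  phi <- signal::unwrap(Arg(w))
  n <- length(w)
  tail <- seq.int(max(1L, n - floor(0.1 * n) + 1L), n)
  noiseSd <- stats::sd(c(Re(w[tail]), Im(w[tail])))
  if (is.finite(noiseSd) && noiseSd > 0) {
    bad <- which(Mod(w) < thresholdFactor * noiseSd)
    if (length(bad)) {
      first <- min(bad)
      if (first == 1L)
        stop("water magnitude below the noise floor from the first sample")
      phi[first:n] <- phi[first - 1L]
    }
  }
  fid(x@samples * exp(-1i * phi), x@axis)
}
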