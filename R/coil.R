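#' Noise-correlation weighted coil combination weights
#'
#' Holds the complex per-coil water amplitudes `s`, the coil noise
#' correlation matrix `N` and the combination weights `w = N^-1 s`. With
#' this choice the combined water FID has zero phase at `t = 0` (the
#' combined amplitude `w^H s = s^H N^-1 s` is real positive) and the
#' whitened-matched-filter SNR optimum is attained.
#'
#' @slot weights complex per-coil weights.
#' @slot waterAmplitudes complex per-coil water signal amplitudes.
#' @slot noiseCorrelation estimated Hermitian coil noise covariance.
#' @exportClass CoilWeights
setClass("CoilWeights",
  representation(
    weights = "complex",
    waterAmplitudes = "complex",
    noiseCorrelation = "matrix"
  )
)

setMethod("show", "CoilWeights", function(object) {
  cat("CoilWeights for", length(object@weights), "coils; |w| =",
    paste(signif(Mod(object@weights), 3), collapse = " "), "\n")
})

#' Estimate coil combination weights from a measurement
#'
#' The per-coil water amplitude `s_i` is the mean of the first
#' `nSignalSamples` samples of the water reference; the noise covariance
#' `N_ij` is the sample covariance across coils of the tail samples (final
#' `noiseTailFraction` of each FID) of all water-suppressed transients.
#' Weights are `w = N^-1 s`; if `N` is numerically singular its off-diagonal
#' part is dropped with a warning.
#'
#' @param set a multi-coil [TransientSet-class].
#' @param noiseTailFraction fraction of each FID treated as pure noise.
#' @param nSignalSamples number of leading water samples averaged for `s`.
#' @return a [CoilWeights-class].
#' @export
estimateCoilWeights <- function(set, noiseTailFraction = 0.25,
                                nSignalSamples = 4L) {
  stopifnot(is(set, "TransientSet"))
  n <- nPoints(set@axis)
  nc <- nCoils(set)
  wi <- which(set@editState == "water_reference")[1]
  s <- set@data[seq_len(nSignalSamples), , wi, drop = FALSE]
  s <- colMeans(matrix(as.complex(s), ncol = nc))

  tailIdx <- seq.int(from = n - ceiling(noiseTailFraction * n) + 1L, to = n)
  if (length(tailIdx) < 64L)
    stop("need at least 64 noise tail samples per coil")
  sup <- which(set@editState != "water_reference")
  X <- matrix(aperm(set@data[tailIdx, , sup, drop = FALSE], c(1, 3, 2)),
              ncol = nc)
  Xc <- sweep(X, 2, colMeans(X))
  N <- crossprod(Conj(Xc), Xc) / (nrow(Xc) - 1)  # N_ij = E[conj(x_i) x_j]
  N <- Conj(N)                                    # convention E[x_i conj(x_j)]

  w <- tryCatch(solve(N, s), error = function(e) {
    warning("singular noise covariance; falling back to its diagonal")
    s / Re(diag(N))
  })
  new("CoilWeights", weights = as.complex(w), waterAmplitudes = as.complex(s),
      noiseCorrelation = N)
}

#' Combine the coils of a transient set
#'
#' Replaces each transient (and the water reference) by the
#' conjugate-weighted sum `sum_i Conj(w_i) A_i(t)`.
#'
#' @param set a multi-coil [TransientSet-class].
#' @param weights a [CoilWeights-class] matching the coil count.
#' @return a single-coil [TransientSet-class].
#' @export
combineCoils <- function(set, weights) {
  stopifnot(is(set, "TransientSet"), is(weights, "CoilWeights"))
  if (length(weights@weights) != nCoils(set))
    stop("weight count does not match coil count")
  n <- nPoints(set@axis)
  nt <- nTransients(set)
  w <- Conj(weights@weights)
  flat <- matrix(aperm(set@data, c(1, 3, 2)), nrow = n * nt)
  comb <- flat %*% w
  out <- array(as.complex(comb), dim = c(n, 1L, nt))
  transientSet(out, set@editState, set@axis, set@subjectId,
               set@measurementIndex)
}
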