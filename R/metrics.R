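## Data quality metrics derived from a fit: NAA linewidth, NAA SNR and the
## GABA+/tCr ratio.

# FWHM of the real part of a spectrum given ascending frequency (Hz) and
# intensity; linear interpolation at the half-maximum crossings.
.measureFwhmHz <- function(hz, y) {
  i0 <- which.max(y)
  ymax <- y[i0]
  if (ymax <= 0) stop("peak has non-positive maximum")
  half <- ymax / 2
  below <- which(y[seq_len(i0)] < half)
  if (!length(below)) stop("left half-maximum crossing not found")
  iL <- max(below)
  xL <- hz[iL] + (half - y[iL]) / (y[iL + 1] - y[iL]) * (hz[iL + 1] - hz[iL])
  above <- which(y[i0:length(y)] < half)
  if (!length(above)) stop("right half-maximum crossing not found")
  iR <- i0 + min(above) - 1L
  xR <- hz[iR - 1] + (half - y[iR - 1]) / (y[iR] - y[iR - 1]) *
    (hz[iR] - hz[iR - 1])
  xR - xL
}

# Render a damped component FID as a real spectrum on a zero-filled axis
# and return (hz ascending, real intensity).
.componentSpectrum <- function(samples, axis, zeroFill = 4L) {
  n <- length(samples) * zeroFill
  sp <- stats::fft(c(samples, complex(length.out = n - length(samples))))
  k <- seq_len(n) - 1
  f <- k / (n * axis@dwellTime)
  f[k >= n / 2] <- f[k >= n / 2] - spectralWidth(axis)
  ord <- order(f)
  list(hz = f[ord], y = Re(sp[ord]))
}

#' Linewidth of the fitted NAA resonance
#'
#' Renders the fitted NAA component (its basis signal with the fitted
#' Lorentzian and global Gaussian damping, no global phase) and measures
#' the full width at half maximum of its real spectrum, with linear
#' interpolation between bins on a four-fold zero-filled grid. This is
#' baseline-free by construction.
#'
#' @param fit a [FitResult-class] whose basis contains the entry.
#' @param entry basis entry name (default `"NAA"`).
#' @return `list(hz = , ppm = )`.
#' @export
fwhmNaa <- function(fit, entry = "NAA") {
  stopifnot(is(fit, "FitResult"))
  m <- match(entry, fit@basis@entryNames)
  if (is.na(m)) stop("entry '", entry, "' not in basis")
  a <- fit@amplitudes[m]
  if (a <= 0) stop("entry '", entry, "' has zero fitted amplitude")
  axis <- fit@basis@axis
  t <- timeScale(axis)
  comp <- a * fit@basis@fids[, m] *
    exp(-fit@lorentzian[m] * t - fit@gaussian * t^2)
  sp <- .componentSpectrum(comp, axis)
  hz <- .measureFwhmHz(sp$hz, sp$y)
  list(hz = hz, ppm = hzToPpm(hz, axis))
}

#' SNR of the NAA resonance
#'
#' Peak signal of the fitted (baseline-free) model spectrum in the NAA
#' region divided by two times the root mean square of the real part of the
#' data spectrum over a resonance-free noise span. Both spectra are rotated
#' by the fitted zero-order phase so the model peak is in absorption.
#'
#' @param fit a [FitResult-class].
#' @param x the fitted data [Fid-class].
#' @param noiseSpanPpm chemical shift window free of resonances (default
#'   8.5-10.5 ppm).
#' @param peakSpanPpm window containing the NAA peak.
#' @return the SNR as a plain number.
#' @export
snrNaa <- function(fit, x, noiseSpanPpm = c(8.5, 10.5),
                   peakSpanPpm = c(1.8, 2.2)) {
  stopifnot(is(fit, "FitResult"), is(x, "Fid"))
  cen <- fit@basis@centers
  if (any(cen >= min(noiseSpanPpm) & cen <= max(noiseSpanPpm)))
    stop("noise span overlaps a basis resonance")
  dephase <- exp(-1i * fit@phase)
  # halve the first time-domain sample before the DFT: the standard
  # correction for the baseline a causal FID otherwise spreads across the
  # whole spectrum, which would dominate the noise-span RMS
  firstHalf <- function(s) { s[1] <- 0.5 * s[1]; s }
  mspec <- fidSpectrum(fid(firstHalf(fit@model@samples * dephase), x@axis))
  dspec <- fidSpectrum(fid(firstHalf(x@samples * dephase), x@axis))
  inPeak <- mspec$ppm >= min(peakSpanPpm) & mspec$ppm <= max(peakSpanPpm)
  inNoise <- dspec$ppm >= min(noiseSpanPpm) & dspec$ppm <= max(noiseSpanPpm)
  if (!any(inNoise)) stop("noise span lies outside the spectral window")
  peak <- max(Re(mspec$y[inPeak]))
  noise <- sqrt(mean(Re(dspec$y[inNoise])^2))
  peak / (2 * noise)
}

#' GABA+/total creatine ratio from a difference and an edit-off fit
#'
#' Sums the edited signal areas (GABA pseudo-doublet group plus the
#' macromolecule entry, each fitted amplitude times its entry's
#' coefficient norm) of the difference fit and divides by the 3.03 ppm
#' creatine area of the edit-off fit. No editing-efficiency or relaxation
#' calibration is applied; such constant factors cancel in
#' coefficient-of-variation statistics.
#'
#' @param diffFit difference-spectrum [FitResult-class].
#' @param offFit edit-off [FitResult-class].
#' @param gabaEntries difference-basis entries summed in the numerator.
#' @param tcrEntries edit-off entries summed in the denominator.
#' @return the ratio as a plain number.
#' @export
gabaTcrRatio <- function(diffFit, offFit,
                         gabaEntries = c("GABA", "MM30"),
                         tcrEntries = "tCr30") {
  stopifnot(is(diffFit, "FitResult"), is(offFit, "FitResult"))
  area <- function(fit, entries) {
    sel <- intersect(entries, fit@basis@entryNames)
    i <- match(sel, fit@basis@entryNames)
    sum(fit@amplitudes[i] * fit@basis@coeffL1[i])
  }
  num <- area(diffFit, gabaEntries)
  den <- area(offFit, tcrEntries)
  if (!is.finite(den) || den <= 0) stop("zero total creatine amplitude")
  num / den
}
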