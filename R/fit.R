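#' Quantification parameters of the linear-combination fit
#'
#' @param ns 1-based index of the first FID sample entering the fit
#'   (`ns = 1` uses the whole FID). Must satisfy `1 <= ns <= nPoints/4`.
#' @param beta initial value of the global Gaussian damping (1/s^2);
#'   must be > 0.
#' @param freqBound bound on the fitted global frequency shift (Hz).
#' @param maxIter maximum Levenberg-Marquardt iterations.
#' @param alphaInit initial per-entry excess Lorentzian damping (1/s).
#' @param alphaMax upper bound on the excess Lorentzian damping (1/s);
#'   excess broadening beyond ~50 Hz is not physical when the global
#'   Gaussian term models the shim-induced width.
#' @param maxTime last FID time entering the fit (s); `Inf` uses the full
#'   FID.
#' @return a classed parameter list.
#' @export
fitConfig <- function(ns = 1L, beta = 500, freqBound = 20, maxIter = 200L,
                      alphaInit = 2, alphaMax = 150, maxTime = Inf) {
  stopifnot(ns >= 1L, beta > 0, freqBound > 0, maxIter >= 1L,
            alphaInit >= 0, alphaMax > alphaInit)
  structure(list(ns = as.integer(ns), beta = beta, freqBound = freqBound,
                 maxIter = as.integer(maxIter), alphaInit = alphaInit,
                 alphaMax = alphaMax, maxTime = maxTime),
            class = "FitConfig")
}

#' Result of a linear-combination fit
#'
#' @slot amplitudes named non-negative basis amplitudes.
#' @slot phase fitted global zero-order phase (rad).
#' @slot frequency fitted global frequency shift (Hz).
#' @slot lorentzian named per-entry Lorentzian dampings (1/s).
#' @slot gaussian fitted global Gaussian damping (1/s^2).
#' @slot crlbPercent named Cramer-Rao lower bounds (% of each amplitude).
#' @slot residualSd noise s.d. estimated from the fitted-residual tail.
#' @slot model the fitted model rendered over the full axis ([Fid-class]).
#' @slot converged logical.
#' @slot nFitted number of complex samples entering the fit.
#' @slot basis the [BasisSet-class] used.
#' @slot config the [fitConfig()] used (as a list).
#' @exportClass FitResult
setClass("FitResult",
  representation(
    amplitudes = "numeric", phase = "numeric", frequency = "numeric",
    lorentzian = "numeric", gaussian = "numeric", crlbPercent = "numeric",
    residualSd = "numeric", model = "Fid", converged = "logical",
    nFitted = "integer", basis = "BasisSet", config = "list"
  )
)

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@basis@target, " basis, ",
      if (object@converged) "converged" else "NOT converged", ")\n", sep = "")
  tab <- data.frame(amplitude = signif(object@amplitudes, 4),
                    crlbPercent = signif(object@crlbPercent, 3),
                    lorentzian = signif(object@lorentzian, 3))
  print(tab)
  cat(sprintf("phase %.4f rad, freq %.3f Hz, gaussian %.1f /s^2, n = %d\n",
              object@phase, object@frequency, object@gaussian,
              object@nFitted))
})

#' @describeIn FitResult-class named basis amplitudes.
#' @param x,object a `FitResult`.
#' @export
amplitudes <- function(x) x@amplitudes

#' @describeIn FitResult-class named CRLB percentages.
#' @export
crlbPercent <- function(x) x@crlbPercent

# Lawson-Hanson non-negative least squares on the normal equations
# (G = A^T A, h = A^T b). The fitter's design has at most a handful of
# columns, so the active-set iterations cost M x M solves only; agreement
# with a full-design NNLS is covered by the test suite.
.nnlsNormal <- function(G, h) {
  M <- length(h)
  tol <- 1e-12 * max(diag(G))
  P <- logical(M)
  x <- numeric(M)
  for (outer in seq_len(30L * M)) {
    w <- h - as.vector(G %*% x)
    w[P] <- -Inf
    j <- which.max(w)
    if (!is.finite(w[j]) || w[j] <= tol) break
    P[j] <- TRUE
    repeat {
      s <- numeric(M)
      sP <- tryCatch(solve(G[P, P, drop = FALSE], h[P]),
                     error = function(e) rep(0, sum(P)))
      s[P] <- sP
      if (all(s[P] > 0)) { x <- s; break }
      q <- which(P & s <= 0)
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      P <- P & x > tol
      x[!P] <- 0
    }
  }
  x
}

# Model pieces at parameter vector p = (phi, df, beta, alpha_1..M) for basis
# matrix B over times t: returns the shaped columns C and amplitudes a from
# non-negative least squares against data d (variable projection).
.fitPieces <- function(p, B, t, d, tbar = 0) {
  M <- ncol(B)
  E <- exp(1i * p[1] + 2i * pi * p[2] * (t - tbar) - p[3] * t^2)
  C <- B * E
  for (m in seq_len(M)) C[, m] <- C[, m] * exp(-p[3 + m] * t)
  G <- Re(crossprod(Conj(C), C))
  h <- Re(as.vector(crossprod(Conj(C), d)))
  a <- .nnlsNormal(G, h)
  list(C = C, a = a, model = as.vector(C %*% a))
}

#' Fit a spectrum by a non-negative linear combination of Voigt resonances
#'
#' Fits `M(t) = exp(i*phi + 2i*pi*df*t - beta*t^2) * sum_m a_m
#' exp(-alpha_m t) B_m(t)` to the FID samples from index `ns` on.
#' Amplitudes are obtained by non-negative linear least squares nested
#' inside a Levenberg-Marquardt optimization of the nonlinear parameters
#' (global phase, frequency shift and Gaussian damping, per-entry
#' Lorentzian dampings); real and imaginary parts are stacked. The Gaussian
#' damping starts at `config$beta`, the Lorentzian dampings at
#' `config$alphaInit`.
#'
#' @param x the [Fid-class] to quantify.
#' @param basis a [BasisSet-class] on the same axis.
#' @param config a [fitConfig()].
#' @return a [FitResult-class]; Cramer-Rao bounds are filled in via
#'   [crlb()].
#' @export
fitSpectrum <- function(x, basis, config = fitConfig()) {
  stopifnot(is(x, "Fid"), is(basis, "BasisSet"))
  if (!identical(x@axis, basis@axis))
    stop("fid and basis must share one axis")
  n <- length(x)
  if (config$ns > n %/% 4L)
    stop("ns exceeds nPoints/4")
  if (all(Mod(x@samples) == 0)) stop("cannot fit an all-zero fid")

  tFull <- timeScale(x@axis)
  idx <- which(seq_len(n) >= config$ns & tFull <= config$maxTime)
  t <- tFull[idx]
  d <- x@samples[idx]
  B <- basis@fids[idx, , drop = FALSE]
  M <- ncol(B)
  # frequency ramp referenced to the data's energy centroid, which keeps the
  # global phase and frequency shift from being nearly collinear for
  # fast-decaying signals
  w2 <- Mod(d)^2
  tbar <- if (sum(w2) > 0) sum(w2 * t) / sum(w2) else mean(t)

  lastP <- NULL; lastPc <- NULL
  pieces <- function(p) {
    # nls.lm updates the parameter vector in place, so cache a value copy
    pCopy <- c(as.numeric(p))
    if (!identical(pCopy, lastP)) {
      lastPc <<- .fitPieces(pCopy, B, t, d, tbar)
      lastP <<- pCopy
    }
    lastPc
  }
  resFn <- function(p) {
    pc <- pieces(p)
    c(Re(pc$model - d), Im(pc$model - d))
  }
  # Kaufman-style approximate Jacobian: amplitudes held at their current
  # projected values.
  jacFn <- function(p) {
    pc <- pieces(p)
    m <- pc$model
    cols <- cbind(1i * m, 2i * pi * (t - tbar) * m, -t^2 * m)
    for (k in seq_len(M)) cols <- cbind(cols, -t * pc$a[k] * pc$C[, k])
    rbind(Re(cols), Im(cols))
  }

  p0 <- c(0, 0, config$beta, rep(config$alphaInit, M))
  lower <- c(-Inf, -config$freqBound, 0, rep(0, M))
  upper <- c(Inf, config$freqBound, Inf, rep(config$alphaMax, M))
  out <- minpack.lm::nls.lm(
    par = p0, fn = resFn, jac = jacFn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = config$maxIter, ftol = 1e-9, ptol = 1e-9))
  p <- out$par
  conv <- out$info %in% c(1L, 2L, 3L, 4L)
  if (!conv)
    warning("linear-combination fit did not converge; best iterate returned")

  pc <- .fitPieces(p, B, t, d, tbar)
  p[1] <- p[1] - 2 * pi * p[2] * tbar  # back to a t = 0 phase reference
  resid <- pc$model - d
  tailIdx <- seq.int(max(1L, length(d) - floor(0.1 * length(d)) + 1L),
                     length(d))
  residualSd <- stats::sd(c(Re(resid[tailIdx]), Im(resid[tailIdx])))

  # full-axis rendering of the fitted model (for spectra and metrics)
  Efull <- exp(1i * p[1] + 2i * pi * p[2] * tFull - p[3] * tFull^2)
  Cfull <- basis@fids * Efull
  for (m in seq_len(M)) Cfull[, m] <- Cfull[, m] * exp(-p[3 + m] * tFull)
  modelFid <- fid(as.vector(Cfull %*% pc$a), x@axis)

  fitres <- new("FitResult",
    amplitudes = stats::setNames(pc$a, basis@entryNames),
    phase = p[1], frequency = p[2],
    lorentzian = stats::setNames(p[4:(3 + M)], basis@entryNames),
    gaussian = p[3],
    crlbPercent = stats::setNames(rep(NA_real_, M), basis@entryNames),
    residualSd = residualSd, model = modelFid, converged = conv,
    nFitted = length(idx), basis = basis,
    config = unclass(config))
  fitres@crlbPercent <- crlb(fitres, x)
  fitres
}

#' Cramer-Rao lower bounds of the fitted amplitudes
#'
#' Builds the model Jacobian over the fitted samples (amplitude columns
#' plus, unless `shapeKnown`, the nonlinear phase/frequency/damping
#' parameters of entries with positive amplitude), forms the Fisher
#' information `F = Re(J^H J) / sigma^2` with `sigma^2` estimated from the
#' final 10% of the fitted residual, and reports
#' `100 * sqrt((F^-1)_aa) / a_m` per entry. Entries with zero amplitude
#' get an infinite bound, as does everything when `F` is singular.
#'
#' @param fit a [FitResult-class].
#' @param x the fitted [Fid-class].
#' @param shapeKnown if `TRUE`, only the amplitudes are treated as unknown
#'   (single-parameter bound).
#' @return named CRLB percentages.
#' @export
crlb <- function(fit, x, shapeKnown = FALSE) {
  stopifnot(is(fit, "FitResult"), is(x, "Fid"))
  cfg <- fit@config
  n <- length(x)
  tFull <- timeScale(x@axis)
  idx <- which(seq_len(n) >= cfg$ns & tFull <= cfg$maxTime)
  t <- tFull[idx]
  B <- fit@basis@fids[idx, , drop = FALSE]
  M <- ncol(B)
  a <- fit@amplitudes
  p <- c(fit@phase, fit@frequency, fit@gaussian)
  E <- exp(1i * p[1] + 2i * pi * p[2] * t - p[3] * t^2)
  C <- B * E
  for (m in seq_len(M)) C[, m] <- C[, m] * exp(-fit@lorentzian[m] * t)
  mdl <- as.vector(C %*% a)

  act <- which(a > 0)
  out <- stats::setNames(rep(Inf, M), fit@basis@entryNames)
  if (!length(act)) return(out)
  J <- C[, act, drop = FALSE]
  if (!shapeKnown) {
    J <- cbind(J, 1i * mdl, 2i * pi * t * mdl, -t^2 * mdl)
    for (k in act) J <- cbind(J, -t * a[k] * C[, k])
  }
  Fmat <- (crossprod(Re(J)) + crossprod(Im(J))) / fit@residualSd^2
  Finv <- tryCatch(solve(Fmat), error = function(e) NULL)
  if (is.null(Finv)) {
    warning("singular Fisher information; CRLB reported as infinite")
    return(out)
  }
  v <- diag(Finv)[seq_along(act)]
  v[v < 0] <- NA_real_
  out[act] <- 100 * sqrt(v) / a[act]
  out
}
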