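## Coefficient-of-variation statistics and the two-step quantification
## parameter optimization (first the Gaussian-damping start value beta_s,
## then the FID start-point pair n_s).

#' Intra-session coefficient of variation
#'
#' Sample standard deviation over mean of the repeated-measurement ratios
#' of one subject. Scale-invariant.
#'
#' @param x numeric vector of at least two finite positive ratios.
#' @return the CoV as a fraction.
#' @export
covIntra <- function(x) {
  if (length(x) < 2L || any(!is.finite(x)))
    stop("need at least two finite values")
  m <- mean(x)
  if (m <= 0) stop("mean must be positive")
  stats::sd(x) / m
}

#' Mean intra-session coefficient of variation over subjects
#'
#' @param table data.frame with columns `subject` and `ratio`, already
#'   restricted to one (variant, beta, ns pair) key; every subject must
#'   contribute all of its repeated measurements.
#' @param nMeasurements expected measurements per subject (checked when
#'   given).
#' @details Subjects with a non-finite ratio (a failed fit at this grid
#'   point) are excluded pairwise with a warning.
#' @return mean over subjects of [covIntra()].
#' @export
mCovIntra <- function(table, nMeasurements = NULL) {
  stopifnot(all(c("subject", "ratio") %in% names(table)))
  split_ <- split(table$ratio, table$subject)
  if (!is.null(nMeasurements) &&
      any(lengths(split_) != nMeasurements))
    stop("missing cells: every subject needs all its measurements")
  bad <- vapply(split_, function(v) any(!is.finite(v)), logical(1))
  if (any(bad)) {
    warning(sum(bad), " subject(s) with failed fits excluded from mCoV")
    split_ <- split_[!bad]
    if (!length(split_)) return(NA_real_)
  }
  mean(vapply(split_, covIntra, numeric(1)))
}

#' Inter-subject coefficient of variation
#'
#' For each measurement index, the CoV across subjects of that
#' measurement's ratios; returned as the mean and standard deviation of
#' these per-index CoVs (the error bar).
#'
#' @param table data.frame with columns `subject`, `measurement`, `ratio`
#'   restricted to one key.
#' @return `list(mean = , error = )`, both fractions.
#' @export
covInter <- function(table) {
  stopifnot(all(c("subject", "measurement", "ratio") %in% names(table)))
  split_ <- split(table$ratio, table$measurement)
  ns <- lengths(split_)
  if (length(unique(ns)) != 1L)
    stop("missing cells: unequal subject counts across measurement indices")
  covs <- vapply(split_, function(v) {
    v <- v[is.finite(v)]
    stats::sd(v) / mean(v)
  }, numeric(1))
  list(mean = mean(covs), error = stats::sd(covs))
}

#' Quantification parameter grid
#'
#' Defaults follow the tested ranges: 10 Gaussian-damping start values
#' between 200 and 5000 (1/s^2) and 13 FID start points between 1 and 50,
#' i.e. 169 (nsDiff, nsOff) pairs.
#'
#' @param betaValues sorted unique Gaussian-damping start values.
#' @param nsValues sorted unique FID start points.
#' @return a classed list with `betaValues`, `nsValues`.
#' @export
gridSpec <- function(betaValues = c(200, 300, 450, 600, 900, 1200, 1500,
                                    2000, 3000, 5000),
                     nsValues = c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L, 15L,
                                  20L, 30L, 40L, 50L)) {
  stopifnot(!is.unsorted(betaValues), !anyDuplicated(betaValues),
            !is.unsorted(nsValues), !anyDuplicated(nsValues),
            all(betaValues > 0), all(nsValues >= 1))
  structure(list(betaValues = betaValues, nsValues = as.integer(nsValues)),
            class = "GridSpec")
}

# Check a mean-CoV table covers variants x betas x all ns pairs exactly once.
.checkGrid <- function(mcov, variants, betas, nsValues) {
  need <- expand.grid(variant = variants, beta = betas,
                      nsDiff = nsValues, nsOff = nsValues,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$variant, d$beta, d$nsDiff, d$nsOff)
  have <- key(mcov)
  if (anyDuplicated(have)) stop("duplicate grid entries in mcov table")
  missing <- setdiff(key(need), have)
  if (length(missing))
    stop("incomplete grid: ", length(missing), " missing entries, e.g. ",
         missing[1])
  invisible(TRUE)
}

#' First optimization step: choose the Gaussian-damping start value
#'
#' For each beta and each of the two reference processing routines
#' (standard `"SR"` and advanced `"ECC+SR+DAS"` by default), the median of
#' the mean intra-session CoV over all ns pairs is taken; the beta
#' minimizing the average of the two medians is returned (ties break to
#' the smallest beta).
#'
#' @param mcov data.frame with columns `variant`, `beta`, `nsDiff`,
#'   `nsOff`, `mcovIntra`.
#' @param grid a [gridSpec()].
#' @param variants the two processing routines entering the criterion.
#' @return `list(beta = chosen value, medians = data.frame)`.
#' @export
optimizeBeta <- function(mcov, grid,
                         variants = c("SR", "ECC+SR+DAS")) {
  sub <- mcov[mcov$variant %in% variants, , drop = FALSE]
  .checkGrid(sub, variants, grid$betaValues, grid$nsValues)
  med <- stats::aggregate(mcovIntra ~ beta + variant, data = sub,
                          FUN = stats::median)
  avg <- stats::aggregate(mcovIntra ~ beta, data = med, FUN = mean)
  best <- min(avg$beta[avg$mcovIntra == min(avg$mcovIntra)])
  list(beta = best, medians = med, average = avg)
}

#' Second optimization step: choose the FID start-point pair
#'
#' At the chosen beta, for every (nsDiff, nsOff) pair the median of the
#' mean intra-session CoV over the preprocessing approaches is computed;
#' the minimizing pair is returned (ties break to the smallest nsDiff,
#' then nsOff).
#'
#' @param mcov data.frame as in [optimizeBeta()], restricted to one beta.
#' @param grid a [gridSpec()].
#' @param variants preprocessing approaches entering the median (the six
#'   tested routines by default).
#' @return `list(nsDiff = , nsOff = , medians = data.frame)`.
#' @export
optimizeStartPoints <- function(mcov, grid, variants = standardVariants()) {
  sub <- mcov[mcov$variant %in% variants, , drop = FALSE]
  beta <- unique(sub$beta)
  if (length(beta) != 1L)
    stop("mcov table must be restricted to the chosen beta")
  .checkGrid(sub, variants, beta, grid$nsValues)
  med <- stats::aggregate(mcovIntra ~ nsDiff + nsOff, data = sub,
                          FUN = stats::median)
  best <- med[med$mcovIntra == min(med$mcovIntra), , drop = FALSE]
  best <- best[order(best$nsDiff, best$nsOff), , drop = FALSE][1, ]
  list(nsDiff = best$nsDiff, nsOff = best$nsOff, medians = med)
}

#' First-decile summary of the grid CoV values per variant
#'
#' The 10th percentile (linear interpolation, `quantile` type 7) of the
#' mean-CoV values over all ns pairs, per preprocessing approach: the
#' boundary of the best tenth of the grid under a lower-is-better metric.
#'
#' @param mcov data.frame with columns `variant` and `mcovIntra` (or the
#'   column named in `value`).
#' @param value column to summarize.
#' @return data.frame with `variant` and `decile`.
#' @export
decileSummary <- function(mcov, value = "mcovIntra") {
  stopifnot(value %in% names(mcov))
  out <- stats::aggregate(mcov[[value]], list(variant = mcov$variant),
                          FUN = function(v)
                            stats::quantile(v, 0.1, type = 7, names = FALSE))
  names(out)[2] <- "decile"
  out
}
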