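test_that("basis construction reflects edit signs and grouping", {
  ax <- testAxis()
  rt <- defaultResonanceTable()
  off <- makeBasisSet(rt, ax, "off")
  expect_true(all(c("NAA", "tCr30", "GABA", "h2o") %in% basisNames(off)))
  # co-edited entries are absent from the edit-off basis
  expect_false(any(c("MM30", "coedit25") %in% basisNames(off)))
  dif <- makeBasisSet(rt, ax, "diff")
  expect_true(all(c("GABA", "MM30", "coedit25", "coedit27", "Glx375",
                    "NAA") %in% basisNames(dif)))
  # doubled inverted doublet: coefficient L1 norm 4, singlets 1
  expect_equal(dif@coeffL1[match("GABA", basisNames(dif))], 4)
  expect_equal(dif@coeffL1[match("MM30", basisNames(dif))], 1)
})

test_that("inner non-negative solver matches the full-design oracle", {
  set.seed(51)
  for (k in 1:50) {
    M <- sample(2:8, 1)
    A <- matrix(rnorm(80 * M), 80)
    b <- rnorm(80)
    mine <- editMRS:::.nnlsNormal(crossprod(A), as.vector(crossprod(A, b)))
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(mine, ref, tolerance = 1e-7)
  }
})

test_that("noise-free spectra are recovered to high accuracy", {
  ch <- tinyCohort(seed = 52L)
  sim <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 52)
  pp <- suppressWarnings(runPipeline(sim$set, "plain"))
  rt <- defaultResonanceTable()
  ob <- makeBasisSet(rt, testAxis(), "off")
  fo <- suppressWarnings(fitSpectrum(offFid(pp), ob,
                                     fitConfig(beta = 1500)))
  truth <- c(NAA = 12, tCr30 = 8, tCr39 = 6.5, Cho = 2.5, mI = 5,
             Glx23 = 6, GABA = 0.3, h2o = 120)
  expect_equal(amplitudes(fo)[names(truth)], truth, tolerance = 1e-3)
  # linearity: doubled data doubles every amplitude
  fo2 <- suppressWarnings(fitSpectrum(offFid(pp) * 2, ob,
                                      fitConfig(beta = 1500)))
  expect_equal(amplitudes(fo2), 2 * amplitudes(fo), tolerance = 1e-3)
  # residual norm at the optimum does not exceed the initial-point misfit
  expect_lt(sum(Mod(samples(fo@model) - samples(offFid(pp)))^2),
            sum(Mod(samples(offFid(pp)))^2))
})

test_that("amplitude estimates are scale-equivariant with invariant CRLB%", {
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 8L, nOff = 8L,
                   nCoils = 1L, noiseSd = 0.3, axis = testAxis(), seed = 53L)
  sim <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 53)
  pp <- runPipeline(sim$set, "plain")
  ob <- makeBasisSet(defaultResonanceTable(), testAxis(), "off")
  f1 <- fitSpectrum(offFid(pp), ob, fitConfig(beta = 1500))
  f2 <- fitSpectrum(offFid(pp) * 5, ob, fitConfig(beta = 1500))
  expect_equal(amplitudes(f2), 5 * amplitudes(f1), tolerance = 1e-4)
  expect_equal(crlbPercent(f2), crlbPercent(f1), tolerance = 1e-3)
  expect_error(fitSpectrum(fid(complex(length.out = 1024L), testAxis()), ob),
               "all-zero")
  expect_error(fitSpectrum(offFid(pp), ob, fitConfig(ns = 500L)), "ns")
})

test_that("CRLB scales with noise, rises with ns and matches oracles", {
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 8L, nOff = 8L,
                   nCoils = 1L, noiseSd = 0.5, axis = testAxis(), seed = 54L)
  sim <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 54)
  pp <- runPipeline(sim$set, "plain")
  ob <- makeBasisSet(defaultResonanceTable(), testAxis(), "off")
  f1 <- fitSpectrum(offFid(pp), ob, fitConfig(beta = 1500))
  # doubling sigma doubles CRLB%
  f2 <- f1; f2@residualSd <- 2 * f1@residualSd
  expect_equal(crlb(f2, offFid(pp)), 2 * crlb(f1, offFid(pp)),
               tolerance = 1e-9)
  # omitting leading samples cannot improve the bound
  f50 <- suppressWarnings(fitSpectrum(offFid(pp), ob,
                                      fitConfig(ns = 50L, beta = 1500)))
  expect_lt(f50@nFitted, f1@nFitted)
  expect_gt(crlbPercent(f50)[["NAA"]], crlbPercent(f1)[["NAA"]])

  # single-resonance case: known-shape bound matches the closed form
  ax <- testAxis()
  t <- timeScale(ax)
  rt1 <- resonance("NAA", 2.01, 10, lorentzian = 30, gaussian = 800)
  b1 <- makeBasisSet(rt1, ax, "off")
  set.seed(54)
  noise <- 0.4 * complex(real = rnorm(1024), imaginary = rnorm(1024))
  d <- fid(samples(editMRS:::.cleanFid(rt1, ax, "off")) + noise, ax)
  ft <- fitSpectrum(d, b1, fitConfig(beta = 800))
  known <- crlb(ft, d, shapeKnown = TRUE)[["NAA"]]
  shape <- b1@fids[, 1] * exp(-ft@lorentzian[1] * t - ft@gaussian * t^2)
  closed <- 100 * ft@residualSd / (amplitudes(ft)[["NAA"]] *
                                     sqrt(sum(Mod(shape)^2)))
  expect_equal(known, closed, tolerance = 0.01)

  # full bound vs a brute-force numeric Fisher matrix
  numJ <- function(pvec) {
    base <- editMRS:::.fitPieces(pvec, b1@fids, t, samples(d))
    cols <- list()
    eps <- 1e-6
    for (kk in seq_along(pvec)) {
      pp_ <- pvec; pp_[kk] <- pp_[kk] + eps
      m2 <- editMRS:::.fitPieces(pp_, b1@fids, t, samples(d))
      # hold amplitudes fixed at the optimum for the nonlinear columns
      cols[[kk]] <- (m2$C %*% base$a - base$C %*% base$a) / eps
    }
    do.call(cbind, cols)
  }
  pvec <- c(ft@phase, ft@frequency, ft@gaussian, ft@lorentzian)
  Jnum <- cbind(editMRS:::.fitPieces(pvec, b1@fids, t, samples(d))$C,
                numJ(pvec))
  Fnum <- (crossprod(Re(Jnum)) + crossprod(Im(Jnum))) / ft@residualSd^2
  crlbNum <- 100 * sqrt(solve(Fnum)[1, 1]) / amplitudes(ft)[["NAA"]]
  expect_equal(crlb(ft, d)[["NAA"]], crlbNum, tolerance = 0.02)
})

test_that("fitted NAA linewidth matches closed forms and the region target", {
  ax <- testAxis()
  # pure Lorentzian and pure Gaussian closed forms via a controlled fit
  for (shape in list(list(al = 60, ga = 1e-9),
                     list(al = 1e-3, ga = 1451.6))) {
    rt1 <- resonance("NAA", 2.01, 10, lorentzian = shape$al,
                     gaussian = shape$ga)
    b1 <- makeBasisSet(rt1, ax, "off", includeLineshape = FALSE)
    d <- editMRS:::.cleanFid(rt1, ax, "off")
    ft <- suppressWarnings(fitSpectrum(d, b1, fitConfig(beta = max(shape$ga,
                                                                   200))))
    expected <- if (shape$al > 1) shape$al / pi else
      2 * sqrt(shape$ga * log(2)) / pi
    expect_equal(fwhmNaa(ft)$hz, expected, tolerance = 0.05)
  }
  # hippocampus-like noisy measurement lands at the reported scale
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 16L, nOff = 16L,
                   nCoils = 2L, noiseSd = 1, axis = spectralAxis(2048L,
                                                                1 / 4000),
                   seed = 55L)
  sim <- simulateTransientSet(ch, seed = 55)
  sc <- combineCoils(sim$set, estimateCoilWeights(sim$set))
  pp <- runPipeline(sc, "ECC+SR")
  q <- quantifyPair(pp, beta = 1500, nsDiff = 3, nsOff = 4)
  expect_equal(q$fwhm$hz, 23, tolerance = 2 / 23)
  expect_equal(q$fwhm$ppm, hzToPpm(q$fwhm$hz, fidAxis(offFid(pp))))
})

test_that("SNR halves when the noise level doubles", {
  snrAt <- function(noiseSd, seed) {
    ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 8L, nOff = 8L,
                     nCoils = 1L, noiseSd = noiseSd, axis = testAxis(),
                     seed = seed)
    sim <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = seed)
    pp <- runPipeline(sim$set, "plain")
    ob <- makeBasisSet(defaultResonanceTable(), testAxis(), "off")
    ft <- fitSpectrum(offFid(pp), ob, fitConfig(beta = 1500))
    snrNaa(ft, offFid(pp))
  }
  set.seed(56)
  lo <- vapply(1:10, function(s) snrAt(0.5, s), numeric(1))
  hi <- vapply(1:10, function(s) snrAt(1.0, s + 100), numeric(1))
  expect_equal(mean(lo) / mean(hi), 2, tolerance = 0.1)
  # the noise span must not contain any basis resonance
  ch <- tinyCohort(seed = 57L)
  sim <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 57)
  pp <- suppressWarnings(runPipeline(sim$set, "plain"))
  ob <- makeBasisSet(defaultResonanceTable(), testAxis(), "off")
  ft <- suppressWarnings(fitSpectrum(offFid(pp), ob, fitConfig(beta = 1500)))
  expect_error(snrNaa(ft, offFid(pp), noiseSpanPpm = c(3.5, 4.0)),
               "overlaps")
})

test_that("the GABA+/tCr ratio is exact noise-free and shift-invariant", {
  ch <- tinyCohort(seed = 58L)
  sim <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 58)
  pp <- suppressWarnings(runPipeline(sim$set, "plain"))
  # exact-model check without water filtering (the clean difference holds
  # no water), so the fit model matches the generator exactly
  q <- suppressWarnings(quantifyPair(pp, beta = 1500, waterRemoval = FALSE))
  expect_equal(q$ratio, sim$truth$trueRatio, tolerance = 0.005)
  # determinism
  q2 <- suppressWarnings(quantifyPair(pp, beta = 1500, waterRemoval = FALSE))
  expect_identical(q$ratio, q2$ratio)
  # a global phase/frequency modulation of the inputs is absorbed
  shift <- function(f) phaseShiftFid(f, 0.7, 3)
  pp2 <- new("ProcessedPair", offFid = shift(offFid(pp)),
             diffFid = shift(diffFid(pp)), waterFid = pairWater(pp),
             variant = pairVariant(pp), alignment = data.frame())
  q3 <- suppressWarnings(quantifyPair(pp2, beta = 1500,
                                      waterRemoval = FALSE))
  expect_equal(q3$ratio, q$ratio, tolerance = 0.01)
})
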