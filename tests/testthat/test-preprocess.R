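test_that("coil weights are signal-weighted under white noise", {
  # two coils, equal then unequal water amplitudes, near-identity noise
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 16L, nOff = 16L,
                   nCoils = 2L, noiseSd = 0.5,
                   coilSensitivities = c(1 + 0i, 1 + 0i),
                   noiseCorrelation = diag(2), axis = testAxis(2048L),
                   seed = 21L)
  sim <- simulateTransientSet(ch, seed = 21)
  w <- estimateCoilWeights(sim$set)
  expect_equal(Mod(w@weights)[1] / Mod(w@weights)[2], 1, tolerance = 0.1)
  ch2 <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 16L,
                    nOff = 16L, nCoils = 2L, noiseSd = 0.5,
                    coilSensitivities = c(2 + 0i, 1 + 0i),
                    noiseCorrelation = diag(2), axis = testAxis(2048L),
                    seed = 22L)
  sim2 <- simulateTransientSet(ch2, seed = 22)
  w2 <- estimateCoilWeights(sim2$set)
  expect_equal(Mod(w2@weights)[1] / Mod(w2@weights)[2], 2, tolerance = 0.1)
})

test_that("correlated-noise weights match the hand-inverted 2x2 oracle", {
  # N = [[1, .5], [.5, 1]], s = (1, 1): N^-1 s is proportional to (2/3, 2/3),
  # i.e. still equal weights but the estimated covariance must show rho = 0.5
  N <- matrix(c(1, 0.5, 0.5, 1), 2)
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 32L, nOff = 32L,
                   nCoils = 2L, noiseSd = 1,
                   coilSensitivities = c(1 + 0i, 1 + 0i),
                   noiseCorrelation = N, axis = testAxis(2048L), seed = 23L)
  sim <- simulateTransientSet(ch, seed = 23)
  w <- estimateCoilWeights(sim$set)
  rho <- Re(w@noiseCorrelation[1, 2]) /
    sqrt(Re(w@noiseCorrelation[1, 1]) * Re(w@noiseCorrelation[2, 2]))
  expect_equal(rho, 0.5, tolerance = 0.1)
  expect_equal(Mod(w@weights)[1] / Mod(w@weights)[2], 1, tolerance = 0.1)
  # oracle: solving the true system by hand gives (2/3, 2/3) x water amp
  s <- w@waterAmplitudes
  expect_equal(as.vector(solve(N, c(1, 1))), c(2, 2) / 3, tolerance = 1e-12)
})

test_that("coil combination is unit-consistent and zero-phase on water", {
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 8L, nOff = 8L,
                   nCoils = 4L, noiseSd = 1, axis = testAxis(), seed = 24L)
  sim <- simulateTransientSet(ch, seed = 24)
  w <- estimateCoilWeights(sim$set)
  sc <- combineCoils(sim$set, w)
  expect_equal(nCoils(sc), 1L)
  expect_equal(abs(Arg(samples(waterFid(sc))[1])), 0, tolerance = 0.05)
  expect_error(combineCoils(sc, w), "coil count")
})

test_that("combined SNR is at least the best single coil's", {
  wins <- 0L
  for (seed in 1:20) {
    ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 4L, nOff = 4L,
                     nCoils = 4L, noiseSd = 1.5, axis = testAxis(512L),
                     seed = seed)
    sim <- simulateTransientSet(ch, seed = seed)
    w <- estimateCoilWeights(sim$set)
    sc <- combineCoils(sim$set, w)
    snrOf <- function(v) Mod(mean(v[1:4])) / sd(c(Re(v[400:512]),
                                                  Im(v[400:512])))
    single <- vapply(seq_len(4), function(cix)
      snrOf(sim$set@data[, cix, 1]), numeric(1))
    comb <- snrOf(sc@data[, 1, 1])
    wins <- wins + (comb >= max(single) * 0.98)
  }
  expect_gte(wins, 19L)
})

test_that("equal sensitivities with identity noise reduce to the mean", {
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 4L, nOff = 4L,
                   nCoils = 3L, noiseSd = 0.2,
                   coilSensitivities = rep(1 + 0i, 3),
                   noiseCorrelation = diag(3), axis = testAxis(512L),
                   seed = 25L)
  sim <- simulateTransientSet(ch, seed = 25)
  sc <- combineCoils(sim$set, estimateCoilWeights(sim$set))
  plain <- rowMeans(matrix(sim$set@data[, , 2], ncol = 3))
  ratio <- sc@data[, 1, 2] / plain
  # proportional, with one complex scalar (the phased average)
  mid <- ratio[Mod(plain) > stats::quantile(Mod(plain), 0.8)]
  expect_lt(sd(Mod(mid)) / mean(Mod(mid)), 0.05)
  expect_lt(sd(Arg(mid)), 0.05)
})

test_that("eddy-current compensation cancels a shared phase exactly", {
  ax <- testAxis()
  t <- timeScale(ax)
  clean <- samples(makeBasisFid(2.01, ax, 10, lorentzian = 30,
                                gaussian = 500))
  waterMag <- 100 * exp(-20 * t)
  # identity when the water has zero phase
  same <- eddyCurrentCorrect(fid(clean, ax), fid(waterMag + 0i, ax))
  expect_equal(samples(same), clean, tolerance = 1e-12)
  # exact cancellation of an arbitrary shared smooth phase, 20 cases
  set.seed(31)
  for (k in 1:20) {
    phi <- cumsum(rnorm(length(t), 0, 0.02))
    corrupted <- fid(clean * exp(1i * phi), ax)
    water <- fid(waterMag * exp(1i * phi), ax)
    out <- eddyCurrentCorrect(corrupted, water)
    expect_lt(max(Mod(samples(out) - clean)), 1e-6 * max(Mod(clean)))
  }
  expect_error(eddyCurrentCorrect(fid(clean, ax),
                                  fid(complex(length.out = length(t)), ax)),
               "all zero")
})

test_that("ECC freezes the phase once water falls below the noise floor", {
  ax <- testAxis()
  t <- timeScale(ax)
  set.seed(32)
  phi <- 2 * exp(-t / 0.05)
  water <- 50 * exp(-60 * t) * exp(1i * phi) +
    0.5 * complex(real = rnorm(length(t)), imaginary = rnorm(length(t)))
  x <- fid(exp(1i * phi) * exp(-30 * t), ax)
  out <- eddyCurrentCorrect(x, fid(water, ax))
  # early samples (high water SNR) are corrected accurately
  early <- t < 0.03
  expect_lt(mean(abs(angDiff(Arg(samples(out)[early]),
                             Arg(exp(-30 * t[early]) + 0i)))), 0.05)
})

test_that("spectral registration recovers exact modulations", {
  ax <- testAxis()
  t <- timeScale(ax)
  r <- samples(makeBasisFid(3.0, ax, 10, lorentzian = 40, gaussian = 800))
  for (tc in list(c(0.3, 1.2), c(-0.7, -3.4), c(2.9, 17), c(0, 0))) {
    x <- r * exp(-1i * tc[1] - 2i * pi * tc[2] * t)
    ft <- editMRS:::.alignFit(x, r, t, seq_along(t))
    expect_lt(abs(angDiff(ft$phase, tc[1])), 1e-6)
    expect_lt(abs(ft$frequency - tc[2]), 1e-5)
  }
})

test_that("registration objective never exceeds the uncorrected misfit", {
  set.seed(33)
  ax <- testAxis(512L)
  t <- timeScale(ax)
  r <- samples(makeBasisFid(3.0, ax, 5, lorentzian = 50))
  for (k in 1:25) {
    x <- r * exp(1i * runif(1, -2, 2) + 2i * pi * runif(1, -5, 5) * t) +
      0.5 * complex(real = rnorm(512), imaginary = rnorm(512))
    ft <- editMRS:::.alignFit(x, r, t, seq_along(t))
    base <- sum(Mod(x - r)^2)
    expect_lte(ft$objective, base + 1e-6 * base)
  }
})

test_that("registration aligns a drifting transient set", {
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 8L, nOff = 8L,
                   nCoils = 1L, noiseSd = 0.2, axis = testAxis(), seed = 34L)
  art <- artifactSpec(phaseDriftSd = 0.05, frequencyDriftSd = 0.5,
                      eddyAmplitude = 0)
  sim <- simulateTransientSet(ch, artifacts = art, seed = 34)
  reg <- spectralRegister(sim$set)
  al <- reg$alignment
  expect_true(all(al$converged[al$state != "water_reference"]))
  # recovered corrections oppose the injected drift up to a shared offset
  tr <- sim$truth$drift
  for (st in c("on", "off")) {
    e <- al$frequency[al$state == st] + tr$frequency[tr$state == st]
    expect_lt(sd(e), 0.2)
  }
})

test_that("DAS recovers an exact on/off modulation and reduces the artifact", {
  ax <- testAxis()
  rt <- defaultResonanceTable()
  on <- editMRS:::.cleanFid(rt, ax, "on")
  off <- editMRS:::.cleanFid(rt, ax, "off")
  z <- dasAlign(on * 1, off)        # aligned inputs: structural pull only
  expect_lt(abs(z$frequency), 0.3)
  # exact model: a modulated copy of the edit-off average is recovered
  # shift on the alignment grid; sub-bin frequency offsets of broad
  # band-limited lines sit below the objective's sensitivity (?dasAlign)
  fbin <- spectralWidth(ax) / nPoints(ax)
  off2 <- phaseShiftFid(off, -0.4, -2 * fbin)
  z2 <- dasAlign(off2, off)
  expect_equal(z2$frequency, 2 * fbin, tolerance = 0.1)
  expect_lt(abs(angDiff(z2$phase, 0.4)), 0.08)
  # injected 1 Hz on/off offset on a creatine-only signal: the residual
  # at 3.03 ppm drops below 20% (early-FID window for sub-bin sensitivity)
  cr <- rt[rt$name %in% c("tCr30", "tCr39"), ]
  crOff <- editMRS:::.cleanFid(cr, ax, "off")
  onShift <- phaseShiftFid(crOff, 0, 1)
  resid <- function(f) {
    sp <- fidSpectrum(f)
    max(Mod(sp$y[abs(sp$ppm - 3.03) < 0.02]))
  }
  before <- resid(onShift - crOff)
  after <- resid(dasAlign(onShift, crOff, window = 0.064)$onAvg - crOff)
  expect_lt(after, 0.2 * before)
})

test_that("difference optimization agrees with DAS on realistic cohorts", {
  ok <- 0L
  rt <- defaultResonanceTable()
  for (seed in 1:20) {
    ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 32L,
                     nOff = 32L, nCoils = 1L, noiseSd = 0.3,
                     axis = testAxis(), seed = seed)
    sim <- simulateTransientSet(ch, rt,
                                artifactSpec(0.05, 0.5, 0, 0.02), seed = seed)
    sr <- spectralRegister(sim$set)
    on <- stateMean(sr$set, "on"); off <- stateMean(sr$set, "off")
    da <- dasAlign(on, off); dn <- doAlign(on, off)
    ok <- ok + (abs(da$frequency - dn$frequency) <= 0.5 &&
                  abs(angDiff(da$phase, dn$phase)) <= 0.1)
  }
  expect_gte(ok, 18L)  # >= 90%
  # trivial cases
  ax <- testAxis()
  on <- editMRS:::.cleanFid(rt, ax, "on")
  off <- editMRS:::.cleanFid(rt, ax, "off")
  z <- doAlign(off * 1, off)
  expect_lt(abs(z$frequency), 0.05)
  expect_lt(abs(z$phase), 0.02)
  z2 <- doAlign(phaseShiftFid(off, -0.3, 0), off)
  expect_lt(abs(angDiff(z2$phase, 0.3)), 0.05)
})

test_that("pipeline variants parse, validate and round-trip provenance", {
  v <- parseVariant("ECC+SR+DAS")
  expect_true(v@ecc); expect_true(v@sr); expect_equal(v@dasMode, "das")
  expect_equal(variantLabel(v), "ECC+SR+DAS")
  expect_equal(variantLabel(parseVariant("plain")), "plain")
  expect_error(pipelineVariant(FALSE, FALSE, "das"), "require")
  expect_error(parseVariant("SR+XX"), "unknown")
  expect_length(standardVariants(), 6L)
  ch <- tinyCohort(seed = 41L)
  sim <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 41)
  pp <- runPipeline(sim$set, "SR+DO")
  expect_equal(variantLabel(pairVariant(pp)), "SR+DO")
})

test_that("plain pipeline on clean input leaves no creatine residual", {
  ch <- tinyCohort(seed = 42L)
  sim <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 42)
  pp <- runPipeline(sim$set, "plain")
  sp <- fidSpectrum(diffFid(pp))
  spo <- fidSpectrum(offFid(pp))
  at <- function(s, p) max(Mod(s$y[abs(s$ppm - p) < 0.02]))
  # creatine cancels; what remains at 3.91 ppm is the tail of the nearby
  # co-edited 3.75 ppm line, a few percent of the off-spectrum peak
  expect_lt(at(sp, 3.91), 0.05 * at(spo, 3.91))
  # subtraction linearity: scaling the set scales the difference
  s2 <- sim$set
  s2@data <- s2@data * 2
  pp2 <- runPipeline(s2, "plain")
  expect_equal(samples(diffFid(pp2)), 2 * samples(diffFid(pp)),
               tolerance = 1e-12)
})

test_that("an on/off offset is suppressed by SR and further by DAS", {
  rt <- defaultResonanceTable()
  t <- timeScale(testAxis())
  joint <- 0L
  for (seed in 1:20) {
    ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 16L,
                     nOff = 16L, nCoils = 1L, noiseSd = 0.3,
                     axis = testAxis(), seed = seed)
    sim <- simulateTransientSet(ch, rt, artifactSpec(0.02, 0.2, 0, 0.02),
                                seed = seed)
    s <- sim$set
    for (j in which(editStates(s) == "on"))
      s@data[, 1, j] <- s@data[, 1, j] * exp(1i * 0.1 + 2i * pi * 1 * t)
    pps <- processMeasurement(s, c("plain", "SR", "SR+DAS"))
    r <- vapply(pps, function(p) {
      sp <- fidSpectrum(diffFid(p))
      max(Mod(sp$y[abs(sp$ppm - 3.91) < 0.02]))
    }, numeric(1))
    joint <- joint + (r[["plain"]] > r[["SR"]] &&
                        r[["SR+DAS"]] <= 1.05 * r[["SR"]])
  }
  expect_gte(joint, 19L)  # >= 95%
})
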