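test_that("basis FID construction honors amplitude and position", {
  ax <- testAxis()
  expect_true(all(samples(makeBasisFid(3.0, ax, amplitude = 0)) == 0))
  # undamped resonance at the carrier: constant-magnitude, zero-frequency
  f <- makeBasisFid(referencePpm(ax), ax, amplitude = 2)
  expect_equal(Mod(samples(f)), rep(2, length(f)), tolerance = 1e-12)
  expect_equal(max(abs(diff(Arg(samples(f))))), 0, tolerance = 1e-12)
  expect_warning(makeBasisFid(40, ax), "outside")
})

test_that("Lorentzian damping gives spectral FWHM of damping/pi", {
  ax <- testAxis(2048L)
  for (alpha in c(30, 60, 120)) {
    f <- makeBasisFid(3.0, ax, lorentzian = alpha)
    expect_equal(oracleFwhmHz(samples(f), dwellTime(ax)), alpha / pi,
                 tolerance = 0.02)
  }
})

test_that("region tables reach the target NAA linewidths", {
  ax <- spectralAxis(2048L, 1 / 4000)
  for (cfg in list(list(region = "hippocampus", target = 23, tol = 2),
                   list(region = "pcc", target = 8.9, tol = 1))) {
    rt <- defaultResonanceTable(cfg$region)
    i <- match("NAA", rt$name)
    f <- makeBasisFid(rt$center[i], ax, rt$amplitude[i],
                      rt$lorentzian[i], rt$gaussian[i])
    expect_equal(oracleFwhmHz(samples(f), dwellTime(ax)), cfg$target,
                 tolerance = cfg$tol / cfg$target)
  }
  expect_error(defaultResonanceTable("cerebellum"))
})

test_that("amplitude scaling of the table scales the clean signal linearly", {
  ax <- testAxis()
  rt <- defaultResonanceTable()
  s1 <- samples(editMRS:::.cleanFid(rt, ax, "off"))
  rt2 <- rt; rt2$amplitude <- 3 * rt2$amplitude
  expect_equal(samples(editMRS:::.cleanFid(rt2, ax, "off")), 3 * s1,
               tolerance = 1e-12)
})

test_that("edit behaviors cancel creatine and double GABA in the difference", {
  ax <- testAxis()
  rt <- defaultResonanceTable()
  diffClean <- editMRS:::.cleanFid(rt, ax, "on") -
    editMRS:::.cleanFid(rt, ax, "off")
  sp <- fidSpectrum(diffClean)
  # tCr at 3.91 ppm is far from edited resonances: must vanish exactly
  offSp <- fidSpectrum(editMRS:::.cleanFid(rt, ax, "off"))
  at <- function(s, p) max(Mod(s$y[abs(s$ppm - p) < 0.02]))
  expect_lt(at(sp, 3.91), 0.05 * at(offSp, 3.91))
  # off_only rows cancel exactly: their own difference is identically zero
  offOnly <- rt[rt$editBehavior == "off_only", ]
  zdiff <- editMRS:::.cleanFid(offOnly, ax, "on") -
    editMRS:::.cleanFid(offOnly, ax, "off")
  expect_lt(max(Mod(samples(zdiff))), 1e-12)
  # doubled inverted GABA: difference of only the GABA rows equals 2x each
  gaba <- rt[rt$group == "GABA", ]
  gOn <- editMRS:::.cleanFid(gaba, ax, "on")
  gDiff <- editMRS:::.cleanFid(gaba, ax, "on") -
    editMRS:::.cleanFid(gaba, ax, "off")
  expect_equal(samples(gDiff), 2 * samples(gOn), tolerance = 1e-12)
})

test_that("simulation is deterministic and clean when artifact-free", {
  ch <- tinyCohort(seed = 5L)
  a <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 5)
  b <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 5)
  expect_identical(a$set@data, b$set@data)
  expect_identical(a$truth$drift, b$truth$drift)
  # zero artifacts, zero noise, one coil: all on-transients identical
  onIdx <- which(editStates(a$set) == "on")
  for (j in onIdx[-1])
    expect_equal(a$set@data[, 1, j], a$set@data[, 1, onIdx[1]],
                 tolerance = 1e-14)
})

test_that("cohort simulation has the declared size and reproducibility", {
  ch <- cohortSpec(nSubjects = 2L, nMeasurements = 3L, nOn = 4L, nOff = 4L,
                   nCoils = 1L, noiseSd = 0.1, axis = testAxis(256L),
                   seed = 9L)
  co <- simulateCohort(ch)
  expect_length(co$sets, 6L)
  expect_equal(nrow(co$manifest), 6L)
  co2 <- simulateCohort(ch)
  expect_identical(co$sets[["S02_m3"]]@data, co2$sets[["S02_m3"]]@data)
  # subject factor shared across the subject's measurements
  expect_equal(co$truth[["S01_m1"]]$trueRatio, co$truth[["S01_m3"]]$trueRatio)
})

test_that("frequency drift follows the random-walk law", {
  ch <- cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 16L, nOff = 16L,
                   nCoils = 1L, noiseSd = 0, axis = testAxis(256L), seed = 1L)
  art <- artifactSpec(phaseDriftSd = 0, frequencyDriftSd = 1,
                      eddyAmplitude = 0)
  set.seed(100)
  finals <- replicate(200, {
    sim <- simulateTransientSet(ch, artifacts = art)
    utils::tail(sim$truth$drift$frequency, 1)
  })
  # after nt steps the walk has sd sqrt(nt) * stepSd = sqrt(32)
  expect_equal(sd(finals), sqrt(32), tolerance = 0.15)
})

test_that("between-subject variability propagates to the true ratio CoV", {
  ch <- cohortSpec(nSubjects = 200L, nMeasurements = 1L, nOn = 4L, nOff = 4L,
                   betweenSubjectCv = 0.05, axis = testAxis(256L), seed = 3L)
  set.seed(11)
  tr <- drawCohortTruth(ch, defaultResonanceTable())
  cv <- sd(tr$trueRatio) / mean(tr$trueRatio)
  expect_equal(cv, 0.05, tolerance = 0.25)
  ch0 <- cohortSpec(nSubjects = 10L, betweenSubjectCv = 0,
                    axis = testAxis(256L), seed = 3L)
  tr0 <- drawCohortTruth(ch0, defaultResonanceTable())
  expect_equal(diff(range(tr0$trueRatio)), 0)
})

test_that("eddy phase is shared by water reference and metabolite transients", {
  ch <- tinyCohort(seed = 2L)
  art <- artifactSpec(0, 0, eddyAmplitude = 1.2, eddyTimeConstant = 0.015)
  sim <- simulateTransientSet(ch, artifacts = art, seed = 2)
  clean <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 2)
  t <- timeScale(setAxis(sim$set))
  expected <- 1.2 * exp(-t / 0.015)
  for (j in c(1L, 2L)) {  # water reference and first metabolite transient
    ratio <- sim$set@data[, 1, j] / clean$set@data[, 1, j]
    expect_equal(Arg(ratio[1:100]), expected[1:100], tolerance = 1e-8)
  }
})

test_that("the spurious echo option adds a delayed transient artifact", {
  ch <- tinyCohort(seed = 4L)
  art <- artifactSpec(0, 0, 0, spuriousEcho = list(delay = 0.1,
                                                   amplitude = 0.5))
  sim <- simulateTransientSet(ch, artifacts = art, seed = 4)
  clean <- simulateTransientSet(ch, artifacts = noArtifacts(), seed = 4)
  extra <- Mod(sim$set@data[, 1, 2] - clean$set@data[, 1, 2])
  t <- timeScale(setAxis(sim$set))
  expect_gt(max(extra[abs(t - 0.1) < 0.01]), 10 * max(extra[t < 0.05]))
})
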