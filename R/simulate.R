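## Synthetic multi-coil, multi-transient edited MRS cohorts with known
## ground truth. Editing is modeled phenomenologically: each resonance
## carries an edit behavior that fixes its sign in the edit-on and edit-off
## transients, rather than a density-matrix simulation.

.EDIT_BEHAVIORS <- c("off_only", "co_edited", "inverted")

# Sign of a resonance in a given edit state.
# off_only:  present identically in on and off -> cancels in the difference.
# co_edited: present in on only               -> survives in the difference.
# inverted:  +1 in on, -1 in off              -> doubled in the difference.
.editSign <- function(behavior, state) {
  stopifnot(behavior %in% .EDIT_BEHAVIORS, state %in% c("on", "off"))
  if (state == "on") return(rep(1, length(behavior)))
  ifelse(behavior == "off_only", 1, ifelse(behavior == "co_edited", 0, -1))
}

#' Describe one resonance of the synthetic spectrum
#'
#' @param name entry label.
#' @param center chemical shift (ppm).
#' @param amplitude concentration-scale amplitude (>= 0, arbitrary units).
#' @param lorentzian Lorentzian damping rate (1/s); spectral FWHM is
#'   `lorentzian / pi` Hz.
#' @param gaussian Gaussian damping (1/s^2); spectral FWHM is
#'   `2 * sqrt(gaussian * log(2)) / pi` Hz.
#' @param editBehavior `"off_only"` (cancels in the difference),
#'   `"co_edited"` (survives) or `"inverted"` (sign flips between edit-on
#'   and edit-off, doubling in the difference).
#' @param group amplitude group label; entries sharing a group are fitted
#'   as one amplitude (the GABA pseudo-doublet).
#' @param role `"gabaplus"`, `"tcr"` or `NA`; marks the rows entering the
#'   GABA+/tCr ground-truth ratio.
#' @param subjectVaries logical; whether the between-subject amplitude
#'   factor applies to this row.
#' @return one-row data.frame usable with `rbind`.
#' @export
resonance <- function(name, center, amplitude, lorentzian = 0, gaussian = 0,
                      editBehavior = "off_only", group = name,
                      role = NA_character_, subjectVaries = FALSE) {
  stopifnot(amplitude >= 0, lorentzian >= 0, gaussian >= 0,
            editBehavior %in% .EDIT_BEHAVIORS)
  data.frame(
    name = name, center = center, amplitude = amplitude,
    lorentzian = lorentzian, gaussian = gaussian,
    editBehavior = editBehavior, group = group, role = role,
    subjectVaries = subjectVaries, stringsAsFactors = FALSE
  )
}

#' Default resonance tables for the two simulated brain regions
#'
#' Returns the resonances of the synthetic edit-on / edit-off spectra:
#' NAA (2.01 ppm), creatine at 3.03 and 3.91 ppm, choline (3.19), myo-inositol
#' (3.55), Glx (2.35), the GABA pseudo-doublet (two equal singlets at 2.95 and
#' 3.05 ppm, `inverted`), a broader macromolecule singlet at 3.0 ppm
#' (`co_edited`, making the edited signal "GABA+"), co-edited Glx at 3.75 ppm,
#' co-edited resonances at 2.5 and 2.7 ppm, and a residual water line.
#'
#' Every metabolite carries a 5 Hz Lorentzian component; the region sets the
#' shared Gaussian damping so that the NAA linewidth is ~23 Hz in the
#' hippocampus (strong susceptibility broadening, short T2*) and ~9 Hz in the
#' posterior cingulate cortex (PCC).
#'
#' @param region `"hippocampus"` or `"pcc"`.
#' @return data.frame of [resonance()] rows.
#' @export
defaultResonanceTable <- function(region = c("hippocampus", "pcc")) {
  region <- match.arg(region)
  # Gaussian dampings solve the Voigt width relation
  # fV = 0.5346 fL + sqrt(0.2166 fL^2 + fG^2) for fL = 5 Hz and target
  # fV = 23 Hz (hippocampus) / 8.9 Hz (PCC); gaussian = (pi*fG/2)^2 / log(2).
  gReg <- switch(region, hippocampus = 1451.6, pcc = 118.8)
  aL <- pi * 5          # 5 Hz Lorentzian component
  aMM <- pi * 25        # broad macromolecule
  rbind(
    resonance("NAA",     2.01, 12.0, aL, gReg),
    resonance("tCr30",   3.03,  8.0, aL, gReg, role = "tcr"),
    resonance("tCr39",   3.91,  6.5, aL, gReg),
    resonance("Cho",     3.19,  2.5, aL, gReg),
    resonance("mI",      3.55,  5.0, aL, gReg),
    resonance("Glx23",   2.35,  6.0, aL, gReg),
    resonance("GABA_A",  2.95,  0.3, aL, gReg, "inverted", group = "GABA",
              role = "gabaplus", subjectVaries = TRUE),
    resonance("GABA_B",  3.05,  0.3, aL, gReg, "inverted", group = "GABA",
              role = "gabaplus", subjectVaries = TRUE),
    resonance("MM30",    3.00,  0.4, aMM, gReg, "co_edited",
              role = "gabaplus", subjectVaries = TRUE),
    resonance("Glx375",  3.75,  1.2, aL, gReg, "co_edited"),
    resonance("coedit25", 2.50, 0.5, aL, gReg, "co_edited"),
    resonance("coedit27", 2.70, 0.5, aL, gReg, "co_edited"),
    # VAPOR-suppressed residual water, ~10x NAA as typical in vivo; the
    # water reference rescales this line by 1/residualWaterFraction
    resonance("h2o",     4.70, 120, aL, gReg)
  )
}

#' Render one resonance as a time-domain FID
#'
#' `amplitude * exp(2i*pi*df*t - lorentzian*t - gaussian*t^2)` with `df` the
#' carrier offset of `center`. The spectral integral is proportional to the
#' amplitude.
#'
#' @param center chemical shift (ppm).
#' @param axis a [SpectralAxis-class].
#' @param amplitude,lorentzian,gaussian lineshape parameters, see
#'   [resonance()].
#' @return a [Fid-class].
#' @export
makeBasisFid <- function(center, axis, amplitude = 1, lorentzian = 0,
                         gaussian = 0) {
  pr <- range(ppmScale(axis))
  if (center < pr[1] || center > pr[2])
    warning("resonance center ", center,
            " ppm lies outside the spectral window; it will alias")
  t <- timeScale(axis)
  df <- ppmToOffsetHz(center, axis)
  fid(amplitude * exp(2i * pi * df * t - lorentzian * t - gaussian * t^2),
      axis)
}

# Noise-free sum of all resonances in one edit state, with optional
# per-row amplitude factors.
.cleanFid <- function(resonances, axis, state, factors = NULL) {
  t <- timeScale(axis)
  acc <- complex(length.out = axis@nPoints)
  if (is.null(factors)) factors <- rep(1, nrow(resonances))
  sgn <- .editSign(resonances$editBehavior, state)
  for (i in seq_len(nrow(resonances))) {
    if (sgn[i] == 0 || resonances$amplitude[i] == 0) next
    df <- ppmToOffsetHz(resonances$center[i], axis)
    acc <- acc + sgn[i] * resonances$amplitude[i] * factors[i] *
      exp(2i * pi * df * t - resonances$lorentzian[i] * t -
            resonances$gaussian[i] * t^2)
  }
  fid(acc, axis)
}

#' Per-transient artifact model
#'
#' Phase and frequency drift are independent Gaussian random walks across
#' the interleaved on/off transient stream; residual eddy currents add the
#' time-dependent phase `eddyAmplitude * exp(-t / eddyTimeConstant)` to every
#' transient of a measurement, including the water reference (the assumption
#' eddy-current compensation exploits). An optional spurious echo adds a
#' delayed, damped oscillation to the water-suppressed transients.
#'
#' @param phaseDriftSd random-walk step s.d. of the zero-order phase
#'   (rad/transient).
#' @param frequencyDriftSd random-walk step s.d. of the frequency offset
#'   (Hz/transient).
#' @param eddyAmplitude eddy-current phase amplitude at `t = 0` (rad).
#' @param eddyTimeConstant eddy-current decay constant (s); must be > 0
#'   when `eddyAmplitude != 0`.
#' @param spuriousEcho `NULL`, or `list(delay = seconds, amplitude =
#'   relative amplitude)`.
#' @return a classed list of artifact parameters.
#' @export
artifactSpec <- function(phaseDriftSd = 0.04, frequencyDriftSd = 0.4,
                         eddyAmplitude = 0.5, eddyTimeConstant = 0.02,
                         spuriousEcho = NULL) {
  stopifnot(phaseDriftSd >= 0, frequencyDriftSd >= 0)
  if (eddyAmplitude != 0 && eddyTimeConstant <= 0)
    stop("eddyTimeConstant must be > 0 when eddyAmplitude != 0")
  structure(
    list(phaseDriftSd = phaseDriftSd, frequencyDriftSd = frequencyDriftSd,
         eddyAmplitude = eddyAmplitude, eddyTimeConstant = eddyTimeConstant,
         spuriousEcho = spuriousEcho),
    class = "ArtifactSpec"
  )
}

#' Cohort-level simulation parameters
#'
#' Defaults emulate the study design: 10 subjects with 3 consecutive
#' measurements each, 32 edit-on and 32 edit-off transients plus one water
#' reference per measurement, 8 receive coils with graded complex
#' sensitivities and weakly correlated noise. All randomness derives from
#' `seed`; re-running with the same seed reproduces the cohort bit-exactly.
#'
#' @param nSubjects,nMeasurements cohort design.
#' @param nOn,nOff transient counts per measurement.
#' @param nCoils number of receive coils.
#' @param betweenSubjectCv coefficient of variation of the per-subject
#'   amplitude factor applied to the edited (GABA+) resonances; this is the
#'   between-subject CV of the true GABA+/tCr ratio.
#' @param noiseSd per-coil noise s.d. (each of real and imaginary part, per
#'   time sample). The default is calibrated so that the default
#'   hippocampal cohort reaches an off-spectrum NAA SNR in the low 40s.
#' @param coilSensitivities complex vector of per-coil sensitivities;
#'   default: moduli declining from 1 to 0.6 with evenly spread phases.
#' @param noiseCorrelation Hermitian positive-definite coil noise
#'   correlation; default: compound symmetry with off-diagonal 0.1.
#' @param waterAmplitude unsuppressed water amplitude (metabolite units).
#' @param residualWaterFraction fraction of `waterAmplitude` surviving
#'   water suppression.
#' @param axis the shared [SpectralAxis-class].
#' @param seed integer seed fixing the whole cohort.
#' @return a classed list of cohort parameters.
#' @export
cohortSpec <- function(nSubjects = 10L, nMeasurements = 3L,
                       nOn = 32L, nOff = 32L, nCoils = 8L,
                       betweenSubjectCv = 0.05, noiseSd = 3,
                       coilSensitivities = NULL, noiseCorrelation = NULL,
                       waterAmplitude = 12000, residualWaterFraction = 0.01,
                       axis = spectralAxis(2048L, 1 / 4000), seed = 1L) {
  stopifnot(nSubjects >= 1, nMeasurements >= 1, nOn >= 1, nOff >= 1,
            nCoils >= 1, betweenSubjectCv >= 0, noiseSd >= 0)
  if (is.null(coilSensitivities)) {
    mods <- seq(1, 0.6, length.out = nCoils)
    coilSensitivities <- mods * exp(2i * pi * (seq_len(nCoils) - 1) / nCoils)
  }
  if (is.null(noiseCorrelation)) {
    noiseCorrelation <- matrix(0.1, nCoils, nCoils)
    diag(noiseCorrelation) <- 1
  }
  stopifnot(length(coilSensitivities) == nCoils,
            all(dim(noiseCorrelation) == c(nCoils, nCoils)))
  ev <- eigen(noiseCorrelation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noiseCorrelation must be positive definite")
  structure(
    list(nSubjects = as.integer(nSubjects),
         nMeasurements = as.integer(nMeasurements),
         nOn = as.integer(nOn), nOff = as.integer(nOff),
         nCoils = as.integer(nCoils),
         betweenSubjectCv = betweenSubjectCv, noiseSd = noiseSd,
         coilSensitivities = coilSensitivities,
         noiseCorrelation = noiseCorrelation,
         waterAmplitude = waterAmplitude,
         residualWaterFraction = residualWaterFraction,
         axis = axis, seed = as.integer(seed)),
    class = "CohortSpec"
  )
}

#' True GABA+/tCr ratio implied by a resonance table
#'
#' The numerator sums, over rows with role `"gabaplus"`, the amplitude each
#' contributes to the noise-free difference spectrum (twice the amplitude for
#' `inverted` rows, once for `co_edited`); the denominator is the summed
#' amplitude of the `"tcr"` rows in the edit-off spectrum.
#'
#' @param resonances a resonance table.
#' @param factors optional per-row amplitude factors.
#' @return the ratio as a plain number.
#' @export
trueGabaTcr <- function(resonances, factors = NULL) {
  if (is.null(factors)) factors <- rep(1, nrow(resonances))
  diffCoeff <- .editSign(resonances$editBehavior, "on") -
    .editSign(resonances$editBehavior, "off")
  num <- sum((abs(diffCoeff) * resonances$amplitude * factors)[
    resonances$role %in% "gabaplus"])
  den <- sum((resonances$amplitude * factors)[resonances$role %in% "tcr"])
  if (den <= 0) stop("resonance table has no tcr role amplitude")
  num / den
}

#' Draw the per-subject ground-truth amplitude factors of a cohort
#'
#' One log-normal factor with mean 1 and coefficient of variation
#' `betweenSubjectCv` is drawn per subject and applied to the rows flagged
#' `subjectVaries` (the edited GABA+ resonances); each subject's repeated
#' measurements share the factor. Uses the current RNG state.
#'
#' @param cohort a [cohortSpec()].
#' @param resonances a resonance table.
#' @return list with `factors` (matrix subjects x resonance rows) and
#'   `trueRatio` (per-subject GABA+/tCr).
#' @export
drawCohortTruth <- function(cohort, resonances) {
  cv <- cohort$betweenSubjectCv
  sdlog <- sqrt(log(1 + cv^2))
  subjFac <- if (cv > 0) {
    stats::rlnorm(cohort$nSubjects, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, cohort$nSubjects)
  factors <- matrix(1, cohort$nSubjects, nrow(resonances),
                    dimnames = list(NULL, resonances$name))
  factors[, resonances$subjectVaries] <- subjFac
  trueRatio <- vapply(seq_len(cohort$nSubjects), function(s)
    trueGabaTcr(resonances, factors[s, ]), numeric(1))
  list(factors = factors, trueRatio = trueRatio)
}

#' Simulate one measurement as a [TransientSet-class] with ground truth
#'
#' Emits the water reference followed by the interleaved on/off transient
#' stream. Each water-suppressed transient is the clean edit-state FID,
#' scaled per coil by its sensitivity, modulated by the accumulated
#' phase/frequency drift and the shared eddy-current phase, plus correlated
#' complex Gaussian noise. The water reference carries the same eddy phase
#' (no drift) and the unsuppressed water resonance.
#'
#' @param cohort a [cohortSpec()].
#' @param resonances resonance table (see [defaultResonanceTable()]).
#' @param artifacts an [artifactSpec()].
#' @param subject,measurement identifiers stored in the set.
#' @param amplitudeFactors optional per-row amplitude factors (one subject
#'   row of [drawCohortTruth()]).
#' @param seed optional integer; when given, `set.seed` is called first so
#'   the set is bit-reproducible in isolation.
#' @return `list(set = TransientSet, truth = list(...))`; `truth` records
#'   the applied per-transient phase/frequency offsets, the eddy phase
#'   parameters, the amplitude factors and the true GABA+/tCr ratio.
#' @export
simulateTransientSet <- function(cohort, resonances = defaultResonanceTable(),
                                 artifacts = artifactSpec(),
                                 subject = "S01", measurement = 1L,
                                 amplitudeFactors = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  axis <- cohort$axis
  n <- axis@nPoints
  t <- timeScale(axis)
  nc <- cohort$nCoils
  if (is.null(amplitudeFactors)) amplitudeFactors <- rep(1, nrow(resonances))

  onClean <- .cleanFid(resonances, axis, "on", amplitudeFactors)@samples
  offClean <- .cleanFid(resonances, axis, "off", amplitudeFactors)@samples

  # unsuppressed water: scale the residual water row up to full amplitude
  ih2o <- which(resonances$name == "h2o")
  waterClean <- offClean
  if (length(ih2o) == 1L) {
    h2oFid <- makeBasisFid(resonances$center[ih2o], axis,
                           amplitude = resonances$amplitude[ih2o],
                           lorentzian = resonances$lorentzian[ih2o],
                           gaussian = resonances$gaussian[ih2o])@samples
    waterClean <- waterClean +
      (1 / cohort$residualWaterFraction - 1) * h2oFid *
      (cohort$waterAmplitude * cohort$residualWaterFraction /
         resonances$amplitude[ih2o])
  }

  eddyPhase <- if (artifacts$eddyAmplitude != 0) {
    artifacts$eddyAmplitude * exp(-t / artifacts$eddyTimeConstant)
  } else rep(0, n)
  eddyMod <- exp(1i * eddyPhase)

  nt <- cohort$nOn + cohort$nOff
  states <- rep(c("on", "off"), length.out = nt)  # interleaved acquisition
  phi <- cumsum(stats::rnorm(nt, 0, artifacts$phaseDriftSd))
  frq <- cumsum(stats::rnorm(nt, 0, artifacts$frequencyDriftSd))

  echo <- NULL
  if (!is.null(artifacts$spuriousEcho)) {
    se <- artifacts$spuriousEcho
    env <- exp(-((t - se$delay)^2) / (2 * (0.004)^2))
    echo <- se$amplitude * max(Mod(offClean)) * env *
      exp(2i * pi * ppmToOffsetHz(1.3, axis) * t)
  }

  R <- chol(cohort$noiseCorrelation)
  drawNoise <- function() {
    re <- matrix(stats::rnorm(n * nc), n, nc) %*% R
    im <- matrix(stats::rnorm(n * nc), n, nc) %*% R
    cohort$noiseSd * (re + 1i * im)
  }

  data <- array(0i, dim = c(n, nc, nt + 1L))
  # water reference first: eddy phase, no drift
  wBase <- waterClean * eddyMod
  data[, , 1L] <- outer(wBase, cohort$coilSensitivities) + drawNoise()
  for (j in seq_len(nt)) {
    clean <- if (states[j] == "on") onClean else offClean
    base <- clean * exp(1i * phi[j] + 2i * pi * frq[j] * t) * eddyMod
    if (!is.null(echo)) base <- base + echo
    data[, , j + 1L] <- outer(base, cohort$coilSensitivities) + drawNoise()
  }

  set <- transientSet(data, c("water_reference", states), axis,
                      subjectId = subject, measurementIndex = measurement)
  truth <- list(
    subject = subject, measurement = measurement,
    amplitudeFactors = stats::setNames(amplitudeFactors, resonances$name),
    drift = data.frame(transient = seq_len(nt) + 1L, state = states,
                       phase = phi, frequency = frq),
    eddy = list(amplitude = artifacts$eddyAmplitude,
                timeConstant = artifacts$eddyTimeConstant),
    trueRatio = trueGabaTcr(resonances, amplitudeFactors)
  )
  list(set = set, truth = truth)
}

#' Simulate a full cohort
#'
#' Seeds the RNG from `cohort$seed`, draws the per-subject amplitude factors
#' once (shared by each subject's repeated measurements), then simulates
#' every (subject, measurement) as a [simulateTransientSet()].
#'
#' @param cohort a [cohortSpec()].
#' @param resonances resonance table.
#' @param artifacts an [artifactSpec()].
#' @return list with `sets` (named `"S01_m1"`, ...), `truth` (per-set ground
#'   truth in matching order), `subjectTruth` (from [drawCohortTruth()]) and
#'   `spec`/`resonances`/`artifacts` echoes; a `manifest` data.frame lists
#'   one row per set.
#' @export
simulateCohort <- function(cohort = cohortSpec(),
                           resonances = defaultResonanceTable(),
                           artifacts = artifactSpec()) {
  set.seed(cohort$seed)
  subjectTruth <- drawCohortTruth(cohort, resonances)
  sets <- list()
  truth <- list()
  manifest <- NULL
  for (s in seq_len(cohort$nSubjects)) {
    sid <- sprintf("S%02d", s)
    for (m in seq_len(cohort$nMeasurements)) {
      key <- sprintf("%s_m%d", sid, m)
      sim <- simulateTransientSet(cohort, resonances, artifacts,
                                  subject = sid, measurement = m,
                                  amplitudeFactors = subjectTruth$factors[s, ])
      sets[[key]] <- sim$set
      truth[[key]] <- sim$truth
      manifest <- rbind(manifest, data.frame(
        key = key, subject = sid, measurement = m,
        trueRatio = sim$truth$trueRatio, stringsAsFactors = FALSE))
    }
  }
  list(sets = sets, truth = truth, subjectTruth = subjectTruth,
       manifest = manifest, spec = cohort, resonances = resonances,
       artifacts = artifacts)
}
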