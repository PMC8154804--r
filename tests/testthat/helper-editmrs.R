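# Shared fixtures: small axes and cohorts sized for fast tests, plus
# independent oracles (a minimal jMRUI parser and a numeric linewidth
# measurement) that deliberately do not reuse package internals.

testAxis <- function(n = 1024L) spectralAxis(n, 1 / 4000)

tinyCohort <- function(..., seed = 1L) {
  cohortSpec(nSubjects = 1L, nMeasurements = 1L, nOn = 8L, nOff = 8L,
             nCoils = 1L, noiseSd = 0, axis = testAxis(), seed = seed, ...)
}

noArtifacts <- function() artifactSpec(0, 0, 0, 0.02)

# numeric FWHM oracle: spline-free linear interpolation on a heavily
# zero-filled magnitude-independent rendering of a time-domain signal
oracleFwhmHz <- function(samples, dwell, zf = 16L) {
  n <- length(samples) * zf
  sp <- Re(stats::fft(c(samples, complex(length.out = n - length(samples)))))
  f <- (seq_len(n) - 1) / (n * dwell)
  f[f >= 1 / (2 * dwell)] <- f[f >= 1 / (2 * dwell)] - 1 / dwell
  ord <- order(f)
  f <- f[ord]; sp <- sp[ord]
  i0 <- which.max(sp)
  half <- sp[i0] / 2
  xs <- approx(sp[1:i0], f[1:i0], xout = half, ties = "ordered")$y
  right <- seq(i0, length(sp))
  xr <- approx(rev(sp[right]), rev(f[right]), xout = half, ties = "ordered")$y
  xr - xs
}

# independent minimal jMRUI text parser (regex based, no package code)
oracleReadJmrui <- function(path) {
  txt <- readLines(path)
  val <- function(key) {
    ln <- grep(paste0("^", key, ":"), txt, value = TRUE)[1]
    trimws(sub("^[^:]*:", "", ln))
  }
  n <- as.integer(val("PointsInDataset"))
  k <- as.integer(val("DatasetsInFile"))
  starts <- grep("^Signal [0-9]+ out of", txt)
  sig <- lapply(starts, function(s) {
    rows <- do.call(rbind, strsplit(trimws(txt[(s + 1):(s + n)]), "\t"))
    complex(real = as.numeric(rows[, 1]), imaginary = as.numeric(rows[, 2]))
  })
  list(n = n, k = k, signals = sig,
       samplingIntervalMs = as.numeric(val("SamplingInterval")),
       transmitterHz = as.numeric(val("TransmitterFrequency")))
}

# wrap an angle difference into (-pi, pi]
angDiff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  d
}
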