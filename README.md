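# editMRS

Quantifying the inhibitory neurotransmitter GABA in vivo is hard: its
signal is weak and buried under creatine and other resonances.
J-difference editing (MEGA-sLASER and related sequences) isolates it by
subtracting interleaved acquisitions with the editing pulse on resonance
(1.9 ppm, *edit-on*) and mirrored about water (7.5 ppm, *edit-off*), so
that only J-coupled partners such as the GABA 3.0 ppm multiplet — plus a
co-edited macromolecular contribution, together "GABA+" — survive. The
subtraction is exquisitely sensitive to instability: per-transient
frequency/phase drift turns creatine into a spurious 3.0 ppm residual that
masquerades as GABA, and residual eddy currents distort the early FID. In
regions with severe B0 inhomogeneity (the hippocampus, with ~23 Hz
linewidths at 7 T) these effects dominate the reproducibility of the
measurement.

**editMRS** implements a complete, tested analysis chain for such data,
for MRS methods developers and analysts who want a reproducible, scripted
pipeline with a validated synthetic test bed:

* **Synthetic cohorts with ground truth** — multi-coil, multi-transient
  edit-on/edit-off FID simulation (drift random walks, eddy-current phase,
  coil sensitivities with correlated noise, between-subject variation,
  optional spurious echoes), with every injected parameter recorded.
* **Preprocessing** — noise-correlation weighted coil combination
  (`w = N^-1 s`), eddy-current compensation (ECC) by water-reference phase
  deconvolution, time-domain spectral registration (SR) of each transient
  `A_j(t) e^{i phi_j + 2 pi i f_j t}` to the edit-off mean by exact
  least squares, and difference-artifact suppression (DAS, band-limited to
  2.8–3.5 ppm) or difference optimization (DO) before subtraction — the
  six tested routines SR, ECC+SR, SR+DAS, ECC+SR+DAS, SR+DO, ECC+SR+DO
  plus a plain-averaging baseline.
* **Quantification** — a linear-combination model fitter with Voigt
  lineshapes: non-negative basis amplitudes nested inside a
  Levenberg–Marquardt optimization of global phase, frequency, Gaussian
  damping `beta` and per-entry Lorentzian dampings, with Cramér–Rao lower
  bounds, NAA linewidth/SNR quality metrics and the GABA+/tCr ratio.
* **Reproducibility analysis** — intra-session and inter-subject
  coefficients of variation and the two-step optimization of the
  quantification parameters (`beta_s` first, then the FID start-point pair
  `n_s`) over a grid, with median and first-decile summaries per
  preprocessing routine.
* **Interchange** — a plain-text jMRUI reader/writer, YAML run
  configurations and a staged command-line entry point
  (`inst/scripts/mrs-pipeline.R`).

## Worked example

```r
library(editMRS)

cohort <- simulateCohort(
  cohortSpec(nSubjects = 2, nMeasurements = 3, nOn = 16, nOff = 16,
             nCoils = 4, axis = spectralAxis(1024, 1/4000), seed = 42))

set1 <- cohort$sets[["S01_m1"]]
set1
#> TransientSet: subject S01, measurement 1; 4 coil(s); 16 on / 16 off / 1 water
#> SpectralAxis: 1024 points, dwell 0.25 ms (sw 4000 Hz), 297.2 MHz, carrier at 4.7 ppm

combined <- combineCoils(set1, estimateCoilWeights(set1))
pair <- runPipeline(combined, "ECC+SR+DAS")
q <- quantifyPair(pair, beta = 1500, nsDiff = 3, nsOff = 4)
round(c(gaba_tcr = q$ratio, true = cohort$truth[["S01_m1"]]$trueRatio,
        fwhm_hz = q$fwhm$hz, snr_off = q$snrOff,
        gaba_crlb_pct = q$gabaCrlb), 3)
#>      gaba_tcr          true       fwhm_hz       snr_off gaba_crlb_pct
#>         0.205         0.214        23.095        30.242        14.189
```

The fitted GABA+/tCr ratio (0.205) recovers this subject's simulated truth
(0.214) within the precision the CRLB predicts (14% of the estimate); the
fitted NAA linewidth (23.1 Hz) reflects the hippocampal lineshape the
simulator is tuned to. Repeating the quantification over all six
measurements and summarizing per subject:

```r
ratios <- sapply(names(cohort$sets), function(k) {
  s <- cohort$sets[[k]]
  sc <- combineCoils(s, estimateCoilWeights(s))
  quantifyPair(runPipeline(sc, "ECC+SR+DAS"), beta = 1500,
               nsDiff = 3, nsOff = 4)$ratio
})
tab <- data.frame(subject = substr(names(ratios), 1, 3), ratio = ratios)
round(100 * mCovIntra(tab, 3), 1)   # mean intra-session CoV, percent
#> [1] 13.8
```

At this deliberately small demo scale (16+16 transients, 4 coils) the
intra-session CoV is 13.8%; the full-size default cohort (32+32
transients, 8 coils) reaches a few percent. `comparePipelines()` runs the
entire variant-by-grid comparison and both optimization steps in one call
and returns an `OptimizationReport`.

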