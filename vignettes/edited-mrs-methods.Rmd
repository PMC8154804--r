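---
title: "Models and methods behind editMRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind editMRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(editMRS)
```

This vignette explains the models the package implements, the choices
made where the design was genuinely open, and what validation on the
synthetic test bed does and does not demonstrate about real data.

## Coordinates and conventions

A `SpectralAxis` fixes time and frequency coordinates: sample `k`
(0-based) of an FID lies at `t = k * dwellTime`; the spectral width is
`1/dwellTime`. Chemical shift follows the standard display convention:
the transmitter (carrier) sits on water at 4.7 ppm and ppm increases as
the frequency offset decreases, so a resonance at `delta` ppm has carrier
offset `(4.7 - delta) * f0` Hz. The default transmitter frequency is
297.2 MHz, the proton frequency at 7 T; with it, linewidths of 23.1,
22.7 and 29.3 Hz convert to 0.078, 0.076 and 0.099 ppm at
three-decimal rounding, which pins the choice. The default axis (4 kHz
width) resolves the 2.8-3.5 ppm editing band with more than 200 bins.

## The synthetic cohort generator

The generator's role is to emulate the *statistical structure* the
analysis pipeline assumes, with every injected quantity recorded, so that
each processing step can be tested against ground truth.

**Spectrum model.** Each resonance is a damped complex exponential
`a * exp(2 pi i df t - alpha t - gamma t^2)`: a Voigt line with
Lorentzian damping `alpha` (1/s; spectral FWHM `alpha/pi`) and Gaussian
damping `gamma` (1/s^2; FWHM `2 sqrt(gamma ln 2)/pi`). All metabolites
carry a 5 Hz Lorentzian component; the region sets the shared Gaussian
term — 1451.6 /s^2 for the hippocampus and 118.8 /s^2 for the posterior
cingulate cortex (PCC), solving the Voigt width relation so the NAA
linewidth is ~23 Hz and ~8.9 Hz respectively, the two regimes of interest
(severe vs benign B0 inhomogeneity).

**Editing.** Editing is phenomenological, not a density-matrix
simulation: each resonance carries one of three behaviors. `off_only`
lines (NAA, creatine, choline, myo-inositol, Glx, residual water) appear
identically in both edit states and cancel in the difference; `co_edited`
lines (the 3.0 ppm macromolecule, Glx at 3.75 ppm, resonances at 2.5 and
2.7 ppm) appear in the edit-on state only and survive; `inverted` lines
(the GABA pseudo-doublet, two equal singlets at 2.95 and 3.05 ppm) flip
sign between states and double in the difference. "GABA+" is the doublet
plus the broader (25 Hz Lorentzian) macromolecule. The ground-truth
GABA+/tCr ratio counts each row's contribution to the difference (twice
the amplitude for inverted rows) over the 3.03 ppm creatine amplitude;
with the default table it is 0.2.

**Artifacts.** Phase and frequency drift are independent Gaussian random
walks across the interleaved on/off transient stream (defaults 0.04
rad and 0.4 Hz per transient; no published values exist for these
magnitudes, so they are configuration, not measurement). Residual eddy
currents add the phase `A exp(-t/tau)` (defaults 0.5 rad, 20 ms) to every
transient of a measurement *including the water reference* — the
assumption ECC exploits, and an invariant of the generator. An optional
spurious echo adds a delayed damped oscillation.

**Water.** The resonance table carries the VAPOR-suppressed residual
water line at ten times the NAA amplitude, a typical in vivo residual;
the unsuppressed water reference rescales it by `1/residualWaterFraction`
(default 100x, i.e. 1000x the metabolite concentration scale). The
residual water matters: it dominates per-transient energy and is what
anchors spectral registration at realistic single-transient SNR.

**Noise and coils.** Per-coil complex Gaussian noise is correlated across
coils (compound symmetry 0.1 by default) and scaled by `noiseSd`; coil
sensitivities decline in modulus from 1 to 0.6 with evenly spread phases.
`noiseSd = 3` is calibrated so the default hippocampal cohort (32+32
transients, 8 coils, 2048 points) yields an off-spectrum NAA SNR in the
mid 40s, the reported scale for such data; linewidth and SNR are the two
quantities the simulator is explicitly tuned to.

**Between-subject variation** is one log-normal factor (mean 1, CV 5% by
default) per subject applied to the edited GABA+ rows and shared by the
subject's repeated measurements. Placing the variation on the numerator
only makes the nominal CV equal the CV of the true ratio, which is the
quantity the inter-subject statistics estimate; denominator variation
would confound that correspondence without adding anything the pipeline
is sensitive to.

**What the generator does not emulate:** J-evolution and multiplet
structure (all lines are singlets or pseudo-doublets), realistic B0 field
maps or frequency-dependent lineshape distortion, lipid contamination,
motion, and scanner-specific drift shapes (real drift is partly monotonic
heating, not a random walk). Passing tests therefore demonstrate the
pipeline's correctness and statistical behavior under the assumed
artifact model, not performance on arbitrary in vivo data.

## Preprocessing

**Coil combination.** The per-coil water amplitude `s` is the mean of the
first 4 water-reference samples; the coil noise covariance `N` is the
sample covariance of the final quarter of every water-suppressed FID.
Weights `w = N^-1 s` (the whitened matched filter) make the combined
water signal real and positive at `t = 0`; the combined transient is the
conjugate-weighted sum. A numerically singular `N` falls back to its
diagonal with a warning. The estimator windows (4 leading samples, 25%
tail) are package choices; no canonical values exist.

**Eddy-current compensation** multiplies each FID by `exp(-i phi_w(t))`
with `phi_w` the unwrapped phase of the coil-combined water reference.
Because the eddy phase is common to water and metabolite acquisitions,
the correction is exact in the noise-free case. Beyond the sample where
the water magnitude falls under 5 noise standard deviations (estimated
from the final 10% of the water FID) the phase is held at its last
reliable value rather than extrapolated.

**Spectral registration** aligns each water-suppressed transient to the
mean of all edit-off transients (the literal processing convention; a
`per_state` mode aligning edit-on transients to their own mean is
provided, since aligning structurally different on-transients to the
off mean imposes a small constant phase pull). The two-parameter
least-squares problem is solved *exactly*: for fixed frequency `f` the
optimal phase is `Arg(H(f))` with `H(f) = sum Conj(x) r exp(-2 pi i f t)`,
so the objective reduces to maximizing `|H|`, the DTFT magnitude of
`Conj(x) * r`; a zero-padded FFT scans it within the +-20 Hz bound and
golden-section search refines the best bin. This replaces the iterative
Levenberg-Marquardt approach originally considered: with the large
structural residual of on-vs-off alignment, joint LM descent crawls along
a shallow phase/frequency valley for hundreds of iterations, while the
projected solver is global, exact and has no convergence failures. The
misfit uses the first 400 ms of the FID; for short-T2* signals the tail
is noise and the choice is uncritical because the signal weights itself
in the objective.

**Difference-artifact suppression (DAS)** band-limits the averaged
edit-on and edit-off signals to 2.8-3.5 ppm by hard spectral masking and
runs the same alignment on the pair, applying the correction to the full
edit-on average. One numerical subtlety is documented in `?dasAlign`:
the masked signals are circular DFT-grid objects, so the full-record
objective is insensitive to *sub-bin* frequency offsets of broad
(hippocampal) lines — the frequency term carries well under a percent of
the band energy — and the correction is dominated by its precisely
estimated phase component. That is also the practically better behavior:
on noisy cohorts a freely estimated frequency adds jitter without
reducing the artifact. A `window` argument restricts the misfit to the
early FID where sub-bin information survives, which the test suite uses
for the creatine-only frequency-recovery check.

**Difference optimization (DO)** minimizes instead the L1 norm of the
magnitude of the difference spectrum over the same band — the residual
subtraction artifact itself. This is a reconstruction from a brief
published description and is flagged approximate. The non-smooth
objective is nearly flat in frequency near its optimum, so Nelder-Mead
is started from the DAS (L2) solution; corrections of the two methods
agree closely on realistic cohorts, which the suite checks.

**Variants.** `runPipeline()` applies, in order: ECC per transient,
spectral registration, state averaging, DAS or DO, subtraction. DAS/DO
require SR (they are defined on SR-corrected averages); the `plain`
variant (nothing but averaging) is the baseline. `processMeasurement()`
shares ECC and SR results across variants, so all seven cost about two
registrations.

## Quantification

The fitter models the FID from sample `n_s` on as

```
M(t) = exp(i phi + 2 pi i df t - beta t^2) * sum_m a_m exp(-alpha_m t) B_m(t)
```

with non-negative amplitudes `a_m`, a global zero-order phase, frequency
shift (bounded at +-20 Hz) and Gaussian damping `beta` (initialized at
the tuning parameter `beta_s`, in 1/s^2), and one excess Lorentzian
damping per entry (initialized at 2 /s, bounded above by 150 /s — excess
broadening beyond ~50 Hz is not physical when the Gaussian term carries
the shim-induced width). This is a deliberately simplified
linear-combination model: no spline baseline and no soft constraints;
baseline handling is via the start point `n_s` alone, so the two knobs
under study are exactly the model's degrees of freedom, and the
"baseline-corrected fit" in the SNR definition is the metabolite model
itself.

**Basis sets** are built from the resonance table. Entries carry each
resonance's intrinsic Lorentzian decay (the way simulated metabolite
bases carry lineshape), grouped by amplitude group: the GABA pseudo-
doublet is one entry (one amplitude), and signs reflect the edit state —
the edit-off basis contains the doublet with negative sign (as it appears
there), the difference basis with its doubled coefficient. A fitted
amplitude times the entry's coefficient L1 norm is the signal area it
contributes, which makes fitted and ground-truth GABA+/tCr directly
comparable. The edit-off basis includes the residual water line; the
difference basis instead assumes water removal (below) but keeps NAA,
whose difference coefficient is zero, as a guard entry.

**Numerics.** Amplitudes are projected out by non-negative least squares
at every step (variable projection), using a Lawson-Hanson active-set
solver on the normal equations — the design has at most eight well-
conditioned columns, and a full-design NNLS per iteration dominated the
runtime; agreement with `pracma::lsqnonneg` is covered by the tests. The
outer Levenberg-Marquardt run (`minpack.lm`, tolerances 1e-9, maximum
200 iterations) uses a Kaufman-style approximate Jacobian (amplitudes
held at their projected values) and references the global frequency ramp
to the data's energy centroid, without which phase and frequency are
nearly collinear for fast-decaying signals and convergence crawls.
Non-convergence returns the best iterate with a warning; an all-zero
input is an error; `n_s` may not exceed a quarter of the record.

**Residual water in the difference.** Subtraction artifacts of the large
residual water line carry arbitrary phase and cannot be represented by a
non-negative amplitude on a zero-phase basis entry; left in place they
can drag the global phase of the whole difference fit. Difference signals
are therefore band-stop filtered at 4.2-5.2 ppm (`removeWaterBand()`)
before fitting, a standard residual-water removal step; exact-model
recovery tests disable it, since a clean difference holds no water.

**CRLB.** The Fisher information is `Re(J^H J)/sigma^2` over the fitted
samples, with `J` spanning amplitude columns and the nonlinear parameters
of entries with positive amplitude, and `sigma^2` estimated from the
final 10% of the fitted residual; the bound is the marginal one (inverse
of the full information matrix), reported as percent of each amplitude.
Entries with zero amplitude, or a singular information matrix, report an
infinite bound. A `shapeKnown` option restricts the information to the
amplitudes, which is what a closed-form single-resonance oracle checks.

**Quality metrics.** The NAA linewidth is the interpolated FWHM of the
real spectrum of the fitted NAA component on a four-fold zero-filled
grid. SNR divides the peak of the fitted model spectrum (NAA region for
the edit-off fit; the edited 3.0 ppm region for the difference fit, which
contains no NAA under the three-behavior edit model) by twice the RMS of
the real data spectrum over the resonance-free 8.5-10.5 ppm span. The
first time-domain sample is halved before these DFTs — the standard
correction for the offset a causal FID otherwise spreads across the
spectrum, which would dominate the noise span. The GABA+/tCr ratio is the
edited area (GABA group plus macromolecule) over the 3.03 ppm creatine
area; no editing-efficiency or relaxation calibration is applied, since
constant factors cancel in every coefficient of variation.

## Reproducibility statistics and parameter optimization

The intra-session CoV is the sample standard deviation over the mean of
one subject's repeated-measurement ratios; its mean over subjects
(`mCovIntra`) is the repeatability metric. Subjects with a failed fit at
a grid point are excluded pairwise with a warning. The inter-subject CoV
is computed per measurement index (the CoV across subjects of that
index's ratios) and summarized as the mean and standard deviation of the
three per-index values — the convention chosen because it is the one that
yields an error bar; averaging subject means first would not.

The parameter grid defaults to 10 `beta_s` values spanning 200-5000
1/s^2 and 13 `n_s` values spanning 1-50 (169 pairs), including the
endpoints of the studied ranges. Optimization is two-step: first, for
each `beta_s`, the median `mCovIntra` over all pairs is computed for the
standard (SR) and advanced (ECC+SR+DAS) routines and the `beta_s`
minimizing their average is chosen (ties to the smaller value); then, at
that `beta_s`, the pair minimizing the median over the six routines is
chosen (ties to the smaller difference start point, then the off one).
Both steps are checked against brute-force loop implementations in the
tests, and both are invariant to row order. The per-variant "first
decile" summary is the 10th percentile (linear interpolation) of the
grid's mCoV values — the boundary of the best tenth under a
lower-is-better metric.

`comparePipelines()` exploits the factorization of the pair grid: the
difference fit depends only on `n_s,diff` and the off fit only on
`n_s,off`, so a 13x13 pair grid costs 13+13 fits per measurement, not
169.

## Problem sizes used in validation

The test suite and acceptance script are sized for a single CPU: unit
tests run on 512-1024-point axes with 8-32 transients and 1-8 coils;
property checks use 10-50 fixed seeds per claim. The acceptance run uses
the full default cohort (10 subjects x 3 measurements, 32+32 transients,
8 coils, 2048 points) with a reduced grid of 3 `beta_s` x 4 `n_s`
values, completing in a few minutes. The qualitative re-enactments set
their artifact levels explicitly: strong eddy currents (2 rad, 20 ms)
for the start-point bias experiment, and heavy drift (0.08 rad / 0.8 Hz
per transient) for the variant-ordering experiment, where plain
averaging must fail; the interleaved acquisition order protects plain
averaging almost completely against *symmetric random-walk* drift at the
default magnitudes, which is one respect in which the generator is
kinder than a scanner.

## Known limitations

* Editing is sign-based; co-edited multiplet shapes and J-evolution are
  not modeled, so difference-spectrum SNR of NAA (which cancels here but
  not in vivo) is not reproducible, and the 2.5/2.7 ppm entries are
  placeholders with nominal amplitudes.
* The DO objective is a reconstruction from a name and a one-line
  description; only its agreement with DAS is validated.
* DAS frequency corrections are insensitive to sub-bin offsets of broad
  lines (see above); in practice the phase term dominates.
* Under the off-mean registration convention, aligning the structurally
  different edit-on average to the edit-off average pulls a small constant
  phase into the difference (on the order of 0.05 rad with the default
  table), which offsets the fitted GABA+/tCr ratio of the DAS/DO variants
  by a constant factor. The offset is shared by all subjects and
  measurements and cancels in every coefficient of variation — the
  quantities these variants are meant to improve — but DAS/DO ratios
  should not be compared in absolute terms against non-DAS variants.
* The fitter's positivity constraint induces a small upward bias of the
  edited area at low SNR (a few percent at the calibrated conditions,
  quantified in the acceptance suite); absolute quantification,
  tissue-fraction correction and macromolecule-nulled fitting are out of
  scope.
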