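---
title: "Modeling ultrafast photocycles: global analysis, trace fitting and FSRS processing with ultrafastSpec"
author: "ultrafastSpec maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ultrafast photocycles with ultrafastSpec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultrafastSpec)
```

## The scientific problem

Femtosecond transient absorption (fs-TA) records a differential absorbance
surface ΔA(t, λ) — delay times from below 100 fs out to the nanosecond range
against probe wavelength — after a short actinic pump pulse. For photoactive
proteins such as green–red calcium biosensors, this surface superimposes
ground-state bleach (GSB, negative), excited-state absorption (ESA,
positive) and stimulated emission (SE, negative) bands whose overlapping
kinetics encode the photocycle: excited-state proton transfer (ESPT) from
the protonated chromophore, chromophore twisting into non-emissive dark
states, and ground-state recovery. Femtosecond stimulated Raman spectroscopy
(FSRS) adds a structural axis: time-resolved vibrational marker bands whose
intensities track the same populations.

`ultrafastSpec` implements the full analysis chain for such data:

* compartmental photocycle models with analytic instrument-response
  convolution (`buildSequential`, `buildTarget`, `solveConcentrations`);
* variable-projection global analysis returning evolution- and
  decay-associated difference spectra, EADS and DADS (`fitGlobal`), with
  model-order scanning (`scanComponents`);
* probe-band trace extraction and IRF-convolved multi-exponential fits with
  rise/decay classification and percentage weights (`integrateBand`,
  `fitMultiexp`, `weightedAverageTau`);
* FSRS axis conventions, spline baseline subtraction, Gaussian peak fitting
  and marker-band dynamics (`normalizeShiftAxis`, `fitBaseline`,
  `fitPeaks`, `peakTrace`);
* steady-state band metrics: Stokes shifts, band ratios, isosbestic-point
  detection and two-state titration decomposition;
* a synthetic-data generator (`simulateTA`, `simulateFSRS`,
  `simulateTitration`, plus `caBoundPreset`/`caFreePreset`) that provides
  realistic, seeded test data so the entire chain is verifiable without
  instrument data.

## The kinetic model

Populations of a compartmental scheme obey first-order kinetics,
\(\dot c = K c\), with a rate matrix in column-to-row convention: entry
\((i, j)\) is the rate of \(j \to i\) flow (1/ps) and each diagonal entry
closes its column, equalling minus the species' total outflow including
return to the unobserved ground-state "sink". Excitation is not
instantaneous: the pump–probe cross-correlation is modeled as a unit-area
Gaussian of FWHM \(w\) (default 140 fs, a typical value for a
prism-compressed 400 nm pump with a white-light probe) centered at time zero
\(t_0\). The population response to Gaussian excitation is the convolution

\[
c_k(t) = \tfrac12\,
  \exp\!\big(k(\sigma^2 k/2 - (t-t_0))\big)\,
  \operatorname{erfc}\!\Big(\frac{\sigma^2 k - (t-t_0)}{\sigma\sqrt 2}\Big),
\qquad \sigma = \frac{w}{2\sqrt{2\ln 2}},
\]

the exponentially modified Gaussian familiar from fluorescence-decay
analysis. `convolvedExponential` evaluates it through the *scaled*
complementary error function, \(\mathrm{erfcx}\), so the two exponential
factors cancel analytically:

\[
c_k(t) = \tfrac12\,\mathrm{erfcx}(z)\, e^{-(t-t_0)^2/2\sigma^2},
\qquad z = \frac{\sigma k - (t-t_0)/\sigma}{\sqrt 2}.
\]

This form cannot overflow for any \(\sigma^2 k\), which matters when a
model-order scan drives a lifetime toward the femtosecond floor. For
\(z < -6\) (delays far past the IRF) the plain erfc form is used with
\(\operatorname{erfc}(z) \approx 2\), exact to machine precision. A
zero-width IRF returns the step-gated exponential, with the value 1/2
exactly at \(t_0\).

General schemes are solved by eigendecomposition of \(K\): populations are
weighted sums of `convolvedExponential` terms over the eigenrates (the
Bateman closed form generalized to branched topologies). When eigenvalues
are degenerate (an equal-lifetime chain) or complex, `solveConcentrations`
falls back to direct ODE integration with the Gaussian pulse as a source
term. The analytic and numerical routes agree to better than \(10^{-6}\)
population units, which the test suite checks against an independent
Runge–Kutta-plus-numerical-convolution oracle.

## Global analysis: EADS, DADS and variable projection

A time-resolved matrix is modeled as \(D = C(\theta)\,S + E\): a
concentration matrix \(C\) (delays × components) that depends nonlinearly
on lifetimes, IRF and dispersion parameters \(\theta\), and component
spectra \(S\) that enter linearly. `fitGlobal` exploits this structure by
variable projection: at every optimizer step the spectra are eliminated
through a QR least-squares solve, and Levenberg–Marquardt (via
`minpack.lm`) iterates only on \(\theta\), with lifetimes parameterized on
the log scale and bounded in \([1\ \mathrm{fs},\ 10\times\) window\(]\).
For fixed lifetimes the projected spectra are the exact least-squares
optimum, a property the tests verify against a dense normal-equations
solve.

Because the sequential (chain) concentration profiles span the same space
as the parallel exponentials whenever the rates are distinct, the residual
is identical in either basis. The fit therefore runs in the
well-conditioned parallel basis; afterwards the DADS are the projected
coefficients and the EADS follow from the exact Bateman amplitude
transform (`eadsFromDads`/`dadsFromEads`, inverse pair to \(10^{-10}\)).
Both representations reconstruct the identical fitted surface
(\(\le 10^{-9}\) mOD apart); the sequential EADS is the default reported
representation, the standard choice when species evolve along a
photocycle. Coincident lifetimes make the transform singular; they are
perturbed by \(10^{-6}\) (relative) with a warning.

Reported lifetimes are always ascending. The IRF width and time zero can
be fixed or floated (`fitIRF`, `fitT0`); a polynomial dispersion of time
zero along the spectral axis (probe chirp) is fitted only when
`dispersionOrder > 0`, with coefficients expressed in ps per 100 nm
relative to the reddest pixel. The coherent artifact at time zero is *not*
modeled; `maskT0 = TRUE` excludes delays within one IRF FWHM of \(t_0\)
instead.

### Model-order selection

`scanComponents` fits each candidate component count and selects the
smallest converged \(n\) such that adding one more component either

1. improves the RMSE by less than 15% (relative) — chosen because a
   printed-precision RMSE sequence of 0.00127 → 0.00111, a 12.6% drop, is
   the canonical example of an improvement practitioners call
   insignificant — or
2. introduces a lifetime below the sub-IRF rejection floor (IRF FWHM / 2,
   70 fs at the default width), the signature of a fit chasing the
   coherent artifact rather than kinetics.

The per-candidate reasoning is recorded in a selection log. Convergence is
additionally required to be *meaningful*: a candidate whose RMSE stays
within 10% of the raw data RMS has converged onto nothing (this is what a
pure-noise matrix produces, and the scan then raises an error rather than
selecting a model).

One property of this rule is worth stating openly: it keys on relative RMSE
improvement, so a kinetic component whose spectral signature is small
relative to the noise floor — like the intermediate ~71 ps relaxation of
the calcium-bound preset, which moves the band amplitudes by only about
10–15% — can be ruled "insignificant" on noisy data even though it is real.
The calcium-free photocycle, whose intermediate component carries a large
fraction of the signal, is the appropriate demonstration case for the
selection behavior, and the packaged tests use it for exactly that reason.

## Trace dynamics

`integrateBand` averages (not sums) the signal across an integration
window, so traces are invariant to window width and keep their sign.
`fitMultiexp` fits \(I(t) = \sum_i a_i\, c_{1/\tau_i}(t) + b\) by the same
variable-projection scheme, with lifetimes bounded in [10 fs, 10 ns]. The
offset \(b\) is off by default for TA traces — the probe window commonly
truncates the longest component (a 900 ps window cannot resolve a 1.1 ns
tail from a constant), so the longest lifetime absorbs it — and enabled by
request for FSRS traces.

Component weights are absolute-amplitude shares,
\(100\,|a_i| / \sum_j |a_j|\), summing to 100 across rise and decay
components; a component is labeled a **rise** when its amplitude sign
opposes the dominant sign of the trace (for an SE band that is negative
everywhere, a positive-amplitude component deepens the signal).
`weightedAverageTau` returns \(\sum w_i \tau_i / \sum w_i\) over a chosen
subset — e.g. amplitudes weighted 67.9 : 32.1 on 0.35 and 3 ps rises
average to 1.2 ps.

Multi-exponential surfaces are multimodal: a notorious local minimum has
two coalesced lifetimes with huge canceling amplitudes emulating a
\(t e^{-t/\tau}\) shape. When no starting values are given, `fitMultiexp`
runs a small deterministic set of log-spaced starting ladders and keeps the
lowest-RMSE fit, deprioritizing fits flagged with canceling coalesced
pairs. Over-parameterized fits (more components than the data contain)
still end in such flagged minima — by design they are reported, not
hidden, and the component count should be reduced.

## FSRS processing

Stimulated Raman spectra collected on the anti-Stokes side carry a negative
raw shift axis; `normalizeShiftAxis` multiplies it by −1 and re-sorts so
vibrational frequencies read positive (idempotent; mixed-sign axes are
rejected as ambiguous). Wavenumber bookkeeping is exact:
`probeWavelength(650, 1641)` places the probe at
\(10^7/(10^7/650 + 1641) \approx 587.4\) nm, bluer than the pump, which is
also where the SE band of the photoproduct sits — the resonance condition
that makes excited-state FSRS of these biosensors feasible.

Excited-state peaks ride on a broad baseline that essentially mimics the SE
band. `fitBaseline` reproduces the field's manual practice in a
reproducible form: the user declares peak-free anchor windows (at least 4,
spanning toward both grid ends; anchors inside declared peak windows are
an error), a natural cubic spline — C² between knots — is drawn through the
per-window median points, and `subtractBaseline` removes it. Since anchor
placement is an analysis input, the placement used is always part of the
record (the pipeline config). Denser anchor sets track curved baselines
better; the tests demonstrate area recovery within 5% under 1% noise with
seven anchors.

`fitPeaks` then fits all declared Gaussians simultaneously within the
union of per-peak windows (overlapping windows merge so overlapped peaks
are fit jointly), reporting center, FWHM, signed amplitude and area.
Excited-state gain is stored as measured — negative on the anti-Stokes
side — and magnitudes are taken only at reporting. `peakTrace` integrates a
(optionally baseline-subtracted) peak window per delay with the trapezoid
rule, producing the marker-band traces fed to `fitMultiexp`; the
ground-state spectrum can be removed from raw pairs with
`subtractGroundState`.

## Steady-state metrics

`stokesShift` reports \(\lambda_{em} - \lambda_{abs}\) in nm and
\(hc\,(1/\lambda_{abs} - 1/\lambda_{em})\) in eV with \(hc = 1239.84\)
eV·nm; 1240 gives identical values at the 2-decimal reporting precision,
and the tests assert both. `peakWavelength` refines the grid maximum with
a parabola through the three highest samples, appropriate for peaks
printed at 1 nm resolution. `bandRatio` is the nearest-percent magnitude
ratio used when comparing SE and ESA band amplitudes in mOD.

A two-state acid/base equilibrium observed across pH is the regime where
all spectra cross at one isosbestic wavelength. `findIsosbestic` locates
the wavelength of minimum across-pH spread, ignoring pixels carrying less
than 5% of the maximum mean intensity (band-free tails trivially have zero
spread), and flags the point "clear" only when the relative spread is
below 2% of the mean in-window intensity — the threshold that separates a
clean two-state series from the nuanced, no-clear-isosbestic behavior of a
chromophore whose absorption shifts continuously with pH. `fitTwoState`
decomposes the series as
\(I(\lambda, \mathrm{pH}) = f\,\mathrm{acid}(\lambda) +
(1-f)\,\mathrm{base}(\lambda)\) with Henderson–Hasselbalch
\(f = 1/(1 + 10^{\mathrm{pH} - pK_a})\): spectra are linear for fixed
\(pK_a\), so a one-dimensional search over \(pK_a\) suffices; on clean
two-state data the residual is zero to numerical precision and the
recovered \(pK_a\) is exact to ±0.1 under realistic noise.

## The synthetic-data generator

No public repository carries raw fs-TA/FSRS matrices for these biosensors,
so the generator is a first-class module, not a fixture. Its presets encode
the two photocycles as the study conditions:

* **`caBoundPreset()`** — calcium-bound: sequential lifetimes 3, 71 and
  1100 ps (ESPT completing on the 3 ps channel, partial ~71 ps relaxation,
  ~1.1 ns apparent fluorescence lifetime). GSB at 447 nm, ESA at 529 nm,
  photoproduct SE at 587 nm; SE and ESA rise together as ESPT proceeds and
  lose ~10–15% on the 71 ps step. ES Raman peaks at 1185, 1277, 1332,
  1385, 1515, 1641 1/cm, with 1641 (phenolate-ring C=O stretch) attached
  to the post-ESPT species only and 1385 a shared reactant–product mode.
  The `variant = "target"` scheme carries the branched multi-step ESPT
  explicitly — parallel 350 fs and 3 ps channels plus an adjustable
  sub-IRF channel. The instrument only bounds that fastest step from above
  (< 140 fs), so it is a free rate defaulting to (100 fs)⁻¹, never a
  fixed constant; branch fractions are likewise free parameters because
  time constants do not determine them.
* **`caFreePreset()`** — calcium-free: sequential lifetimes 2, 44 and
  330 ps (twisting into the dark state, intermediate relaxation, ground-
  state return). GSB at 446 nm, dark-state ESA at 526 nm rising, bright-
  state SE at 613 nm decaying; rising 1070/1350 1/cm dark-state markers
  and a decaying 1628 1/cm bright-state peak. Steady-state landmarks: A
  form absorbing at 446 nm, B form at 581 nm, emission at 511/613 nm.

Band shapes are Gaussian in wavelength (TA) and Raman shift (FSRS) —
Gaussian is the stated fit form for the Raman peaks, and for TA bands it
keeps the titration isosbestic point analytically solvable, which the
tests exploit as a closed-form oracle. Band amplitudes are set to the
printed mOD landmarks where available (SE magnitudes near −18/−14 mOD, ESA
near +28/+36 mOD at their characteristic delays); band *widths* are not
printed anywhere, so the preset widths (34–64 nm) are free parameters
chosen to reproduce the qualitative band overlap of the published contour
plots. Default grids: delays −1 to 900 ps (50 fs linear steps through the
IRF region, then 60 logarithmic points — matching a 900 ps experimental
window), probe 420–700 nm at 1 nm, Raman shift 900–1800 1/cm at 2 1/cm.

Noise is iid Gaussian per pixel with a user seed; heteroscedastic shot
noise, pump scatter and cross-phase modulation are out of scope, and chirp
is the only instrument artifact simulated (a polynomial time-zero shift
across the probe axis). Consequences for interpretation: passing recovery
tests show the estimators are unbiased and precise under the *assumed*
noise model and exactly-Gaussian bands. They do not demonstrate robustness
to correlated baseline drift, non-Gaussian lineshapes, or coherent
artifacts — on real data those effects argue for `maskT0`, explicit
baseline anchors, and inspection of the residual matrix (whose first
singular value should sit near the noise floor, another packaged check).

## Numerical choices and degenerate inputs

* Lifetimes are optimized in log space; global-fit bounds are
  [1 fs, 10 × window], trace-fit bounds [10 fs, 10 ns]. Initializations
  default to log-spaced ladders across the window.
* Rank-deficient projection bases (coincident lifetimes mid-iteration) get
  a \(10^{-10}\) ridge so the step stays defined; final transforms perturb
  ties by \(10^{-6}\) with a warning.
* `erfcx` uses `pracma` below 25 and a five-term asymptotic expansion
  above (relative error < \(10^{-12}\) at the crossover), because the
  direct \(e^{x^2}\mathrm{erfc}(x)\) route overflows near 26.6.
* Populations from the ODE fallback may undershoot zero by integration
  error; values above \(-10^{-7}\) are clamped to zero, anything lower is
  a validity failure.
* Zero-width IRFs, single-species schemes, plateau spectra (no peak),
  empty integration windows, ragged files and missing unit headers are all
  explicit error paths with tests.

## Problem sizes

The packaged tests and the acceptance analysis run on the default grids:
101 delays × 281 wavelengths per TA matrix (~28,000 pixels), 71 delays ×
451 shifts per FSRS series, 20-seed recovery ensembles for the global
fits. A single three-component global fit takes well under a second; the
full suite runs in seconds on one core. These sizes were chosen to match
the published experiments' sampling, not to stress hardware.

## Known limitations

* Target-scheme *fitting* estimates lifetimes for a fixed topology only;
  branching fractions are simulation inputs, not identifiable from a
  single matrix without spectral constraints, and no lifetime-density or
  maximum-entropy analysis is offered.
* The coherent artifact is masked, never modeled; sub-IRF lifetimes are
  therefore rejection criteria, not measurements.
* FSRS lineshapes are Gaussian only — no Voigt, dispersive or Fano forms —
  and resonance-enhancement factors are not modeled, so preset Raman
  amplitudes encode relative intensities phenomenologically.
* The two-state titration model assumes exactly two interconverting forms;
  a third state shows up only as residual growth (tested), not as a
  fitted species.

## A worked end-to-end run

```{r demo, eval = FALSE}
cfg <- system.file("extdata", "ca_bound_demo.yaml", package = "ultrafastSpec")
runPipeline(cfg, outDir = "demo_out")
cat(readLines(file.path("demo_out", "report.txt")), sep = "\n")
```

The report contains the three-component sequential fit of the simulated
calcium-bound matrix, the SE-band trace fit with its rise component marked
by an asterisk, the biphasic 1641 1/cm marker-band rise, and the
steady-state metrics, all reproducible byte-for-byte under the config
seed.
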