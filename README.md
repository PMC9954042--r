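# ultrafastSpec

Global and target analysis of ultrafast time-resolved spectra in R:
femtosecond transient absorption (fs-TA), femtosecond stimulated Raman
(FSRS), and the steady-state electronic spectroscopy around them.

## The problem this package addresses

Photoactive proteins — here, a green–red excitation-ratiometric calcium
biosensor — respond to light on femtosecond-to-nanosecond timescales:
excited-state proton transfer (ESPT) from the protonated chromophore,
twisting into non-emissive dark states, and ground-state recovery. fs-TA
measures a differential absorbance surface ΔA(t, λ) in mOD that
superimposes ground-state bleach (GSB), excited-state absorption (ESA) and
stimulated emission (SE) bands with overlapping kinetics; FSRS adds
time-resolved vibrational marker bands riding on a broad SE-like baseline.
Extracting a photocycle from these data requires, in one coherent chain:

* **Compartmental kinetics with IRF convolution.** Populations obey
  ċ = K c with a first-order rate matrix; excitation through a Gaussian
  instrument response of FWHM *w* (default 140 fs) turns each eigenmode
  into the analytic form
  c_k(t) = ½ exp(k(σ²k/2 − (t−t₀))) · erfc((σ²k − (t−t₀))/(σ√2)),
  σ = w / (2√(2 ln 2)), evaluated overflow-free via the scaled
  complementary error function.
* **Global analysis by variable projection.** ΔA = C(θ) S: lifetimes (and
  optionally IRF/dispersion) are optimized by Levenberg–Marquardt while the
  conditionally linear component spectra are eliminated at each step.
  Results are reported as sequential evolution-associated difference
  spectra (EADS) and parallel decay-associated difference spectra (DADS),
  exact linear transforms of each other that reconstruct the identical
  surface; `scanComponents` performs the two-to-five-component model scan
  with marginal-improvement and sub-IRF rejection rules.
* **Probe-band trace fitting.** Integrated band traces fit with
  IRF-convolved multi-exponentials; components carry percentage weights
  (absolute-amplitude shares) and rise/decay labels, with weighted-average
  lifetimes on any subset.
* **FSRS processing.** Anti-Stokes axis normalization, natural-spline
  baselines through user-declared peak-free anchors, simultaneous Gaussian
  peak fits, and per-delay peak-integral traces for marker-band dynamics.
* **Steady-state metrics.** Peak wavelengths with parabolic refinement,
  Stokes shifts in nm and eV (hc = 1239.84 eV·nm), nearest-percent band
  ratios, isosbestic-point detection, and Henderson–Hasselbalch two-state
  titration decomposition.

Because no public archive carries raw matrices for these experiments, the
package ships a first-class synthetic-data module: `caBoundPreset()`
(sequential lifetimes 3 / 71 / 1100 ps; GSB 447 nm, ESA 529 nm, SE 587 nm;
ES Raman peaks incl. the 1641 cm⁻¹ photoproduct marker and the shared
1385 cm⁻¹ mode) and `caFreePreset()` (2 / 44 / 330 ps; SE 613 nm decaying,
dark-state ESA 526 nm rising; 1070/1350 cm⁻¹ rising markers), plus
`simulateTA`, `simulateFSRS`, `simulateTrace` and `simulateTitration` with
seeded Gaussian noise.

## Worked example

Simulate the calcium-bound photocycle at realistic noise, run the
three-component sequential global analysis, and fit the SE-band trace:

```r
library(ultrafastSpec)

p   <- caBoundPreset()
ta  <- simulateTA(p$scheme, p$bands, noiseSigma = 0.3, seed = 1)
ta
#> SpectralMatrix: 101 delays (-1..900 ps) x 281 wavelengths (420..700 nm)
#>   excitation 400 nm
#>   signal range -17.8 .. 20.7 mOD

fitGlobal(ta, 3, initLifetimes = c(4.5, 106, 1650))
#> Global fit: 3 sequential components, RMSE 0.2962
#>   lifetimes: 2.998, 77.04, 1102 ps
#>   IRF: fwhm 140 fs, t0 0.000 ps

fitMultiexp(integrateBand(ta, c(583, 620)), 3)
#> Multi-exponential trace fit (3 components, RMSE 0.03978)
#>   tau 2.968 ps, weight 36% (rise*)
#>   tau 81.27 ps, weight 5%
#>   tau 1102 ps, weight 59%
```

The recovered lifetimes sit within a few percent of the generating values
(3, 71, 1100 ps) at the 0.3 mOD noise level, and the fit RMSE equals the
injected noise. The SE trace shows the ~3 ps ESPT rise (asterisked), a
small intermediate relaxation, and the long fluorescence decay. Steady-state
landmarks print as expected:

```r
stokesShift(481, 587)   # $nm 106, $eV 0.4655 -> 0.47 at 2 decimals
bandRatio(14, 36)       # 39 (percent)
```

A complete config-driven run — simulation, global fit, trace fit, FSRS
baseline/marker-band analysis and steady-state metrics with one seed and a
consolidated text report — is bundled:

```r
cfg <- system.file("extdata", "ca_bound_demo.yaml", package = "ultrafastSpec")
runPipeline(cfg, outDir = "demo_out")
```

A thin command-line front end over the same functions lives at
`inst/scripts/ultrafast-cli.R` (verbs: `run`, `simulate`, `globalfit`,
`tracefit`, `fsrs`, `steady`, `report`).

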