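## Synthetic-data generator: forward models of the fs-TA and FSRS experiments
## on a green-red calcium biosensor, so every analysis stage is testable
## without instrument data.

.gaussBand <- function(x, center, fwhm, amplitude) {
  s <- fwhm * .FWHM2SIGMA
  amplitude * exp(-(x - center)^2 / (2 * s^2))
}

## Evaluate seeded noise without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Default delay grid for simulated transient-absorption matrices
#'
#' Linear sampling through the IRF region (-1 to 1 ps in 50 fs steps) followed
#' by logarithmic sampling out to the end of the experimental time window
#' (900 ps by default, matching a typical fs-TA delay-stage span).
#'
#' @param tmax last delay (ps)
#' @param nLog number of logarithmic points after 1 ps
#' @return numeric vector of delays (ps)
#' @export
defaultDelayGrid <- function(tmax = 900, nLog = 60) {
  c(seq(-1, 1, by = 0.05),
    exp(seq(log(1.1), log(tmax), length.out = nLog)))
}

#' Photocycle presets of the calcium biosensor
#'
#' Bundled forward-model parameters emulating the two states of a green-red
#' excitation-ratiometric calcium biosensor at neutral pH.
#'
#' \code{caBoundPreset()}: the calcium-bound photocycle. The reported
#' sequential description has lifetimes 3, 71 and 1100 ps (excited-state
#' proton transfer completing on the 3 ps channel, partial nonradiative
#' relaxation at ~71 ps, and an ~1.1 ns apparent fluorescence lifetime).
#' Probe bands: ground-state bleach near 447 nm (negative), excited-state
#' absorption near 529 nm (positive), and the photoproduct (I*) stimulated
#' emission near 587 nm (negative) that rises as ESPT proceeds.
#' Excited-state Raman peaks sit at 1185, 1277, 1332, 1385, 1515 and
#' 1641 1/cm: the 1641 1/cm phenolate-ring C=O stretch is attached to the
#' post-ESPT species only (a pure photoproduct marker), while 1385 1/cm is a
#' shared reactant-product hydrogen-motion mode that decays after excitation.
#'
#' \code{caFreePreset()}: the calcium-free photocycle with sequential
#' lifetimes 2, 44 and 330 ps (chromophore twisting to a dark state in ~2 ps,
#' intermediate relaxation at 44 ps, and a ~330 ps ground-state return).
#' The bright B* state carries stimulated emission near 613 nm and the
#' decaying 1628 1/cm peak; the twisted dark state carries the rising
#' excited-state absorption near 526 nm and the rising 1070 and 1350 1/cm
#' marker peaks. Ground-state absorption peaks at pH 7 are ~446 nm
#' (protonated A form) and ~581 nm (deprotonated B form).
#'
#' The branched \code{variant = "target"} of the bound preset carries the
#' multi-step ESPT explicitly: A* feeds I* through parallel 350 fs and 3 ps
#' channels (plus an adjustable sub-IRF channel, bounded below by nothing but
#' the instrument response, defaulting to 100 fs), with branch fractions as
#' free parameters rather than hard-coded values.
#'
#' @param variant "sequential" (the representation used by global analysis)
#'   or "target" (branched photocycle topology)
#' @param subIrfTau lifetime (ps) of the unresolved sub-IRF ESPT channel in
#'   the target variant; the instrument bounds it from above (< 0.14 ps) but
#'   its true value is free
#' @return a list with elements \code{name}, \code{lifetimes} (ps),
#'   \code{scheme} (\linkS4class{KineticScheme}), \code{bands} (data.frame:
#'   species, center nm, fwhm nm, amplitude mOD, feature), \code{ramanPeaks}
#'   (data.frame: species, center 1/cm, fwhm 1/cm, amplitude %),
#'   \code{baselineBand} (broad SE-mimicking FSRS baseline), \code{excitation}
#'   (nm), \code{ramanPumpNm}, and steady-state landmarks
#'   (\code{absPeaks}, \code{emPeaks} in nm).
#' @export
caBoundPreset <- function(variant = c("sequential", "target"),
                          subIrfTau = 0.1) {
  variant <- match.arg(variant)
  lifetimes <- c(3, 71, 1100)
  species <- c("A*", "I*", "I*rel")
  scheme <- if (variant == "sequential") {
    buildSequential(lifetimes, species = species)
  } else {
    buildTarget(data.frame(
      from = c("A*", "A*", "A*", "I*", "I*rel"),
      to   = c("I*", "I*", "I*", "I*rel", "ground"),
      rate = c(1 / subIrfTau, 1 / 0.35, 1 / 3, 1 / 71, 1 / 1100)),
      initial = c("A*" = 1))
  }
  bands <- data.frame(
    species   = rep(species, 3),
    center    = rep(c(447, 529, 587), each = 3),
    fwhm      = rep(c(38, 46, 62), each = 3),
    amplitude = c(-10, -9, -8,      # GSB: slow recovery
                  14, 22, 19,       # ESA: rises with ESPT, partial 71 ps decay
                  -8, -18, -15.5),  # SE: I* photoproduct emission
    feature   = rep(c("GSB", "ESA", "SE"), each = 3))
  ramanPeaks <- data.frame(
    species   = rep(species, 6),
    center    = rep(c(1185, 1277, 1332, 1385, 1515, 1641), each = 3),
    fwhm      = rep(c(18, 20, 16, 22, 20, 24), each = 3),
    amplitude = c(-0.20, -0.14, -0.13,
                  -0.16, -0.11, -0.10,
                  -0.12, -0.09, -0.08,
                  -0.45, -0.30, -0.28,   # shared reactant-product mode
                  -0.18, -0.13, -0.12,
                   0.00, -0.42, -0.38))  # pure photoproduct C=O marker
  list(name = "ca_bound", lifetimes = lifetimes, scheme = scheme,
       bands = bands, ramanPeaks = ramanPeaks,
       baselineBand = list(center = 1650, fwhm = 1800, amplitude = -1.2,
                           species = "I*"),
       excitation = 400, ramanPumpNm = 650,
       absPeaks = c(A = 481, B = 566), emPeaks = c(I = 587))
}

#' @rdname caBoundPreset
#' @export
caFreePreset <- function(variant = c("sequential", "target")) {
  variant <- match.arg(variant)
  lifetimes <- c(2, 44, 330)
  species <- c("B*", "I1*", "I1*rel")
  scheme <- if (variant == "sequential") {
    buildSequential(lifetimes, species = species)
  } else {
    ## two parallel entry channels (A* and B*) funnel into the dark state
    buildTarget(data.frame(
      from = c("A*", "B*", "I1*", "I1*rel"),
      to   = c("I1*", "I1*", "I1*rel", "ground"),
      rate = c(1 / 2, 1 / 2.5, 1 / 44, 1 / 330)),
      initial = c("A*" = 0.7, "B*" = 0.3))
  }
  bands <- data.frame(
    species   = rep(species, 3),
    center    = rep(c(446, 526, 613), each = 3),
    fwhm      = rep(c(34, 44, 64), each = 3),
    amplitude = c(-8, -10, -6,    # GSB apparent rise on the ~2 ps timescale
                  8, 14, 8,       # ESA: dark-state rise then 44 ps decay
                  -12, -7, -4.5), # SE: bright B* decays as twisting proceeds
    feature   = rep(c("GSB", "ESA", "SE"), each = 3))
  ramanPeaks <- data.frame(
    species   = rep(species, 6),
    center    = rep(c(1070, 1195, 1280, 1350, 1520, 1628), each = 3),
    fwhm      = rep(c(20, 18, 20, 22, 20, 22), each = 3),
    amplitude = c(0.00, -0.30, -0.26,   # dark-state marker, rises
                  -0.16, -0.12, -0.10,
                  -0.14, -0.11, -0.09,
                  0.00, -0.40, -0.34,   # dark-state marker, rises
                  -0.13, -0.10, -0.08,
                  -0.50, -0.25, -0.15)) # bright-state C=O/C=C, decays
  list(name = "ca_free", lifetimes = lifetimes, scheme = scheme,
       bands = bands, ramanPeaks = ramanPeaks,
       baselineBand = list(center = 930, fwhm = 1800, amplitude = -0.5,
                           species = "B*"),
       excitation = 400, ramanPumpNm = 650,
       absPeaks = c(A = 446, B = 581), emPeaks = c(A = 511, B = 613))
}

.presetByName <- function(name) {
  switch(name,
         ca_bound = caBoundPreset(),
         ca_free = caFreePreset(),
         stop("unknown preset: ", name))
}

## chirp: polynomial coefficients of the per-wavelength time-zero shift,
## delta t0(lambda) = sum_k chirp[k] * ((lambda - lambdaRef) / 100)^(k-1), ps.
.chirpShift <- function(chirp, wl, lambdaRef) {
  if (is.null(chirp) || !length(chirp)) return(rep(0, length(wl)))
  u <- (wl - lambdaRef) / 100
  as.numeric(outer(u, seq_along(chirp) - 1, "^") %*% chirp)
}

#' Simulate a transient-absorption matrix
#'
#' Forward model \eqn{\Delta A(t, \lambda) = \sum_s c_s(t - \delta(\lambda))
#' \sum_{b \in s} G_b(\lambda)} + iid Gaussian noise: IRF-convolved
#' compartment populations weighted by per-species Gaussian probe bands,
#' with an optional polynomial probe chirp.
#'
#' @param scheme a \linkS4class{KineticScheme}
#' @param bands data.frame with columns species, center (nm), fwhm (nm),
#'   amplitude (mOD, signed: negative for GSB/SE, positive for ESA)
#' @param times delay grid (ps)
#' @param wavelengths probe grid (nm)
#' @param irf an \linkS4class{IRFModel}
#' @param chirp polynomial coefficients of the per-wavelength t0 shift in ps
#'   per (100 nm)^k, evaluated relative to \code{lambdaRef}; NULL = no chirp
#' @param lambdaRef chirp reference wavelength (default: reddest pixel)
#' @param noiseSigma additive Gaussian noise sd (mOD)
#' @param seed noise seed (bit-reproducible output for equal seeds)
#' @param excitation pump wavelength recorded in metadata (nm)
#' @param label free text
#' @return a \linkS4class{SpectralMatrix}
#' @examples
#' p <- caBoundPreset()
#' ta <- simulateTA(p$scheme, p$bands, noiseSigma = 0.3, seed = 1)
#' @export
simulateTA <- function(scheme, bands, times = defaultDelayGrid(),
                       wavelengths = seq(420, 700, by = 1),
                       irf = irfModel(), chirp = NULL, lambdaRef = NULL,
                       noiseSigma = 0, seed = NULL, excitation = 400,
                       label = "") {
  stopifnot(is(scheme, "KineticScheme"))
  unknown <- setdiff(bands$species, scheme@species)
  if (length(unknown))
    stop("band references unknown species: ", paste(unknown, collapse = ", "))
  B <- .bandMatrix(bands, scheme@species, wavelengths)
  if (is.null(lambdaRef)) lambdaRef <- max(wavelengths)
  shift <- .chirpShift(chirp, wavelengths, lambdaRef)
  if (all(shift == 0)) {
    conc <- solveConcentrations(scheme, times, irf)@values
    vals <- conc %*% B
  } else {
    vals <- matrix(0, length(times), length(wavelengths))
    for (g in split(seq_along(wavelengths), shift)) {
      irfG <- new("IRFModel", t0 = irf@t0 + shift[g[1]], fwhm = irf@fwhm)
      conc <- solveConcentrations(scheme, times, irfG)@values
      vals[, g] <- conc %*% B[, g, drop = FALSE]
    }
  }
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (noiseSigma > 0)
    vals <- vals + .withSeed(seed, matrix(
      stats::rnorm(length(vals), sd = noiseSigma), nrow(vals)))
  spectralMatrix(times, wavelengths, vals, excitation = excitation,
                 label = label)
}

## species x axis matrix of summed Gaussian band contributions
.bandMatrix <- function(bands, species, axis) {
  B <- matrix(0, length(species), length(axis),
              dimnames = list(species, NULL))
  for (r in seq_len(nrow(bands)))
    B[bands$species[r], ] <- B[bands$species[r], ] +
      .gaussBand(axis, bands$center[r], bands$fwhm[r], bands$amplitude[r])
  B
}

#' Simulate an excited-state FSRS time series
#'
#' Each delay's spectrum is a broad stimulated-emission-mimicking baseline
#' scaled by the emitting species' population, plus species-weighted Gaussian
#' Raman peaks, plus iid Gaussian noise.
#'
#' @param scheme a \linkS4class{KineticScheme}
#' @param ramanPeaks data.frame with columns species, center (1/cm),
#'   fwhm (1/cm), amplitude (signed gain %)
#' @param baselineBand list(center, fwhm, amplitude, species): the broad
#'   SE-like baseline the peaks ride on
#' @param delays actinic delay grid (ps)
#' @param shiftGrid Raman shift grid (1/cm), positive ascending
#' @param irf an \linkS4class{IRFModel}
#' @param noiseSigma additive Gaussian noise sd (gain %)
#' @param seed noise seed
#' @param pumpNm Raman pump wavelength for metadata
#' @return a \linkS4class{RamanTimeSeries}
#' @export
simulateFSRS <- function(scheme, ramanPeaks, baselineBand = NULL,
                         delays = c(seq(-0.5, 1, by = 0.05),
                                    exp(seq(log(1.2), log(600), length.out = 40))),
                         shiftGrid = seq(900, 1800, by = 2),
                         irf = irfModel(), noiseSigma = 0, seed = NULL,
                         pumpNm = 650) {
  stopifnot(is(scheme, "KineticScheme"))
  if (any(shiftGrid <= 0) || is.unsorted(shiftGrid, strictly = TRUE))
    stop("shift grid must be positive ascending")
  unknown <- setdiff(ramanPeaks$species, scheme@species)
  if (length(unknown))
    stop("peak references unknown species: ", paste(unknown, collapse = ", "))
  conc <- solveConcentrations(scheme, delays, irf)@values
  P <- .bandMatrix(data.frame(species = ramanPeaks$species,
                              center = ramanPeaks$center,
                              fwhm = ramanPeaks$fwhm,
                              amplitude = ramanPeaks$amplitude),
                   scheme@species, shiftGrid)
  vals <- conc %*% P
  if (!is.null(baselineBand)) {
    if (!baselineBand$species %in% scheme@species)
      stop("baseline references unknown species: ", baselineBand$species)
    base <- .gaussBand(shiftGrid, baselineBand$center, baselineBand$fwhm,
                       baselineBand$amplitude)
    vals <- vals + outer(conc[, baselineBand$species], base)
  }
  if (noiseSigma > 0)
    vals <- vals + .withSeed(seed, matrix(
      stats::rnorm(length(vals), sd = noiseSigma), nrow(vals)))
  ramanTimeSeries(delays, shiftGrid, vals, pumpNm = pumpNm,
                  side = "anti_stokes")
}

#' Simulate an IRF-convolved multi-exponential time trace
#'
#' Forward model of \code{\link{fitMultiexp}}: intensity(t) =
#' sum_i a_i * convolvedExponential(t, 1/tau_i, irf) + offset + noise.
#'
#' @param taus component lifetimes (ps)
#' @param amplitudes signed component amplitudes (same length)
#' @param times delay grid (ps)
#' @param irf an \linkS4class{IRFModel}
#' @param offset constant offset
#' @param noiseSigma additive Gaussian noise sd
#' @param seed noise seed
#' @param label free text
#' @return a \linkS4class{TimeTrace}
#' @export
simulateTrace <- function(taus, amplitudes, times, irf = irfModel(),
                          offset = 0, noiseSigma = 0, seed = NULL,
                          label = "") {
  stopifnot(length(taus) == length(amplitudes), all(taus > 0))
  y <- rep(offset, length(times))
  for (i in seq_along(taus))
    y <- y + amplitudes[i] * convolvedExponential(times, 1 / taus[i], irf)
  if (noiseSigma > 0)
    y <- y + .withSeed(seed, stats::rnorm(length(times), sd = noiseSigma))
  timeTrace(times, y, label = label)
}

#' Simulate a two-state pH titration series
#'
#' Henderson--Hasselbalch fractions weight two fixed Gaussian band shapes,
#' so all spectra share one exact crossing (isosbestic) wavelength where the
#' acid and base extinctions are equal.
#'
#' @param pKa acid dissociation constant of the chromophore
#' @param acidBand,baseBand list(center nm, fwhm nm, amplitude) band shapes of
#'   the protonated and deprotonated forms
#' @param pH pH values, one spectrum each
#' @param wavelengths shared grid (nm)
#' @param noiseSigma additive Gaussian noise sd
#' @param seed noise seed
#' @return a \linkS4class{TitrationSeries}
#' @examples
#' simulateTitration(6.5,
#'   acidBand = list(center = 446, fwhm = 60, amplitude = 1),
#'   baseBand = list(center = 581, fwhm = 70, amplitude = 1.4),
#'   pH = c(3.5, 5, 6.5, 8, 11))
#' @export
simulateTitration <- function(pKa, acidBand, baseBand,
                              pH = c(3.5, 5, 7, 9, 11),
                              wavelengths = seq(380, 700, by = 1),
                              noiseSigma = 0, seed = NULL) {
  ga <- .gaussBand(wavelengths, acidBand$center, acidBand$fwhm,
                   acidBand$amplitude)
  gb <- .gaussBand(wavelengths, baseBand$center, baseBand$fwhm,
                   baseBand$amplitude)
  cross <- which(diff(sign(ga - gb)) != 0)
  if (!length(cross) || max(pmin(ga, gb)[c(cross, cross + 1)]) <
      0.02 * max(ga, gb))
    warning("acid and base bands do not meaningfully cross: ",
            "no usable isosbestic point")
  f <- 1 / (1 + 10^(pH - pKa)) # acid fraction
  vals <- outer(f, ga) + outer(1 - f, gb)
  if (noiseSigma > 0)
    vals <- vals + .withSeed(seed, matrix(
      stats::rnorm(length(vals), sd = noiseSigma), nrow(vals)))
  titrationSeries(pH, wavelengths, vals)
}
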