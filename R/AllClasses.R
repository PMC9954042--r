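#' @import methods
NULL

.FWHM2SIGMA <- 1 / (2 * sqrt(2 * log(2)))

.asPs <- function(x, unit = c("ps", "fs", "ns")) {
  unit <- match.arg(unit)
  switch(unit, ps = x, fs = x / 1000, ns = x * 1000)
}

## ---------------------------------------------------------------------------
## IRFModel

#' Gaussian instrument response function
#'
#' The pump--probe cross-correlation is modeled as a unit-area Gaussian
#' parameterized by its center (time zero) and full width at half maximum.
#' The default FWHM of 140 fs is a typical cross-correlation time for a
#' prism-compressed 400 nm pump with a supercontinuum probe.
#'
#' @slot t0 time-zero center (ps)
#' @slot fwhm full width at half maximum (ps); must be >= 0 (0 = ideal
#'   delta-function response, i.e. a step-gated exponential)
#' @export
setClass("IRFModel", representation(t0 = "numeric", fwhm = "numeric"))

setValidity("IRFModel", function(object) {
  if (length(object@t0) != 1L || length(object@fwhm) != 1L)
    return("t0 and fwhm must be scalars")
  if (!is.finite(object@t0) || !is.finite(object@fwhm))
    return("t0 and fwhm must be finite")
  if (object@fwhm < 0) return("fwhm must be >= 0")
  TRUE
})

#' Construct a Gaussian IRF model
#'
#' @param fwhm full width at half maximum of the Gaussian cross-correlation.
#' @param t0 time-zero center. Same unit as \code{fwhm}.
#' @param unit unit of both arguments; stored internally in ps.
#' @return an \linkS4class{IRFModel}
#' @examples
#' irfModel(140, unit = "fs")
#' @export
irfModel <- function(fwhm = 0.140, t0 = 0, unit = c("ps", "fs", "ns")) {
  unit <- match.arg(unit)
  new("IRFModel", t0 = .asPs(t0, unit), fwhm = .asPs(fwhm, unit))
}

#' @describeIn irfModel Gaussian standard deviation (ps), derived from FWHM
#' @param irf an \linkS4class{IRFModel}
#' @export
irfSigma <- function(irf) irf@fwhm * .FWHM2SIGMA

#' @describeIn irfModel FWHM accessor (ps)
#' @export
irfFwhm <- function(irf) irf@fwhm

#' @describeIn irfModel time-zero accessor (ps)
#' @export
irfT0 <- function(irf) irf@t0

## ---------------------------------------------------------------------------
## KineticScheme

#' First-order compartmental photocycle scheme
#'
#' Species connected by first-order rate constants. The rate matrix follows
#' the column-to-row convention: entry (i, j) is the rate (1/ps) of j -> i
#' flow, and each diagonal entry closes the column, equalling minus the total
#' outflow of that species including flow to the unobserved ground-state sink.
#'
#' @slot species ordered species labels
#' @slot rateMatrix square first-order rate matrix (1/ps), diagonal closure
#' @slot initial initial excited-population vector, entries in [0, 1]
#' @slot sinkRates per-species rate of return to the unobserved ground state
#' @export
setClass("KineticScheme",
  representation(species = "character", rateMatrix = "matrix",
                 initial = "numeric", sinkRates = "numeric"))

setValidity("KineticScheme", function(object) {
  n <- length(object@species)
  K <- object@rateMatrix
  if (n == 0L) return("at least one species required")
  if (anyDuplicated(object@species)) return("species labels must be unique")
  if (!all(dim(K) == c(n, n))) return("rateMatrix dimension mismatch")
  if (length(object@initial) != n || length(object@sinkRates) != n)
    return("initial/sinkRates length mismatch")
  if (!all(is.finite(K))) return("non-finite rates")
  off <- K; diag(off) <- 0
  if (any(off < 0)) return("off-diagonal rates must be >= 0")
  if (any(object@sinkRates < 0)) return("sink rates must be >= 0")
  closure <- -(colSums(off) + object@sinkRates)
  if (max(abs(diag(K) - closure)) > 1e-9 * max(1, max(abs(K))))
    return("diagonal must equal -(sum of outflows incl. sink)")
  if (any(object@initial < 0 | object@initial > 1))
    return("initial populations must lie in [0, 1]")
  if (sum(object@initial) > 1 + 1e-9)
    return("initial populations must sum to <= 1")
  TRUE
})

#' @describeIn KineticScheme species labels
#' @param object,x a \code{KineticScheme}
#' @export
setMethod("names", "KineticScheme", function(x) x@species)

#' Accessors for kinetic schemes
#'
#' @param x a \linkS4class{KineticScheme}
#' @return \code{rateMatrix}: the closed rate matrix (1/ps);
#'   \code{initialPopulations}: the initial excited-population vector;
#'   \code{sinkRates}: per-species ground-state return rates (1/ps);
#'   \code{speciesLabels}: the ordered species labels.
#' @export
rateMatrix <- function(x) x@rateMatrix

#' @rdname rateMatrix
#' @export
initialPopulations <- function(x) setNames(x@initial, x@species)

#' @rdname rateMatrix
#' @export
sinkRates <- function(x) setNames(x@sinkRates, x@species)

#' @rdname rateMatrix
#' @export
speciesLabels <- function(x) x@species

## ---------------------------------------------------------------------------
## ConcentrationMatrix

#' IRF-convolved compartment populations on a delay grid
#'
#' @slot times delay grid (ps)
#' @slot species labels matching the originating scheme
#' @slot values population matrix, one row per time, one column per species
#' @export
setClass("ConcentrationMatrix",
  representation(times = "numeric", species = "character", values = "matrix"))

setValidity("ConcentrationMatrix", function(object) {
  if (nrow(object@values) != length(object@times) ||
      ncol(object@values) != length(object@species))
    return("values dimensions must match times x species")
  if (any(object@values < -1e-9)) return("populations below numerical floor")
  if (any(object@values > 1 + 1e-9)) return("populations exceed 1")
  TRUE
})

## ---------------------------------------------------------------------------
## SpectralMatrix

#' Transient absorption data matrix
#'
#' Differential absorbance \eqn{\Delta A}(delay, wavelength) in mOD, the
#' central object of femtosecond transient-absorption global analysis.
#'
#' @slot times delay grid (ps), strictly ascending
#' @slot wavelengths probe wavelength grid (nm), strictly ascending
#' @slot values mOD matrix, rows = delays, columns = wavelengths
#' @slot excitation actinic pump wavelength (nm)
#' @slot label free-text description
#' @export
setClass("SpectralMatrix",
  representation(times = "numeric", wavelengths = "numeric",
                 values = "matrix", excitation = "numeric", label = "character"))

.checkAxes <- function(times, axis, values) {
  if (length(times) < 1L || length(axis) < 1L) return("empty axis")
  if (any(diff(times) <= 0)) return("delay axis must be strictly ascending")
  if (any(diff(axis) <= 0)) return("spectral axis must be strictly ascending")
  if (nrow(values) != length(times) || ncol(values) != length(axis))
    return("values dimensions must match axes")
  if (!all(is.finite(values))) return("values must be finite")
  TRUE
}

setValidity("SpectralMatrix", function(object)
  .checkAxes(object@times, object@wavelengths, object@values))

#' Construct a SpectralMatrix
#'
#' @param times delay grid (ps), strictly ascending
#' @param wavelengths wavelength grid (nm), strictly ascending
#' @param values mOD matrix (delays x wavelengths)
#' @param excitation pump wavelength (nm)
#' @param label free text
#' @export
spectralMatrix <- function(times, wavelengths, values,
                           excitation = NA_real_, label = "") {
  new("SpectralMatrix", times = as.numeric(times),
      wavelengths = as.numeric(wavelengths),
      values = as.matrix(values), excitation = as.numeric(excitation),
      label = label)
}

## ---------------------------------------------------------------------------
## Raman containers

#' A single stimulated Raman spectrum
#'
#' @slot shift Raman shift grid (1/cm), positive ascending once normalized
#' @slot gain stimulated Raman gain (%), signed (excited-state peaks on the
#'   anti-Stokes side are stored as measured, typically negative)
#' @slot pumpNm Raman pump wavelength (nm)
#' @slot side "stokes" or "anti_stokes" probe side
#' @slot delay actinic delay (ps); NA for ground-state spectra
#' @export
setClass("RamanSpectrum",
  representation(shift = "numeric", gain = "numeric", pumpNm = "numeric",
                 side = "character", delay = "numeric"))

setValidity("RamanSpectrum", function(object) {
  if (length(object@shift) != length(object@gain))
    return("shift/gain length mismatch")
  if (is.unsorted(object@shift, strictly = TRUE) &&
      is.unsorted(rev(object@shift), strictly = TRUE))
    return("shift axis must be strictly monotonic")
  if (!all(is.finite(object@gain))) return("gain must be finite")
  if (!object@side %in% c("stokes", "anti_stokes"))
    return("side must be 'stokes' or 'anti_stokes'")
  TRUE
})

#' Construct a RamanSpectrum
#' @param shift Raman shift grid (1/cm)
#' @param gain stimulated Raman gain (%), signed
#' @param pumpNm Raman pump wavelength (nm)
#' @param side probe side relative to the pump
#' @param delay actinic delay (ps), NA for ground state
#' @export
ramanSpectrum <- function(shift, gain, pumpNm = NA_real_,
                          side = c("anti_stokes", "stokes"),
                          delay = NA_real_) {
  side <- match.arg(side)
  new("RamanSpectrum", shift = as.numeric(shift), gain = as.numeric(gain),
      pumpNm = pumpNm, side = side, delay = delay)
}

#' Time series of excited-state Raman spectra on a common shift grid
#'
#' @slot delays actinic delays (ps), ascending
#' @slot shift common Raman shift grid (1/cm), ascending
#' @slot values gain matrix, rows = delays, columns = shifts
#' @slot pumpNm Raman pump wavelength (nm)
#' @slot side probe side
#' @export
setClass("RamanTimeSeries",
  representation(delays = "numeric", shift = "numeric", values = "matrix",
                 pumpNm = "numeric", side = "character"))

setValidity("RamanTimeSeries", function(object)
  .checkAxes(object@delays, object@shift, object@values))

#' Construct a RamanTimeSeries
#' @param delays actinic delays (ps), ascending
#' @param shift Raman shift grid (1/cm), ascending
#' @param values gain matrix (delays x shifts)
#' @param pumpNm Raman pump wavelength (nm)
#' @param side probe side
#' @export
ramanTimeSeries <- function(delays, shift, values, pumpNm = NA_real_,
                            side = c("anti_stokes", "stokes")) {
  side <- match.arg(side)
  new("RamanTimeSeries", delays = as.numeric(delays),
      shift = as.numeric(shift), values = as.matrix(values),
      pumpNm = pumpNm, side = side)
}

#' Spline baseline under Raman peaks
#'
#' @slot knots two-column matrix of (shift, gain) anchor medians
#' @slot curve baseline evaluated on the full spectrum grid
#' @slot shift the spectrum grid the curve is defined on
#' @slot method method tag
#' @export
setClass("RamanBaseline",
  representation(knots = "matrix", curve = "numeric", shift = "numeric",
                 method = "character"))

setValidity("RamanBaseline", function(object) {
  if (length(object@curve) != length(object@shift))
    return("curve must be defined on the full grid")
  TRUE
})

## ---------------------------------------------------------------------------
## Traces and trace fits

#' Integrated probe-band time trace
#'
#' @slot times delays (ps), ascending
#' @slot intensity signed signal (mOD or Raman gain)
#' @slot window integrated axis window (low, high)
#' @slot windowUnit unit of the window ("nm" or "cm-1")
#' @slot label free text
#' @export
setClass("TimeTrace",
  representation(times = "numeric", intensity = "numeric",
                 window = "numeric", windowUnit = "character",
                 label = "character"))

setValidity("TimeTrace", function(object) {
  if (length(object@times) != length(object@intensity))
    return("times/intensity length mismatch")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly ascending")
  if (length(object@window) == 2 && !anyNA(object@window) &&
      object@window[1] >= object@window[2])
    return("window low must be < high")
  TRUE
})

#' Construct a TimeTrace
#' @param times delays (ps)
#' @param intensity signed signal values
#' @param window integration window of the originating axis
#' @param windowUnit axis unit of the window
#' @param label free text
#' @export
timeTrace <- function(times, intensity, window = c(NA_real_, NA_real_),
                      windowUnit = "", label = "") {
  new("TimeTrace", times = as.numeric(times),
      intensity = as.numeric(intensity), window = as.numeric(window),
      windowUnit = windowUnit, label = label)
}

#' Multi-exponential trace fit result
#'
#' Components are reported with lifetimes ascending; weight percentages are
#' absolute-amplitude shares summing to 100 across rise and decay components,
#' and a component is a "rise" when its amplitude sign opposes the dominant
#' sign of the fitted feature.
#'
#' @slot components data.frame with columns tau (ps), amplitude, weightPercent,
#'   kind ("rise"/"decay")
#' @slot irfFit the IRF used or fitted
#' @slot offset fitted constant offset (0 when disabled)
#' @slot rmse root-mean-square residual
#' @slot converged optimizer convergence flag
#' @slot notes diagnostic messages (bound collapse etc.)
#' @export
setClass("TraceFitResult",
  representation(components = "data.frame", irfFit = "IRFModel",
                 offset = "numeric", rmse = "numeric", converged = "logical",
                 notes = "character"))

setValidity("TraceFitResult", function(object) {
  cmp <- object@components
  need <- c("tau", "amplitude", "weightPercent", "kind")
  if (!all(need %in% names(cmp))) return("missing component columns")
  if (nrow(cmp) > 0) {
    if (abs(sum(cmp$weightPercent) - 100) > 0.5)
      return("weight percents must sum to 100 +/- 0.5")
    if (is.unsorted(cmp$tau)) return("component taus must be ascending")
  }
  if (object@rmse < 0) return("rmse must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Global analysis results

#' Global (EADS/DADS) fit result
#'
#' @slot lifetimes ascending fitted lifetimes (ps)
#' @slot eads evolution-associated difference spectra (components x axis),
#'   from the sequential compartment basis
#' @slot dads decay-associated difference spectra (parallel basis); linear
#'   transform of the EADS, both reconstruct the identical fitted surface
#' @slot axis spectral axis of the fitted data (nm or 1/cm)
#' @slot axisUnit "nm" or "cm-1"
#' @slot times delay axis of the fitted data (ps)
#' @slot irfFit IRF (fitted or fixed)
#' @slot dispersion polynomial coefficients of the t0-vs-axis correction
#'   (ps per (axis step)^k), empty when not fitted
#' @slot rmse root-mean-square residual over all pixels
#' @slot nComponents number of kinetic components
#' @slot converged optimizer convergence flag
#' @slot notes diagnostic messages
#' @export
setClass("GlobalFitResult",
  representation(lifetimes = "numeric", eads = "matrix", dads = "matrix",
                 axis = "numeric", axisUnit = "character", times = "numeric",
                 irfFit = "IRFModel", dispersion = "numeric", rmse = "numeric",
                 nComponents = "integer", converged = "logical",
                 notes = "character"))

setValidity("GlobalFitResult", function(object) {
  n <- object@nComponents
  if (length(object@lifetimes) != n) return("lifetime count != nComponents")
  if (nrow(object@eads) != n || nrow(object@dads) != n)
    return("EADS/DADS row count != nComponents")
  if (is.unsorted(object@lifetimes)) return("lifetimes must be ascending")
  if (object@rmse < 0) return("rmse must be >= 0")
  TRUE
})

#' Model-order scan result
#'
#' @slot candidates data.frame with n, rmse, converged, minLifetime
#' @slot fits list of \linkS4class{GlobalFitResult}, one per candidate
#' @slot selectedN selected component count
#' @slot selectionLog one reasoning line per candidate
#' @export
setClass("ModelScanResult",
  representation(candidates = "data.frame", fits = "list",
                 selectedN = "integer", selectionLog = "character"))

setValidity("ModelScanResult", function(object) {
  ok <- object@candidates$n[object@candidates$converged]
  if (!object@selectedN %in% ok)
    return("selectedN must be a converged candidate")
  TRUE
})

## ---------------------------------------------------------------------------
## Steady-state containers

#' One-dimensional steady-state spectrum
#'
#' @slot axis wavelength grid (nm), strictly ascending
#' @slot intensity OD or emission intensity
#' @slot axisKind "absorption", "emission" or "excitation"
#' @slot label free text
#' @export
setClass("Spectrum1D",
  representation(axis = "numeric", intensity = "numeric",
                 axisKind = "character", label = "character"))

setValidity("Spectrum1D", function(object) {
  if (length(object@axis) != length(object@intensity))
    return("axis/intensity length mismatch")
  if (is.unsorted(object@axis, strictly = TRUE))
    return("axis must be strictly ascending")
  if (!all(is.finite(object@intensity))) return("intensities must be finite")
  if (!object@axisKind %in% c("absorption", "emission", "excitation"))
    return("axisKind must be absorption/emission/excitation")
  TRUE
})

#' Construct a Spectrum1D
#' @param axis wavelength grid (nm)
#' @param intensity intensities
#' @param axisKind spectrum kind
#' @param label free text
#' @export
spectrum1D <- function(axis, intensity,
                       axisKind = c("absorption", "emission", "excitation"),
                       label = "") {
  axisKind <- match.arg(axisKind)
  new("Spectrum1D", axis = as.numeric(axis),
      intensity = as.numeric(intensity), axisKind = axisKind, label = label)
}

#' pH titration series of absorption spectra on a shared grid
#'
#' @slot pH pH values, one per spectrum
#' @slot axis shared wavelength grid (nm)
#' @slot values intensity matrix, rows = pH values, columns = wavelengths
#' @export
setClass("TitrationSeries",
  representation(pH = "numeric", axis = "numeric", values = "matrix"))

setValidity("TitrationSeries", function(object) {
  if (length(object@pH) < 2) return("at least 2 spectra required")
  if (nrow(object@values) != length(object@pH) ||
      ncol(object@values) != length(object@axis))
    return("values dimensions must match pH x axis")
  TRUE
})

#' Construct a TitrationSeries
#' @param pH pH values
#' @param axis shared wavelength grid (nm)
#' @param values intensity matrix (pH x wavelength)
#' @export
titrationSeries <- function(pH, axis, values) {
  new("TitrationSeries", pH = as.numeric(pH), axis = as.numeric(axis),
      values = as.matrix(values))
}
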