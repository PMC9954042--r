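#' Delay-axis accessor
#' @param x an object with a delay axis
#' @return numeric vector of delays (ps)
#' @export
setGeneric("delayTimes", function(x) standardGeneric("delayTimes"))

#' @rdname delayTimes
#' @export
setMethod("delayTimes", "SpectralMatrix", function(x) x@times)
#' @rdname delayTimes
#' @export
setMethod("delayTimes", "RamanTimeSeries", function(x) x@delays)
#' @rdname delayTimes
#' @export
setMethod("delayTimes", "ConcentrationMatrix", function(x) x@times)
#' @rdname delayTimes
#' @export
setMethod("delayTimes", "TimeTrace", function(x) x@times)

#' Spectral-axis accessors
#' @param x an object with a spectral axis
#' @return numeric vector: probe wavelengths (nm) or Raman shifts (1/cm)
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralMatrix", function(x) x@wavelengths)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum1D", function(x) x@axis)
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "TitrationSeries", function(x) x@axis)

#' @rdname wavelengths
#' @export
setGeneric("ramanShift", function(x) standardGeneric("ramanShift"))

#' @rdname wavelengths
#' @export
setMethod("ramanShift", "RamanSpectrum", function(x) x@shift)
#' @rdname wavelengths
#' @export
setMethod("ramanShift", "RamanTimeSeries", function(x) x@shift)

#' Signal-value accessor
#' @param x a data container
#' @return the numeric matrix or vector of signal values
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname signalValues
#' @export
setMethod("signalValues", "SpectralMatrix", function(x) x@values)
#' @rdname signalValues
#' @export
setMethod("signalValues", "RamanTimeSeries", function(x) x@values)
#' @rdname signalValues
#' @export
setMethod("signalValues", "ConcentrationMatrix", function(x) x@values)
#' @rdname signalValues
#' @export
setMethod("signalValues", "RamanSpectrum", function(x) x@gain)
#' @rdname signalValues
#' @export
setMethod("signalValues", "TimeTrace", function(x) x@intensity)
#' @rdname signalValues
#' @export
setMethod("signalValues", "Spectrum1D", function(x) x@intensity)
#' @rdname signalValues
#' @export
setMethod("signalValues", "TitrationSeries", function(x) x@values)

#' Fit-result accessors
#' @param x a fit result
#' @return \code{lifetimes}: ascending lifetimes (ps); \code{eads}/\code{dads}:
#'   component spectra matrices; \code{rmse}: root-mean-square residual;
#'   \code{nComponents}: component count; \code{isConverged}: logical;
#'   \code{traceComponents}: component table of a trace fit;
#'   \code{selectedN}/\code{selectionLog}: model-scan selection outputs.
#' @export
setGeneric("lifetimes", function(x) standardGeneric("lifetimes"))

#' @rdname lifetimes
#' @export
setMethod("lifetimes", "GlobalFitResult", function(x) x@lifetimes)
#' @rdname lifetimes
#' @export
setMethod("lifetimes", "TraceFitResult", function(x) x@components$tau)

#' @rdname lifetimes
#' @export
eads <- function(x) x@eads

#' @rdname lifetimes
#' @export
dads <- function(x) x@dads

#' @rdname lifetimes
#' @export
setGeneric("rmse", function(x) standardGeneric("rmse"))
#' @rdname lifetimes
#' @export
setMethod("rmse", "GlobalFitResult", function(x) x@rmse)
#' @rdname lifetimes
#' @export
setMethod("rmse", "TraceFitResult", function(x) x@rmse)

#' @rdname lifetimes
#' @export
nComponents <- function(x) x@nComponents

#' @rdname lifetimes
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname lifetimes
#' @export
setMethod("isConverged", "GlobalFitResult", function(x) x@converged)
#' @rdname lifetimes
#' @export
setMethod("isConverged", "TraceFitResult", function(x) x@converged)

#' @rdname lifetimes
#' @export
traceComponents <- function(x) x@components

#' @rdname lifetimes
#' @export
selectedN <- function(x) x@selectedN

#' @rdname lifetimes
#' @export
selectionLog <- function(x) x@selectionLog

#' @rdname lifetimes
#' @export
scanFits <- function(x) x@fits

#' @rdname lifetimes
#' @export
scanCandidates <- function(x) x@candidates

#' Rebuild the fitted model surface on data axes
#' @param result a fit result
#' @param ... method arguments
#' @export
setGeneric("reconstruct", function(result, ...) standardGeneric("reconstruct"))
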