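#' Show methods
#'
#' Compact console summaries of the package's S4 containers.
#'
#' @param object the object to display
#' @name show-methods
#' @keywords internal
NULL

#' @rdname show-methods
setMethod("show", "IRFModel", function(object) {
  cat(sprintf("Gaussian IRF: fwhm %.0f fs, t0 %.3f ps\n",
              1000 * object@fwhm, object@t0))
})

#' @rdname show-methods
setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("KineticScheme with %d species: %s\n", length(object@species),
              paste(object@species, collapse = " -> ")))
  sink <- which(object@sinkRates > 0)
  if (length(sink))
    cat(sprintf("  ground-state return from: %s\n",
                paste(object@species[sink], collapse = ", ")))
})

#' @rdname show-methods
setMethod("show", "SpectralMatrix", function(object) {
  cat(sprintf(paste0("SpectralMatrix: %d delays (%.3g..%.3g ps) x ",
                     "%d wavelengths (%g..%g nm)\n"),
              length(object@times), min(object@times), max(object@times),
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths)))
  if (!is.na(object@excitation))
    cat(sprintf("  excitation %g nm\n", object@excitation))
  cat(sprintf("  signal range %.3g .. %.3g mOD\n", min(object@values),
              max(object@values)))
})

#' @rdname show-methods
setMethod("show", "RamanTimeSeries", function(object) {
  cat(sprintf(paste0("RamanTimeSeries: %d delays (%.3g..%.3g ps) x ",
                     "%d shifts (%g..%g 1/cm), %s side\n"),
              length(object@delays), min(object@delays), max(object@delays),
              length(object@shift), min(object@shift), max(object@shift),
              object@side))
})

#' @rdname show-methods
setMethod("show", "RamanSpectrum", function(object) {
  cat(sprintf("RamanSpectrum (%s): %d points, %g..%g 1/cm%s\n",
              object@side, length(object@shift), min(object@shift),
              max(object@shift),
              if (is.na(object@delay)) " (ground state)"
              else sprintf(", delay %.3g ps", object@delay)))
})

#' @rdname show-methods
setMethod("show", "TimeTrace", function(object) {
  win <- if (all(is.na(object@window))) "" else
    sprintf(" [%g, %g] %s", object@window[1], object@window[2],
            object@windowUnit)
  cat(sprintf("TimeTrace%s: %d delays (%.3g..%.3g ps)\n", win,
              length(object@times), min(object@times), max(object@times)))
})

#' @rdname show-methods
setMethod("show", "TraceFitResult", function(object) {
  cat(sprintf("Multi-exponential trace fit (%d components, RMSE %.4g)%s\n",
              nrow(object@components), object@rmse,
              if (object@converged) "" else " NOT CONVERGED"))
  cmp <- object@components
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  tau %.4g ps, weight %.0f%%%s\n", cmp$tau[i],
                cmp$weightPercent[i],
                if (cmp$kind[i] == "rise") " (rise*)" else ""))
  if (object@offset != 0) cat(sprintf("  offset %.4g\n", object@offset))
})

#' @rdname show-methods
setMethod("show", "GlobalFitResult", function(object) {
  cat(sprintf("Global fit: %d sequential components, RMSE %.4g%s\n",
              object@nComponents, object@rmse,
              if (object@converged) "" else " NOT CONVERGED"))
  cat(sprintf("  lifetimes: %s ps\n",
              paste(signif(object@lifetimes, 4), collapse = ", ")))
  cat(sprintf("  IRF: fwhm %.0f fs, t0 %.3f ps\n",
              1000 * object@irfFit@fwhm, object@irfFit@t0))
  for (n in object@notes) cat("  note: ", n, "\n", sep = "")
})

#' @rdname show-methods
setMethod("show", "ModelScanResult", function(object) {
  cat(sprintf("Model-order scan: selected n = %d\n", object@selectedN))
  for (l in object@selectionLog) cat("  ", l, "\n", sep = "")
})

#' @rdname show-methods
setMethod("show", "Spectrum1D", function(object) {
  cat(sprintf("Spectrum1D (%s): %d points, %g..%g nm\n", object@axisKind,
              length(object@axis), min(object@axis), max(object@axis)))
})

#' @rdname show-methods
setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d spectra at pH %s\n", length(object@pH),
              paste(object@pH, collapse = ", ")))
})

#' Quick-look plots
#'
#' \code{plot} on a \linkS4class{SpectralMatrix} draws a filled contour of
#' the mOD surface on a symmetric color scale; on a \linkS4class{TimeTrace}
#' it draws the trace (optionally with a fitted curve overlaid).
#'
#' @param x the object to plot
#' @param y for a TimeTrace, an optional \linkS4class{TraceFitResult} overlay
#' @param ... further arguments passed to the base graphics call
#' @export
setMethod("plot", signature("SpectralMatrix", "missing"), function(x, y, ...) {
  lim <- max(abs(x@values))
  cols <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(x@times, x@wavelengths, x@values, col = cols,
                  zlim = c(-lim, lim), xlab = "delay (ps)",
                  ylab = "wavelength (nm)", ...)
})

#' @rdname plot-SpectralMatrix-missing-method
#' @export
setMethod("plot", signature("TimeTrace", "ANY"), function(x, y, ...) {
  graphics::plot(x@times, x@intensity, pch = 16, cex = 0.6, log = "",
                 xlab = "delay (ps)", ylab = "intensity", ...)
  if (!missing(y) && is(y, "TraceFitResult")) {
    fine <- seq(min(x@times), max(x@times), length.out = 500)
    graphics::lines(fine, reconstruct(y, fine)@intensity, col = 2)
  }
})
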