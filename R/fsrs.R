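## FSRS processing: Raman axis conventions, spline baseline estimation and
## subtraction, Gaussian multi-peak fitting, and time-resolved peak-integral
## extraction.

#' Normalize the Raman shift axis to positive vibrational frequencies
#'
#' Anti-Stokes spectra are recorded with a negative stimulated Raman shift
#' axis; the convention is to multiply it by -1 and re-sort ascending so
#' vibrational frequencies read positive. Stokes spectra are returned
#' unchanged. Idempotent: a second application is a no-op.
#'
#' @param spectrum a \linkS4class{RamanSpectrum} (possibly with a raw signed
#'   axis)
#' @return a \linkS4class{RamanSpectrum} with positive ascending shift axis
#' @export
normalizeShiftAxis <- function(spectrum) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  sh <- spectrum@shift; g <- spectrum@gain
  if (any(sh > 0) && any(sh < 0))
    stop("mixed-sign shift axis is ambiguous; split the sides first")
  if (all(sh <= 0)) { sh <- -sh }
  ord <- order(sh)
  new("RamanSpectrum", shift = sh[ord], gain = g[ord],
      pumpNm = spectrum@pumpNm, side = spectrum@side, delay = spectrum@delay)
}

#' Raman probe wavelength from pump wavelength and shift
#'
#' Wavenumber bookkeeping: the probe sits at the pump wavenumber plus
#' (anti-Stokes) or minus (Stokes) the Raman shift, so an anti-Stokes probe
#' is bluer than the pump.
#'
#' @param pumpNm Raman pump wavelength (nm)
#' @param shift Raman shift (1/cm), positive
#' @param side "anti_stokes" or "stokes"
#' @return probe wavelength (nm)
#' @examples
#' probeWavelength(650, 1641)  # ~587.4 nm, bluer than the 650 nm pump
#' @export
probeWavelength <- function(pumpNm, shift, side = c("anti_stokes", "stokes")) {
  side <- match.arg(side)
  nuPump <- 1e7 / pumpNm
  nuProbe <- if (side == "anti_stokes") nuPump + shift else nuPump - shift
  1e7 / nuProbe
}

#' Estimate a spline baseline through declared peak-free anchor regions
#'
#' A natural cubic spline (C2-continuous between knots) is passed through the
#' median (shift, gain) point of each anchor region, emulating the manual
#' "spline-like" baselines drawn under broad stimulated-emission backgrounds
#' in excited-state FSRS.
#'
#' @param spectrum a \linkS4class{RamanSpectrum}, axis already normalized
#' @param anchorRegions list (or 2-column matrix) of (low, high) shift windows
#'   declared peak-free; at least 4, spanning toward both grid ends
#' @param peakWindows optional list of declared peak windows; anchors
#'   intersecting any of them raise an error
#' @return a \linkS4class{RamanBaseline}
#' @export
fitBaseline <- function(spectrum, anchorRegions, peakWindows = NULL) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  if (is.matrix(anchorRegions))
    anchorRegions <- split(anchorRegions, row(anchorRegions))
  if (length(anchorRegions) < 4)
    stop("at least 4 anchor regions are required")
  sh <- spectrum@shift; g <- spectrum@gain
  if (!is.null(peakWindows)) {
    for (a in anchorRegions) for (p in peakWindows)
      if (a[1] < p[2] && p[1] < a[2])
        stop("anchor region [", a[1], ", ", a[2],
             "] lies inside a declared peak window")
  }
  knots <- t(vapply(anchorRegions, function(w) {
    sel <- sh >= w[1] & sh <= w[2]
    if (!any(sel)) stop("anchor region [", w[1], ", ", w[2],
                        "] does not overlap the grid")
    c(stats::median(sh[sel]), stats::median(g[sel]))
  }, numeric(2)))
  knots <- knots[order(knots[, 1]), , drop = FALSE]
  span <- diff(range(sh))
  if (knots[1, 1] > sh[1] + 0.25 * span ||
      knots[nrow(knots), 1] < sh[length(sh)] - 0.25 * span)
    warning("anchor regions leave more than a quarter of the grid ",
            "unanchored at an end; the baseline is extrapolated there")
  fn <- stats::splinefun(knots[, 1], knots[, 2], method = "natural")
  new("RamanBaseline", knots = knots, curve = fn(sh), shift = sh,
      method = "natural cubic spline through anchor-region medians")
}

#' Subtract a baseline from a Raman spectrum
#'
#' @param spectrum a \linkS4class{RamanSpectrum}
#' @param baseline a \linkS4class{RamanBaseline} on the same grid
#' @return the baseline-subtracted \linkS4class{RamanSpectrum}
#' @export
subtractBaseline <- function(spectrum, baseline) {
  stopifnot(is(spectrum, "RamanSpectrum"), is(baseline, "RamanBaseline"))
  if (length(baseline@shift) != length(spectrum@shift) ||
      any(abs(baseline@shift - spectrum@shift) > 1e-9))
    stop("grid mismatch between spectrum and baseline")
  new("RamanSpectrum", shift = spectrum@shift,
      gain = spectrum@gain - baseline@curve, pumpNm = spectrum@pumpNm,
      side = spectrum@side, delay = spectrum@delay)
}

#' Subtract a ground-state spectrum from an excited-state spectrum
#'
#' Excited-state FSRS traces are conventionally stored with the ground-state
#' trace already subtracted; this performs that subtraction when raw pairs
#' are supplied.
#'
#' @param es,gs \linkS4class{RamanSpectrum} objects on the same grid
#' @return the difference spectrum (excited minus ground)
#' @export
subtractGroundState <- function(es, gs) {
  if (length(es@shift) != length(gs@shift) ||
      any(abs(es@shift - gs@shift) > 1e-9))
    stop("grid mismatch between excited- and ground-state spectra")
  new("RamanSpectrum", shift = es@shift, gain = es@gain - gs@gain,
      pumpNm = es@pumpNm, side = es@side, delay = es@delay)
}

#' Fit Gaussian peaks to a baseline-subtracted Raman spectrum
#'
#' Simultaneous least-squares fit of one Gaussian per initial center within
#' the union of per-peak windows; overlapping windows are merged so
#' overlapped peaks are fit jointly.
#'
#' @param spectrum a baseline-subtracted \linkS4class{RamanSpectrum}
#' @param initCenters starting peak centers (1/cm), inside the grid
#' @param window half-width (1/cm) of the fit window around each center
#'   (scalar or per-peak)
#' @param initFwhm starting FWHM (1/cm), scalar or per-peak
#' @return a peak table (data.frame): center, fwhm, amplitude, area (signed,
#'   amplitude x fwhm x sqrt(2 pi) / (2 sqrt(2 ln 2))), converged
#' @examples
#' sp <- ramanSpectrum(seq(900, 1800, 2),
#'                     -0.4 * exp(-(seq(900, 1800, 2) - 1641)^2 / (2 * 7.6^2)))
#' fitPeaks(sp, 1641)
#' @export
fitPeaks <- function(spectrum, initCenters, window = 40, initFwhm = 18) {
  stopifnot(is(spectrum, "RamanSpectrum"))
  sh <- spectrum@shift; g <- spectrum@gain
  np <- length(initCenters)
  if (!np) stop("no initial centers supplied")
  if (any(initCenters < min(sh) | initCenters > max(sh)))
    stop("init centers must lie inside the grid")
  window <- rep_len(window, np)
  initFwhm <- rep_len(initFwhm, np)
  sel <- rep(FALSE, length(sh))
  for (i in seq_len(np))
    sel <- sel | (sh >= initCenters[i] - window[i] &
                  sh <= initCenters[i] + window[i])
  x <- sh[sel]; y <- g[sel]
  ## amplitude guesses from the data at the init centers
  a0 <- vapply(initCenters, function(c0) y[which.min(abs(x - c0))], numeric(1))
  a0[a0 == 0] <- ifelse(stats::median(y) < 0, -1e-3, 1e-3)
  par <- c(initCenters, log(initFwhm), a0)
  model <- function(p) {
    out <- numeric(length(x))
    for (i in seq_len(np))
      out <- out + .gaussBand(x, p[i], exp(p[np + i]), p[2 * np + i])
    out
  }
  fit <- minpack.lm::nls.lm(
    par, fn = function(p) y - model(p),
    lower = c(initCenters - window, rep(log(1), np), rep(-Inf, np)),
    upper = c(initCenters + window, rep(log(4 * max(window)), np),
              rep(Inf, np)),
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12))
  p <- fit$par
  centers <- p[seq_len(np)]
  fwhms <- exp(p[np + seq_len(np)])
  amps <- p[2 * np + seq_len(np)]
  ord <- order(centers)
  data.frame(center = centers[ord], fwhm = fwhms[ord],
             amplitude = amps[ord],
             area = (amps * fwhms * .FWHM2SIGMA * sqrt(2 * pi))[ord],
             converged = fit$info %in% 1:4)
}

#' Time-resolved peak-integral trace from an FSRS series
#'
#' Per-delay trapezoidal integral of the (optionally baseline-subtracted)
#' gain over a shift window, preserving sign; the result feeds
#' \code{\link{fitMultiexp}}.
#'
#' @param series a \linkS4class{RamanTimeSeries}
#' @param window (low, high) shift window (1/cm) around the peak
#' @param baselineAnchors optional anchor regions; when given, each delay's
#'   spectrum is baseline-subtracted with \code{\link{fitBaseline}} first
#' @param label free text
#' @return a \linkS4class{TimeTrace} (window unit 1/cm)
#' @export
peakTrace <- function(series, window, baselineAnchors = NULL, label = "") {
  stopifnot(is(series, "RamanTimeSeries"))
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be (low, high) with low < high")
  sh <- series@shift
  sel <- sh >= window[1] & sh <= window[2]
  if (sum(sel) < 2) stop("window does not cover at least two grid points")
  vals <- series@values
  if (!is.null(baselineAnchors)) {
    for (i in seq_len(nrow(vals))) {
      sp <- ramanSpectrum(sh, vals[i, ], pumpNm = series@pumpNm,
                          side = series@side, delay = series@delays[i])
      vals[i, ] <- subtractBaseline(sp, fitBaseline(sp, baselineAnchors))@gain
    }
  }
  xs <- sh[sel]
  ys <- vals[, sel, drop = FALSE]
  w <- diff(xs)
  integ <- as.numeric(ys[, -1, drop = FALSE] %*% w +
                        ys[, -ncol(ys), drop = FALSE] %*% w) / 2
  timeTrace(series@delays, integ, window = window, windowUnit = "cm-1",
            label = label)
}
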