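## Steady-state band metrics: peak wavelengths, Stokes shifts, intensity
## ratios, isosbestic-point detection, and two-state titration fits.

#' Peak wavelength with parabolic refinement
#'
#' Wavelength of the maximum intensity inside a search window, refined by a
#' parabola through the three samples around the grid maximum (printed peak
#' wavelengths are typically 1 nm resolution, so sub-grid refinement
#' matters).
#'
#' @param spectrum a \linkS4class{Spectrum1D}
#' @param window (low, high) search window (nm); default: whole axis
#' @param refine apply 3-point parabolic interpolation (default TRUE)
#' @return peak wavelength (nm)
#' @export
peakWavelength <- function(spectrum, window = NULL, refine = TRUE) {
  stopifnot(is(spectrum, "Spectrum1D"))
  ax <- spectrum@axis; y <- spectrum@intensity
  if (!is.null(window)) {
    sel <- ax >= window[1] & ax <= window[2]
    if (!any(sel)) stop("window does not overlap the axis")
    ax <- ax[sel]; y <- y[sel]
  }
  if (diff(range(y)) < 1e-12 * max(1, max(abs(y))))
    stop("flat spectrum in window: no peak")
  i <- which.max(y)
  if (!refine || i == 1L || i == length(y)) return(ax[i])
  ## parabola through the three highest samples around the maximum
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < 1e-15) return(ax[i])
  delta <- 0.5 * (y1 - y3) / denom
  ax[i] + delta * (ax[i + 1] - ax[i])
}

#' Stokes shift in nm and eV
#'
#' nm shift = lambda_em - lambda_abs; energy shift =
#' hc (1/lambda_abs - 1/lambda_em) with hc = 1239.84 eV nm (1240 gives the
#' same values at the 2-decimal reporting precision). Values are rounded
#' only at reporting. A negative shift is allowed and flagged anti-Stokes.
#'
#' @param lambdaAbs absorption peak (nm)
#' @param lambdaEm emission peak (nm)
#' @param hc energy conversion constant (eV nm)
#' @return list with \code{nm}, \code{eV}, and \code{antiStokes} flag
#' @examples
#' stokesShift(481, 587)  # ~0.47 eV, the calcium-bound ESPT product
#' stokesShift(446, 511)  # ~0.35 eV, protonated form
#' stokesShift(446, 613)  # ~0.76 eV, deprotonated form
#' @export
stokesShift <- function(lambdaAbs, lambdaEm, hc = 1239.84) {
  if (lambdaAbs <= 0 || lambdaEm <= 0) stop("wavelengths must be positive")
  nm <- lambdaEm - lambdaAbs
  eV <- hc * (1 / lambdaAbs - 1 / lambdaEm)
  list(nm = nm, eV = eV, antiStokes = nm < 0)
}

#' Band intensity ratio in percent
#'
#' 100 |a| / |b|, reported to the nearest percent (the convention used when
#' comparing stimulated-emission and excited-state-absorption magnitudes
#' in mOD).
#'
#' @param a,b signal magnitudes (signs ignored); b must be nonzero
#' @return ratio in percent, rounded to the nearest integer
#' @examples
#' bandRatio(14, 36)   # 39
#' bandRatio(18, 28)   # 64
#' @export
bandRatio <- function(a, b) {
  if (b == 0) stop("zero denominator")
  round(100 * abs(a) / abs(b))
}

#' Locate an isosbestic point in a titration series
#'
#' Finds the wavelength minimizing the across-pH intensity spread inside a
#' window. A clear isosbestic point requires the minimum relative spread to
#' stay below \code{tol} (default 2% of the mean in-window intensity);
#' otherwise the series is flagged as having no clear isosbestic point.
#'
#' @param series a \linkS4class{TitrationSeries} with >= 3 spectra
#' @param window (low, high) search window (nm); default: whole axis
#' @param tol relative-spread tolerance for a "clear" isosbestic point
#' @return list: \code{wavelength}, \code{spread} (max-min at the crossing),
#'   \code{relSpread}, \code{isosbestic} (logical), \code{degenerate}
#'   (TRUE when all spectra coincide everywhere)
#' @export
findIsosbestic <- function(series, window = NULL, tol = 0.02) {
  stopifnot(is(series, "TitrationSeries"))
  if (length(series@pH) < 3) stop("at least 3 spectra required")
  ax <- series@axis; V <- series@values
  if (!is.null(window)) {
    sel <- ax >= window[1] & ax <= window[2]
    if (!any(sel)) stop("window does not overlap the axis")
    ax <- ax[sel]; V <- V[, sel, drop = FALSE]
  }
  spread <- apply(V, 2, function(col) diff(range(col)))
  meanInt <- mean(abs(V))
  if (meanInt < 1e-15) meanInt <- 1e-15
  if (all(spread < 1e-12 * max(1, meanInt)))
    return(list(wavelength = NA_real_, spread = 0, relSpread = 0,
                isosbestic = TRUE, degenerate = TRUE))
  ## a crossing at negligible intensity (band-free tails) is not isosbestic:
  ## restrict to pixels carrying at least 5% of the maximum mean intensity
  perPix <- colMeans(abs(V))
  keep <- perPix >= 0.05 * max(perPix)
  if (!any(keep)) stop("window without appreciable intensity")
  spread[!keep] <- Inf
  i <- which.min(spread)
  rel <- spread[i] / meanInt
  list(wavelength = ax[i], spread = spread[i], relSpread = rel,
       isosbestic = rel <= tol, degenerate = FALSE)
}

#' Fit a two-state (Henderson--Hasselbalch) model to a titration series
#'
#' Decomposes intensity(lambda, pH) = f(pH) acid(lambda) +
#' (1 - f(pH)) base(lambda) with f = 1 / (1 + 10^(pH - pKa)). For a fixed
#' pKa the two spectra are the linear least-squares solution; the pKa itself
#' is found by one-dimensional minimization of the residual sum of squares.
#'
#' @param series a \linkS4class{TitrationSeries} with >= 3 pH points spanning
#'   the transition
#' @return list: \code{pKa}, \code{acid} and \code{base}
#'   (\linkS4class{Spectrum1D}), \code{rss}, \code{fractions} (acid fraction
#'   per pH)
#' @export
fitTwoState <- function(series) {
  stopifnot(is(series, "TitrationSeries"))
  pH <- series@pH
  if (length(unique(pH)) < 3)
    stop("at least 3 distinct pH points are required")
  V <- series@values
  rssAt <- function(pKa) {
    f <- 1 / (1 + 10^(pH - pKa))
    F <- cbind(acid = f, base = 1 - f)
    if (qr(F)$rank < 2) return(Inf) # all pH on one side: rank-deficient
    S <- qr.coef(qr(F), V)
    sum((V - F %*% S)^2)
  }
  opt <- stats::optimize(rssAt, interval = range(pH) + c(-2, 2), tol = 1e-6)
  pKa <- opt$minimum
  f <- 1 / (1 + 10^(pH - pKa))
  F <- cbind(f, 1 - f)
  if (qr(F)$rank < 2)
    stop("rank-deficient series: all pH points lie on one side of the pKa")
  S <- qr.coef(qr(F), V)
  list(pKa = pKa,
       acid = spectrum1D(series@axis, S[1, ], "absorption", "acid form"),
       base = spectrum1D(series@axis, S[2, ], "absorption", "base form"),
       rss = opt$objective, fractions = f)
}
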