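## Probe-band time traces and IRF-convolved multi-exponential fits with
## rise/decay classification and absolute-amplitude percentage weights.

#' Integrate a probe band into a time trace
#'
#' Mean (not sum) of the signal across in-window pixels at every delay, so
#' traces are invariant to the window width; the sign is preserved.
#'
#' @param x a \linkS4class{SpectralMatrix} or \linkS4class{RamanTimeSeries}
#' @param window two-element (low, high) window on the spectral axis
#'   (nm or 1/cm)
#' @param label free text for the trace
#' @return a \linkS4class{TimeTrace}
#' @examples
#' p <- caFreePreset()
#' ta <- simulateTA(p$scheme, p$bands)
#' se <- integrateBand(ta, c(581, 604))  # stimulated-emission band
#' @export
integrateBand <- function(x, window, label = "") {
  ai <- .axisInfo(x)
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be (low, high) with low < high")
  sel <- ai$axis >= window[1] & ai$axis <= window[2]
  if (!any(sel)) stop("window does not overlap the spectral axis")
  timeTrace(ai$times, rowMeans(ai$values[, sel, drop = FALSE]),
            window = window, windowUnit = ai$unit, label = label)
}

#' Fit an IRF-convolved multi-exponential to a time trace
#'
#' intensity(t) = sum_i a_i convolvedExponential(t, 1/tau_i, irf) (+ offset).
#' Amplitudes are solved linearly at each lifetime step (variable
#' projection). Component weights are absolute-amplitude shares
#' (100 |a_i| / sum |a_j|), and a component is labeled a rise when its
#' amplitude sign opposes the dominant sign of the trace.
#'
#' @param trace a \linkS4class{TimeTrace} with at least 3n points
#' @param n number of exponential components
#' @param irf \linkS4class{IRFModel}; fixed during the fit
#' @param offset include a constant offset term (default off: the probe
#'   window commonly truncates the longest component, which absorbs any
#'   apparent baseline)
#' @param initTaus starting lifetimes (ps); default log-spaced across the
#'   time window
#' @param maxIter Levenberg-Marquardt iteration cap
#' @return a \linkS4class{TraceFitResult}
#' @examples
#' tt <- simulateTrace(c(0.75, 3, 440), c(-0.44, 0.16, -0.40),
#'                     times = defaultDelayGrid(100))
#' fitMultiexp(tt, 3)
#' @export
fitMultiexp <- function(trace, n, irf = irfModel(), offset = FALSE,
                        initTaus = NULL, maxIter = 200) {
  stopifnot(is(trace, "TimeTrace"))
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  times <- trace@times
  y <- trace@intensity
  if (length(times) < 3 * n) stop("trace must have at least 3n points")
  if (is.null(initTaus)) {
    ## multi-start: a handful of deterministic log-spaced ladders; the
    ## lowest-RMSE fit wins (guards against coalesced-lifetime minima with
    ## canceling amplitudes)
    lo <- max(irf@fwhm / 2, min(diff(times)))
    hi <- max(times) / 3
    starts <- list(exp(seq(log(lo), log(hi), length.out = max(n, 2)))[seq_len(n)],
                   exp(seq(log(lo * 4), log(hi / 4),
                           length.out = max(n, 2)))[seq_len(n)],
                   hi * 10^-(rev(seq_len(n)) - 1),
                   hi / 3 * 10^-(rev(seq_len(n)) - 1))
    starts <- unique(lapply(starts, function(s) signif(sort(s), 6)))
    fits <- lapply(starts, function(s)
      fitMultiexp(trace, n, irf = irf, offset = offset, initTaus = s,
                  maxIter = maxIter))
    score <- vapply(fits, function(f) {
      pen <- if (!f@converged) 1e6 else 0
      if (any(grepl("canceling", f@notes))) pen <- pen + 1e3
      f@rmse * (1 + pen)
    }, numeric(1))
    return(fits[[which.min(score)]])
  }
  if (length(initTaus) != n || any(initTaus <= 0))
    stop("initTaus must be ", n, " positive values")
  lowTau <- 0.01                 # 10 fs
  highTau <- 1e4                 # 10 ns
  par <- log(pmin(pmax(initTaus, lowTau), highTau))

  design <- function(taus) {
    C <- .expBasis(times, taus, irf)
    if (offset) cbind(C, 1) else C
  }
  resfun <- function(p) .project(design(exp(p)), cbind(y))$res[, 1]
  fit <- minpack.lm::nls.lm(par, lower = rep(log(lowTau), n),
                            upper = rep(log(highTau), n), fn = resfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxIter, ftol = 1e-12, ptol = 1e-10))
  converged <- fit$info %in% 1:4
  notes <- character(0)
  if (!converged) notes <- c(notes, paste0("optimizer did not converge (info=",
                                           fit$info, ")"))
  taus <- exp(fit$par)
  atBound <- taus < lowTau * 1.0001 | taus > highTau * 0.9999
  if (any(atBound))
    notes <- c(notes, paste0("lifetime(s) collapsed to the search bounds: ",
                             paste(signif(taus[atBound], 3), collapse = ", "),
                             " ps"))
  ord <- order(taus)
  taus <- taus[ord]
  pj <- .project(design(taus), cbind(y))
  coefs <- pj$S[, 1]
  if (n > 1) {
    aa <- coefs[seq_len(n)]
    close <- which(diff(log(taus)) < log(1.05))
    for (i in close) if (aa[i] * aa[i + 1] < 0 &&
                         min(abs(aa[c(i, i + 1)])) > 2 * diff(range(y)))
      notes <- c(notes, paste0("coalesced lifetimes near ", signif(taus[i], 3),
                               " ps with large canceling amplitudes: ",
                               "degenerate local minimum"))
  }
  a <- coefs[seq_len(n)]
  off <- if (offset) coefs[n + 1] else 0
  dominant <- sign(y[which.max(abs(y))])
  cmp <- data.frame(
    tau = taus, amplitude = a,
    weightPercent = 100 * abs(a) / sum(abs(a)),
    kind = ifelse(sign(a) == dominant | a == 0, "decay", "rise"))
  new("TraceFitResult", components = cmp, irfFit = irf, offset = off,
      rmse = sqrt(mean(pj$res^2)), converged = converged, notes = notes)
}

#' Weighted average lifetime of fitted components
#'
#' \eqn{\sum w_i \tau_i / \sum w_i} over the selected component subset.
#'
#' @param fit a \linkS4class{TraceFitResult}
#' @param subset "all", "rise" or "decay"
#' @return weighted mean lifetime (ps)
#' @examples
#' ## a biexponential rise of 350 fs and 3 ps with amplitudes weighted
#' ## ~68:32 averages to ~1.2 ps
#' @export
weightedAverageTau <- function(fit, subset = c("all", "rise", "decay")) {
  subset <- match.arg(subset)
  cmp <- fit@components
  if (subset != "all") cmp <- cmp[cmp$kind == subset, , drop = FALSE]
  if (!nrow(cmp)) stop("no components in subset '", subset, "'")
  sum(cmp$weightPercent * cmp$tau) / sum(cmp$weightPercent)
}

#' Evaluate the fitted multi-exponential model
#'
#' @param result a \linkS4class{TraceFitResult}
#' @param times delay grid (ps)
#' @return a \linkS4class{TimeTrace} of the model curve
#' @export
setMethod("reconstruct", "TraceFitResult", function(result, times) {
  cmp <- result@components
  simulateTrace(cmp$tau, cmp$amplitude, times, irf = result@irfFit,
                offset = result@offset, label = "trace fit")
})
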