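# Independent numerical oracles, deliberately implemented through different
# routes than the package code paths they validate.

# Brute-force numerical convolution of exp(-k t) * step(t) with a unit-area
# Gaussian, trapezoidal rule on a 0.1 fs grid.
numericalConvolutionOracle <- function(t, k, fwhm, t0 = 0, dt = 1e-4) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  vapply(t, function(ti) {
    hi <- ti - t0 + 8 * sigma
    if (hi <= 0) return(0)
    u <- seq(0, hi, by = dt) # integrand smooth on u >= 0: O(dt^2) trapezoid
    w <- exp(-k * u) * dnorm(ti - u, t0, sigma)
    sum((w[-1] + w[-length(w)]) / 2) * dt
  }, numeric(1))
}

# Impulse response of dc/dt = K c by classical Runge-Kutta on a fine grid,
# then numerical convolution with the Gaussian IRF. Independent of the
# eigen-decomposition closed form and of the lsoda source-term fallback.
odeConvolutionOracle <- function(K, c0, times, fwhm, t0 = 0, dt = 1e-3) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  tEnd <- max(times) + 8 * sigma
  n <- ceiling(tEnd / dt)
  imp <- matrix(0, n + 1, length(c0))
  imp[1, ] <- c0
  y <- c0
  f <- function(y) as.numeric(K %*% y)
  for (i in seq_len(n)) { # RK4
    k1 <- f(y); k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2); k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    imp[i + 1, ] <- y
  }
  tImp <- seq(0, n * dt, by = dt)
  vapply(seq_along(c0), function(j) {
    fj <- approxfun(tImp, imp[, j], yleft = 0, yright = 0)
    vapply(times, function(ti) {
      u <- seq(max(0, ti - t0 - 8 * sigma), ti - t0 + 8 * sigma, by = dt)
      u <- u[u >= 0]
      if (!length(u)) return(0)
      w <- fj(u) * dnorm(ti - t0 - u, 0, sigma)
      sum((w[-1] + w[-length(w)]) / 2) * dt
    }, numeric(1))
  }, numeric(length(times)))
}

# Closed-form crossing of two Gaussian bands (equal-extinction wavelength),
# solved on the segment between the two centers.
gaussianCrossingOracle <- function(acid, base) {
  s1 <- acid$fwhm / (2 * sqrt(2 * log(2)))
  s2 <- base$fwhm / (2 * sqrt(2 * log(2)))
  f <- function(l) acid$amplitude * exp(-(l - acid$center)^2 / (2 * s1^2)) -
    base$amplitude * exp(-(l - base$center)^2 / (2 * s2^2))
  uniroot(f, c(acid$center, base$center), tol = 1e-10)$root
}

# Moment-based center and FWHM estimators for a single peak.
momentEstimators <- function(shift, gain) {
  w <- abs(gain) / sum(abs(gain))
  mu <- sum(w * shift)
  sd <- sqrt(sum(w * (shift - mu)^2))
  c(center = mu, fwhm = 2 * sqrt(2 * log(2)) * sd)
}

gaussCurve <- function(x, center, fwhm, amplitude) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(x - center)^2 / (2 * s^2))
}
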