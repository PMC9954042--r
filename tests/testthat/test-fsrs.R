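test_that("anti-Stokes axis normalization flips sign, reorders, and is idempotent", {
  raw <- ramanSpectrum(seq(-1800, -900, by = 2),
                       sin(seq_len(451) / 20), pumpNm = 650)
  norm <- normalizeShiftAxis(raw)
  expect_equal(ramanShift(norm), seq(900, 1800, by = 2))
  expect_equal(signalValues(norm), rev(signalValues(raw)))
  again <- normalizeShiftAxis(norm)
  expect_equal(ramanShift(again), ramanShift(norm))
  expect_equal(signalValues(again), signalValues(norm))
  mixed <- ramanSpectrum(seq(-100, 100, by = 2), rnorm(101))
  expect_error(normalizeShiftAxis(mixed), "ambiguous")
})

test_that("wavenumber bookkeeping between pump, shift and probe is exact", {
  expect_equal(probeWavelength(650, 1641), 1e7 / (1e7 / 650 + 1641))
  expect_lt(probeWavelength(650, 1641), 650) # anti-Stokes probe is bluer
  expect_gt(probeWavelength(650, 1641, "stokes"), 650)
  # round trip: probe wavenumber minus pump wavenumber returns the shift
  lam <- probeWavelength(650, 1385)
  expect_equal(1e7 / lam - 1e7 / 650, 1385, tolerance = 1e-9)
})

test_that("a flat baseline under peaks is recovered within 2% of the peak height", {
  grid <- seq(900, 1800, by = 2)
  peaks <- gaussCurve(grid, 1385, 22, -0.45) + gaussCurve(grid, 1641, 24, -0.4)
  sp <- ramanSpectrum(grid, peaks + 0.1)
  anchors <- list(c(900, 1000), c(1150, 1250), c(1450, 1550), c(1700, 1800))
  bl <- fitBaseline(sp, anchors, peakWindows = list(c(1340, 1430),
                                                    c(1590, 1690)))
  expect_lt(max(abs(bl@curve - 0.1)), 0.02 * 0.45)
  # zero spectrum: zero baseline
  z <- ramanSpectrum(grid, rep(0, length(grid)))
  expect_equal(max(abs(fitBaseline(z, anchors)@curve)), 0)
  expect_error(fitBaseline(sp, anchors[1:3]), "at least 4")
  expect_error(fitBaseline(sp, list(c(1380, 1400), c(900, 950), c(1450, 1500),
                                    c(1700, 1800)),
                           peakWindows = list(c(1340, 1430))),
               "peak window")
  expect_warning(fitBaseline(sp, list(c(1200, 1230), c(1250, 1280),
                                      c(1440, 1470), c(1470, 1500))),
                 "unanchored")
})

test_that("an SE-shaped baseline from the forward model is recovered to the noise level", {
  p <- caBoundPreset()
  sigma <- 0.003
  fs <- simulateFSRS(p$scheme, p$ramanPeaks, p$baselineBand,
                     delays = c(1, 10), noiseSigma = sigma, seed = 21)
  fs0 <- simulateFSRS(p$scheme, p$ramanPeaks, baselineBand = NULL,
                      delays = c(1, 10))
  anchors <- list(c(900, 1000), c(1080, 1140), c(1220, 1250), c(1420, 1480),
                  c(1560, 1600), c(1700, 1800))
  sp <- ramanSpectrum(ramanShift(fs), signalValues(fs)[2, ])
  bl <- fitBaseline(sp, anchors)
  clean <- subtractBaseline(sp, bl)
  # residual against the known peak-only truth, away from band edges
  resid <- signalValues(clean) - signalValues(fs0)[2, ]
  inner <- ramanShift(fs) > 950 & ramanShift(fs) < 1750
  expect_lt(sqrt(mean(resid[inner]^2)), 3 * sigma)
})

test_that("baseline subtraction is exact pointwise arithmetic", {
  grid <- seq(900, 1800, 2)
  sp <- ramanSpectrum(grid, rnorm(length(grid)))
  zero <- new("RamanBaseline", knots = cbind(c(900, 1800), c(0, 0)),
              curve = rep(0, length(grid)), shift = grid, method = "zero")
  expect_equal(signalValues(subtractBaseline(sp, zero)), signalValues(sp))
  self <- new("RamanBaseline", knots = cbind(grid[c(1, 10)], 0),
              curve = signalValues(sp), shift = grid, method = "self")
  expect_equal(max(abs(signalValues(subtractBaseline(sp, self)))), 0)
  other <- new("RamanBaseline", knots = cbind(c(900, 1800), c(0, 0)),
               curve = rep(0, 10), shift = grid[1:10], method = "zero")
  expect_error(subtractBaseline(sp, other), "grid mismatch")
})

test_that("excited-minus-ground subtraction handles raw pairs", {
  grid <- seq(900, 1800, 2)
  gs <- ramanSpectrum(grid, gaussCurve(grid, 1631, 20, 0.3))
  es <- ramanSpectrum(grid, gaussCurve(grid, 1631, 20, 0.3) +
                        gaussCurve(grid, 1641, 24, -0.4), delay = 1)
  diffSp <- subtractGroundState(es, gs)
  expect_equal(signalValues(diffSp), gaussCurve(grid, 1641, 24, -0.4))
})

test_that("a single noiseless Gaussian peak is recovered exactly", {
  grid <- seq(900, 1800, by = 2)
  sp <- ramanSpectrum(grid, gaussCurve(grid, 1641, 18, -0.4))
  pk <- fitPeaks(sp, 1641, window = 50, initFwhm = 15)
  expect_equal(pk$center, 1641, tolerance = 1e-6)
  expect_equal(pk$fwhm, 18, tolerance = 1e-6)
  expect_equal(pk$amplitude, -0.4, tolerance = 1e-6)
  expect_true(pk$converged)
})

test_that("ground- vs excited-state peak centers resolve a 10 1/cm blue shift", {
  grid <- seq(1500, 1750, by = 2)
  set.seed(31)
  gs <- ramanSpectrum(grid, gaussCurve(grid, 1631, 22, 0.5) +
                        rnorm(length(grid), sd = 0.005))
  es <- ramanSpectrum(grid, gaussCurve(grid, 1641, 24, -0.4) +
                        rnorm(length(grid), sd = 0.005))
  cGS <- fitPeaks(gs, 1630, window = 60)$center
  cES <- fitPeaks(es, 1645, window = 60)$center
  expect_equal(cES - cGS, 10, tolerance = 1)
})

test_that("two overlapping Gaussians separated by 0.8 fwhm keep their areas within 5%", {
  grid <- seq(1200, 1500, by = 1)
  a1 <- -0.5; a2 <- -0.3; fw <- 25
  truth <- gaussCurve(grid, 1340, fw, a1) + gaussCurve(grid, 1340 + 0.8 * fw, fw, a2)
  pk <- fitPeaks(ramanSpectrum(grid, truth), c(1338, 1362), window = 35,
                 initFwhm = 20)
  areaOf <- function(a, f) a * f * sqrt(2 * pi) / (2 * sqrt(2 * log(2)))
  expect_lt(abs(pk$area[1] - areaOf(a1, fw)) / abs(areaOf(a1, fw)), 0.05)
  expect_lt(abs(pk$area[2] - areaOf(a2, fw)) / abs(areaOf(a2, fw)), 0.05)
})

test_that("peak fits agree with moment estimators on noiseless single peaks", {
  grid <- seq(1000, 1300, by = 2)
  y <- gaussCurve(grid, 1185, 18, -0.2)
  pk <- fitPeaks(ramanSpectrum(grid, y), 1180, window = 60)
  mom <- momentEstimators(grid, y)
  expect_lt(abs(pk$center - mom["center"]), 0.5)
  expect_lt(abs(pk$fwhm - mom["fwhm"]), 0.5)
})

test_that("marker-band traces report the photocycle dynamics they were built from", {
  anchors <- list(c(900, 1000), c(1120, 1160), c(1420, 1480), c(1700, 1800))
  # calcium-free 1350 marker rises with the dark-state formation time
  q <- caFreePreset()
  fsQ <- simulateFSRS(q$scheme, q$ramanPeaks, q$baselineBand,
                      noiseSigma = 0.002, seed = 13)
  trQ <- peakTrace(fsQ, c(1310, 1390), baselineAnchors = anchors)
  fitQ <- fitMultiexp(trQ, 2, irf = irfModel(140, unit = "fs"))
  cmp <- traceComponents(fitQ)
  expect_equal(cmp$kind[1], "rise")
  expect_gt(cmp$tau[1], 1)   # dark-state rise on the few-ps timescale
  expect_lt(cmp$tau[1], 3.5)
  # calcium-bound 1641 marker is already nonzero one IRF sigma after t0
  p <- caBoundPreset()
  fsP <- simulateFSRS(p$scheme, p$ramanPeaks, baselineBand = NULL,
                      delays = c(-0.3, 0.0593, 0.5, 3, 10))
  trP <- peakTrace(fsP, c(1600, 1680))
  expect_gt(abs(signalValues(trP)[2]), 1e-3)
  # zero-amplitude peaks give a zero trace
  none <- q$ramanPeaks
  none$amplitude <- 0
  fs0 <- simulateFSRS(q$scheme, none, baselineBand = NULL, delays = c(1, 10))
  expect_equal(max(abs(signalValues(peakTrace(fs0, c(1310, 1390))))), 0)
  expect_error(peakTrace(fsQ, c(100, 200)), "window")
})

test_that("baseline + peak-fit closure recovers areas within 5% at 1% noise", {
  grid <- seq(900, 1800, by = 2)
  amps <- c(-0.45, -0.4)
  centers <- c(1385, 1641)
  fwhms <- c(22, 24)
  base <- gaussCurve(grid, 1650, 1800, -1.2) # broad SE-like background
  set.seed(17)
  y <- base + gaussCurve(grid, centers[1], fwhms[1], amps[1]) +
    gaussCurve(grid, centers[2], fwhms[2], amps[2]) +
    rnorm(length(grid), sd = 0.01 * max(abs(amps)))
  sp <- ramanSpectrum(grid, y)
  anchors <- list(c(900, 1000), c(1050, 1150), c(1200, 1300), c(1460, 1500),
                  c(1510, 1560), c(1715, 1760), c(1760, 1800))
  clean <- subtractBaseline(sp, fitBaseline(sp, anchors))
  pk <- fitPeaks(clean, centers, window = 45)
  want <- amps * fwhms * sqrt(2 * pi) / (2 * sqrt(2 * log(2)))
  expect_lt(max(abs(pk$area - want) / abs(want)), 0.05)
})
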