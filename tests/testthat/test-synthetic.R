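test_that("simulation is bit-reproducible for equal seeds and parameters", {
  p <- caBoundPreset()
  a <- simulateTA(p$scheme, p$bands, noiseSigma = 0.3, seed = 9)
  b <- simulateTA(p$scheme, p$bands, noiseSigma = 0.3, seed = 9)
  c <- simulateTA(p$scheme, p$bands, noiseSigma = 0.3, seed = 10)
  expect_identical(signalValues(a), signalValues(b))
  expect_false(identical(signalValues(a), signalValues(c)))
  f1 <- simulateFSRS(p$scheme, p$ramanPeaks, p$baselineBand,
                     noiseSigma = 0.01, seed = 4)
  f2 <- simulateFSRS(p$scheme, p$ramanPeaks, p$baselineBand,
                     noiseSigma = 0.01, seed = 4)
  expect_identical(signalValues(f1), signalValues(f2))
})

test_that("noiseless single-species, single-band output is a rank-1 outer product", {
  sch <- buildSequential(10, species = "X")
  bands <- data.frame(species = "X", center = 550, fwhm = 40, amplitude = -5)
  ta <- simulateTA(sch, bands, times = defaultDelayGrid(100),
                   wavelengths = seq(480, 620, 2))
  sv <- svd(signalValues(ta))$d
  expect_lt(sv[2] / sv[1], 1e-12)
})

test_that("noiseless matrices lie in the span of the concentration profiles", {
  p <- caFreePreset()
  ta <- simulateTA(p$scheme, p$bands)
  C <- signalValues(solveConcentrations(p$scheme, delayTimes(ta),
                                        irfModel(140, unit = "fs")))
  D <- signalValues(ta)
  resid <- D - C %*% qr.coef(qr(C), D)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("the forward model is linear in the band amplitudes", {
  p <- caBoundPreset()
  doubled <- p$bands
  doubled$amplitude <- 2 * doubled$amplitude
  a <- simulateTA(p$scheme, p$bands)
  b <- simulateTA(p$scheme, doubled)
  expect_equal(2 * signalValues(a), signalValues(b))
})

test_that("a linear probe chirp shifts the time zero of the bluest pixel as constructed", {
  sch <- buildSequential(50, species = "X")
  bands <- data.frame(species = "X", center = 560, fwhm = 200, amplitude = 10)
  wl <- seq(420, 700, 20)
  tt <- seq(-1, 1, 0.01)
  # chirp referenced to the reddest pixel: 50 fs across the 280 nm window
  ta <- simulateTA(sch, bands, times = tt, wavelengths = wl,
                   chirp = c(0, -0.05 / 2.8))
  t50 <- function(col) approx(col / max(col), tt, xout = 0.5)$y
  tBlue <- t50(signalValues(ta)[, 1])
  tRed <- t50(signalValues(ta)[, length(wl)])
  expect_equal(tBlue - tRed, 0.05, tolerance = 1e-3)
  expect_error(simulateTA(sch, data.frame(species = "Y", center = 500,
                                          fwhm = 10, amplitude = 1)),
               "unknown species")
})

test_that("the calcium-bound preset carries the published spectral landmarks", {
  p <- caBoundPreset()
  expect_equal(p$lifetimes, c(3, 71, 1100))
  se <- p$bands[p$bands$feature == "SE", ]
  expect_true(all(se$center == 587) && all(se$amplitude < 0))
  esa <- p$bands[p$bands$feature == "ESA", ]
  expect_true(all(esa$center == 529) && all(esa$amplitude > 0))
  gsb <- p$bands[p$bands$feature == "GSB", ]
  expect_true(all(gsb$center == 447) && all(gsb$amplitude < 0))
  # 1641 marker attached to the post-ESPT species only
  m <- p$ramanPeaks[p$ramanPeaks$center == 1641, ]
  expect_equal(m$amplitude[m$species == "A*"], 0)
  expect_true(all(m$amplitude[m$species != "A*"] < 0))
  # 1385 is a shared reactant-product mode present on every species
  s <- p$ramanPeaks[p$ramanPeaks$center == 1385, ]
  expect_true(all(s$amplitude < 0))
  expect_setequal(unique(p$ramanPeaks$center),
                  c(1185, 1277, 1332, 1385, 1515, 1641))
  # branched target variant keeps an adjustable sub-IRF ESPT channel
  tg <- caBoundPreset("target", subIrfTau = 0.08)
  expect_equal(rateMatrix(tg$scheme)["I*", "A*"], 1 / 0.08 + 1 / 0.35 + 1 / 3)
})

test_that("the calcium-free preset carries the dark-state landmarks", {
  p <- caFreePreset()
  expect_equal(p$lifetimes, c(2, 44, 330))
  expect_equal(unname(p$absPeaks), c(446, 581))
  expect_equal(unname(p$emPeaks["B"]), 613)
  se <- p$bands[p$bands$feature == "SE", ]
  expect_true(all(se$center == 613))
  # SE sits on the bright B* state and decays along the chain
  expect_true(which.max(abs(se$amplitude)) == which(se$species == "B*"))
  # rising dark-state Raman markers are absent from the bright state
  for (ctr in c(1070, 1350)) {
    m <- p$ramanPeaks[p$ramanPeaks$center == ctr, ]
    expect_equal(m$amplitude[m$species == "B*"], 0)
    expect_true(all(m$amplitude[m$species != "B*"] < 0))
  }
  # 1628 decays from the bright state
  d <- p$ramanPeaks[p$ramanPeaks$center == 1628, ]
  expect_true(abs(d$amplitude[d$species == "B*"]) ==
                max(abs(d$amplitude)))
})

test_that("FSRS simulation is flat before time zero and tracks populations by construction", {
  p <- caBoundPreset()
  fs <- simulateFSRS(p$scheme, p$ramanPeaks, p$baselineBand,
                     delays = c(-0.5, -0.4, 0.5, 3, 30))
  expect_lt(max(abs(signalValues(fs)[1, ])), 1e-8)
  # the 1641 trace equals the I* + I*rel populations weighted by the fixed
  # band integrals (baseline off to isolate the peaks)
  fs2 <- simulateFSRS(p$scheme, p$ramanPeaks, baselineBand = NULL,
                      delays = c(0.5, 3, 30, 300))
  tr <- peakTrace(fs2, c(1590, 1692))
  conc <- signalValues(solveConcentrations(p$scheme, delayTimes(fs2),
                                           irfModel(140, unit = "fs")))
  m <- p$ramanPeaks[p$ramanPeaks$center == 1641, ]
  sgrid <- ramanShift(fs2)
  sel <- sgrid >= 1590 & sgrid <= 1692
  unitArea <- function(amp) {
    y <- gaussCurve(sgrid, 1641, 24, amp)[sel]
    sum((y[-1] + y[-length(y)]) / 2 * diff(sgrid[sel]))
  }
  want <- conc[, "I*"] * unitArea(m$amplitude[m$species == "I*"]) +
    conc[, "I*rel"] * unitArea(m$amplitude[m$species == "I*rel"])
  expect_equal(signalValues(tr), want, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("baseline-only FSRS simulation is fully removed by baseline subtraction", {
  p <- caFreePreset()
  noPeaks <- p$ramanPeaks
  noPeaks$amplitude <- 0
  fs <- simulateFSRS(p$scheme, noPeaks, p$baselineBand, delays = c(1, 10))
  anchors <- list(c(900, 960), c(1150, 1250), c(1400, 1500), c(1700, 1800))
  for (i in 1:2) {
    sp <- ramanSpectrum(ramanShift(fs), signalValues(fs)[i, ])
    cl <- subtractBaseline(sp, fitBaseline(sp, anchors))
    expect_lt(max(abs(signalValues(cl))),
              0.02 * max(abs(signalValues(fs)[i, ])) + 1e-12)
  }
})

test_that("titration fractions follow Henderson-Hasselbalch and share one crossing", {
  acid <- list(center = 446, fwhm = 60, amplitude = 1)
  base <- list(center = 581, fwhm = 70, amplitude = 1.4)
  # pH = pKa: exactly half-half
  ser <- simulateTitration(6, acid, base, pH = c(6, 6))
  wl <- wavelengths(ser)
  want <- 0.5 * gaussCurve(wl, 446, 60, 1) + 0.5 * gaussCurve(wl, 581, 70, 1.4)
  expect_equal(signalValues(ser)[1, ], want)
  # pH far below pKa: the acid band alone
  ser2 <- simulateTitration(6, acid, base, pH = c(-4, 6))
  expect_equal(signalValues(ser2)[1, ], gaussCurve(wl, 446, 60, 1),
               tolerance = 1e-9)
  # every spectrum passes through the analytic equal-extinction point
  ser3 <- simulateTitration(6, acid, base, pH = c(3.5, 5, 6, 7.5, 9, 11))
  lam <- gaussianCrossingOracle(acid, base)
  at <- apply(signalValues(ser3), 1, function(row)
    approx(wavelengths(ser3), row, xout = lam)$y)
  expect_lt(diff(range(at)), 1e-4) # limited by linear interp on the 1 nm grid
  # disjoint bands are flagged
  expect_warning(simulateTitration(6, list(center = 420, fwhm = 8, amplitude = 1),
                                   list(center = 690, fwhm = 8, amplitude = 1)),
                 "isosbestic")
})
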