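test_that("convolved exponential reduces to the step-gated decay at zero IRF width", {
  expect_equal(convolvedExponential(1, 0.5, irfModel(0)), exp(-0.5))
  expect_equal(convolvedExponential(0, 0.5, irfModel(0)), 0.5)
  expect_equal(convolvedExponential(-0.3, 2, irfModel(0)), 0)
  # zero-IRF limit: shrinking fwhm converges pointwise away from t0
  t <- c(-0.5, 0.2, 1, 5)
  for (fwhm in c(0.1, 0.01, 0.001)) {
    err <- abs(convolvedExponential(t, 1 / 3, irfModel(fwhm)) -
                 convolvedExponential(t, 1 / 3, irfModel(0)))
    expect_lt(max(err), 3 * fwhm)
  }
})

test_that("half the IRF has arrived at t = t0 when k = 0", {
  expect_equal(convolvedExponential(0, 0, irfModel(140, unit = "fs")), 0.5)
  irf <- irfModel(200, t0 = 350, unit = "fs")
  expect_equal(convolvedExponential(0.35, 0, irf), 0.5)
})

test_that("analytic convolution matches the brute-force numerical oracle", {
  irf <- irfModel(140, unit = "fs")
  cases <- expand.grid(t = c(-0.2, 0, 0.2, 1, 5), k = c(1 / 3, 1 / 0.35, 0.1))
  for (i in seq_len(nrow(cases))) {
    expected <- numericalConvolutionOracle(cases$t[i], cases$k[i], 0.140)
    expect_lt(abs(convolvedExponential(cases$t[i], cases$k[i], irf) -
                    expected), 1e-6)
  }
})

test_that("extreme sigma^2 k products stay finite (log-space guard)", {
  irf <- irfModel(140, unit = "fs")
  v <- convolvedExponential(c(-1, 0, 1, 900), 1000, irf) # tau = 1 fs
  expect_true(all(is.finite(v)))
  expect_true(all(v >= 0 & v <= 1))
  expect_error(convolvedExponential(1, -0.1, irf), "k must be")
})

test_that("sequential schemes carry chain rates, sink closure and unit initial population", {
  sch <- buildSequential(c(3, 71, 1100))
  K <- rateMatrix(sch)
  expect_equal(diag(K), -c(1 / 3, 1 / 71, 1 / 1100), ignore_attr = TRUE)
  expect_equal(K[2, 1], 1 / 3)
  expect_equal(K[3, 2], 1 / 71)
  expect_equal(unname(sinkRates(sch)), c(0, 0, 1 / 1100))
  expect_equal(unname(initialPopulations(sch)), c(1, 0, 0))
  sch2 <- buildSequential(c(2, 44, 330))
  expect_equal(diag(rateMatrix(sch2)), -c(1 / 2, 1 / 44, 1 / 330),
               ignore_attr = TRUE)
  expect_error(buildSequential(numeric(0)), "at least one")
  expect_error(buildSequential(c(2, -1)), "positive")
})

test_that("a single-lifetime scheme is a plain exponential", {
  sch <- buildSequential(5)
  tt <- c(0.5, 2, 10)
  cm <- solveConcentrations(sch, tt, irfModel(0))
  expect_equal(as.numeric(signalValues(cm)), exp(-tt / 5))
})

test_that("target schemes assemble branched topologies and reject cycles", {
  edges <- data.frame(from = c("A*", "A*", "I*"),
                      to = c("I*", "I*", "ground"),
                      rate = c(1 / 0.35, 1 / 3, 1 / 1100))
  sch <- buildTarget(edges, initial = c("A*" = 1))
  K <- rateMatrix(sch)
  expect_equal(K["I*", "A*"], 1 / 0.35 + 1 / 3)
  expect_equal(K["A*", "A*"], -(1 / 0.35 + 1 / 3))
  expect_equal(unname(sinkRates(sch)["I*"]), 1 / 1100)
  expect_error(
    buildTarget(data.frame(from = c("A", "B"), to = c("B", "A"),
                           rate = c(1, 1)), initial = c(A = 1)),
    "cycle")
})

test_that("two parallel species each decaying to ground reproduce independent exponentials", {
  edges <- data.frame(from = c("P1", "P2"), to = c("ground", "ground"),
                      rate = c(1 / 2, 1 / 20))
  sch <- buildTarget(edges, initial = c(P1 = 0.6, P2 = 0.4))
  tt <- c(0.1, 1, 5, 30)
  cm <- solveConcentrations(sch, tt, irfModel(0))
  expect_equal(signalValues(cm)[, "P1"], 0.6 * exp(-tt / 2),
               ignore_attr = TRUE)
  expect_equal(signalValues(cm)[, "P2"], 0.4 * exp(-tt / 20),
               ignore_attr = TRUE)
})

test_that("populations match an independent RK4 + numerical-convolution oracle", {
  # branched calcium-bound topology incl. a sub-IRF ESPT channel
  edges <- data.frame(from = c("A*", "A*", "A*", "I*", "I*rel"),
                      to = c("I*", "I*", "I*", "I*rel", "ground"),
                      rate = c(1 / 0.1, 1 / 0.35, 1 / 3, 1 / 71, 1 / 1100))
  sch <- buildTarget(edges, initial = c("A*" = 1))
  tt <- c(-0.1, 0.05, 0.3, 1, 10)
  got <- signalValues(solveConcentrations(sch, tt, irfModel(140, unit = "fs")))
  want <- odeConvolutionOracle(rateMatrix(sch), initialPopulations(sch), tt,
                               0.140, dt = 2e-4)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("sequential population decays to completion and equal lifetimes hit the Bateman form", {
  sch <- buildSequential(c(2, 44, 330))
  cm <- solveConcentrations(sch, c(1, 10, 2000), irfModel(140, unit = "fs"))
  expect_lt(signalValues(cm)[3, 1], 1e-4)
  # degenerate chain: second species is (t/tau) exp(-t/tau) at zero IRF
  tau <- 7
  cm2 <- solveConcentrations(buildSequential(c(tau, tau)), c(1, 7, 30),
                             irfModel(0))
  expect_equal(signalValues(cm2)[, 2],
               c(1, 7, 30) / tau * exp(-c(1, 7, 30) / tau),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(solveConcentrations(sch, c(1, 1, 2), irfModel(0)), "duplicate")
})

test_that("population is conserved once the IRF has fully risen (sinks removed)", {
  set.seed(42)
  irf <- irfModel(140, unit = "fs")
  for (rep in 1:5) {
    n <- sample(2:5, 1)
    # random tree topology: species i flows to one later species, no sink
    edges <- data.frame(from = paste0("S", seq_len(n - 1)),
                        to = paste0("S", vapply(seq_len(n - 1), function(i) {
                          cand <- (i + 1):n
                          cand[sample.int(length(cand), 1)]
                        }, numeric(1))),
                        rate = 1 / runif(n - 1, 0.5, 100))
    sch <- buildTarget(edges, initial = c(S1 = 0.9))
    tt <- c(irfModel()@t0 + 5 * irfSigma(irf) + c(0.01, 1, 50, 400))
    cm <- solveConcentrations(sch, tt, irf)
    expect_lt(max(abs(rowSums(signalValues(cm)) - 0.9)), 1e-6)
  }
})

test_that("cumulative sink outflow is nondecreasing", {
  sch <- buildSequential(c(2, 44, 330))
  cm <- solveConcentrations(sch, defaultDelayGrid(), irfModel(140, unit = "fs"))
  out <- cumulativeSinkOutflow(sch, cm)
  expect_true(all(diff(out) >= -1e-12))
})

test_that("EADS/DADS transforms are exact inverses and reconstruct one surface", {
  lt <- c(2, 44, 330)
  set.seed(7)
  spec <- matrix(rnorm(3 * 50), 3)
  expect_equal(eadsFromDads(dadsFromEads(spec, lt), lt), spec,
               tolerance = 1e-10)
  expect_equal(dadsFromEads(eadsFromDads(spec, lt), lt), spec,
               tolerance = 1e-10)
  # one-component model: EADS = DADS
  one <- matrix(rnorm(20), 1)
  expect_equal(eadsFromDads(one, 5), one)
  # both representations reconstruct the same (t, lambda) surface
  irf <- irfModel(140, unit = "fs")
  tt <- defaultDelayGrid()
  Cseq <- signalValues(solveConcentrations(buildSequential(lt), tt, irf))
  Cpar <- sapply(lt, function(tau) convolvedExponential(tt, 1 / tau, irf))
  eadsM <- spec
  dadsM <- dadsFromEads(eadsM, lt)
  expect_lt(max(abs(Cseq %*% eadsM - Cpar %*% dadsM)), 1e-9)
  expect_error(dadsFromEads(spec, c(2, 44)), "row count")
  expect_warning(dadsFromEads(spec, c(2, 2, 330)), "coincident")
})
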