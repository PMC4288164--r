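test_that("reconvolution fit recovers a noiseless monoexponential exactly", {
  spec <- simpleSpec(taus = 11.3)
  tr <- simulateDecay(spec, noise = FALSE)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitIntensityDecay(tr, irf, nComponents = 1L)
  expect_equal(taus(fittedParams(fit)), 11.3, tolerance = 1e-5)
  expect_lt(chi2Reduced(fit), 1e-6)
})

test_that("noisy free-probe lifetime is recovered with honest statistics", {
  spec <- simpleSpec(taus = 11.3, seed = 101)
  tr <- simulateDecay(spec)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitIntensityDecay(tr, irf, nComponents = 1L)
  tau <- taus(fittedParams(fit))
  se <- stdErrors(fit)[["tau1"]]
  expect_lt(abs(tau - 11.3) / 11.3, 0.02)
  # chi2_r near 1 and random residuals for a correctly specified model
  expect_gt(chi2Reduced(fit), 0.8)
  expect_lt(chi2Reduced(fit), 1.2)
  expect_gt(runsTestP(fit), 0.05)
  # the reported error is on the right scale (true value within ~3 sigma)
  expect_lt(abs(tau - 11.3), 5 * se)
  expect_gt(se, 0)
})

test_that("two components close to the quenched-site regime are resolved", {
  spec <- simpleSpec(alphas = c(0.5, 0.5), taus = c(0.5, 5), seed = 7)
  tr <- simulateDecay(spec)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitIntensityDecay(tr, irf, nComponents = 2L)
  p <- fittedParams(fit)
  expect_equal(taus(p), c(0.5, 5), tolerance = 0.1)
  expect_equal(alphas(p), c(0.5, 0.5), tolerance = 0.1)
  expect_equal(sum(alphas(p)), 1, tolerance = 1e-12)  # simplex is exact
  expect_lt(chi2Reduced(fit), 1.3)
  expect_equal(meanLifetime(p), 2.75, tolerance = 0.1)
})

test_that("a 50 ps component far below the 40 ps IRF width is detected", {
  # fast quenched-site component of a heavily quenched 2-AP site
  spec <- simpleSpec(alphas = c(0.9, 0.1), taus = c(0.05, 10), seed = 21)
  tr <- simulateDecay(spec)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitIntensityDecay(tr, irf, nComponents = 2L)
  p <- fittedParams(fit)
  expect_lt(taus(p)[1], 0.15)      # sub-IRF component found
  expect_gt(taus(p)[1], 0.01)
  expect_equal(taus(p)[2], 10, tolerance = 0.5)
  expect_equal(meanLifetime(p), 1.045, tolerance = 0.15)
})

test_that("IRF channel shift is recovered as a nuisance parameter", {
  g <- ChannelGrid()
  spec <- simpleSpec(taus = 3, seed = 33)
  irf0 <- makeIrf(spec, unitArea = TRUE)
  # build data with the IRF displaced by 1.5 channels
  m <- evaluateMultiExp(MultiExpParams(1, 3), g)
  conv <- convolveIrf(m, irf0, shift = 1.5)
  e <- pmax(10000 / max(conv) * conv, 0)
  counts <- tcspcfit:::.withSeed(5, stats::rpois(length(e), e))
  tr <- DecayTrace(counts, g, kind = "decay")
  fit <- fitIntensityDecay(tr, irf0, nComponents = 1L)
  expect_equal(fittedParams(fit)@shift, 1.5, tolerance = 0.2)
  expect_equal(taus(fittedParams(fit)), 3, tolerance = 0.05)
})

test_that("background floor is recovered and kept non-negative", {
  spec <- SimulationSpec(MultiExpParams(1, 5, background = 20), seed = 9)
  tr <- simulateDecay(spec)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitIntensityDecay(tr, irf, nComponents = 1L)
  expect_equal(fittedParams(fit)@background, 20, tolerance = 5)
  expect_gte(fittedParams(fit)@background, 0)
})

test_that("component count selection is parsimonious", {
  irf <- defaultIrf()
  # one real component: should not over-fit
  one <- simulateDecay(simpleSpec(taus = 4, seed = 41))
  sel1 <- selectNComponents(one, irf, maxN = 3L)
  expect_equal(sel1$bestN, 1L)
  # two well-separated components: needs exactly two
  two <- simulateDecay(simpleSpec(alphas = c(0.5, 0.5), taus = c(0.5, 5),
                                  seed = 42))
  sel2 <- selectNComponents(two, irf, maxN = 3L)
  expect_equal(sel2$bestN, 2L)
  # the rejected 1-component fit shows the failure signature
  expect_gt(chi2Reduced(sel2$fits[[1]]), 2)
  expect_lt(runsTestP(sel2$fits[[1]]), 0.05)
})

test_that("fit window starts before the rise and drops the empty tail", {
  spec <- simpleSpec(taus = 0.3, seed = 2)
  tr <- simulateDecay(spec)
  win <- fitWindow(tr)
  expect_equal(win[1], t0Channel(traceGrid(tr)) - 10L)
  expect_lt(max(win), nChannels(tr) + 1L)
  # a short decay leaves an empty tail that must be excluded
  expect_lt(length(win), nChannels(tr) - 100L)
})

test_that("misspecified single-exponential model is flagged by diagnostics", {
  spec <- simpleSpec(alphas = c(0.5, 0.5), taus = c(0.5, 5), seed = 13)
  tr <- simulateDecay(spec)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitIntensityDecay(tr, irf, nComponents = 1L)
  expect_gt(chi2Reduced(fit), 1.5)
  expect_lt(runsTestP(fit), 0.01)
})
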