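test_that("multi-exponential model evaluates the decay law exactly", {
  # grid whose channel 11 is exactly t = 0
  g <- ChannelGrid(nChannels = 256, dwell = 0.1, t0Channel = 11L)
  t <- channelTimes(g)

  y1 <- evaluateMultiExp(MultiExpParams(1, 11.3), g)
  expect_equal(y1[11], 1.0)                       # value at origin
  k <- which.min(abs(t - 11.3))
  expect_equal(y1[k], exp(-t[k] / 11.3))
  expect_true(all(y1[t < 0] == 0))                # causal: dark before pulse

  # two components evaluated by hand at t = 2 ns
  g2 <- ChannelGrid(nChannels = 64, dwell = 0.5, t0Channel = 1L)
  y2 <- evaluateMultiExp(MultiExpParams(c(0.5, 0.5), c(1, 2)), g2)
  expect_equal(y2[which(channelTimes(g2) == 2)],
               0.5 * exp(-2) + 0.5 * exp(-1), tolerance = 1e-12)

  # scale and background enter linearly
  y3 <- evaluateMultiExp(MultiExpParams(1, 2, scale = 100, background = 7), g2)
  expect_equal(y3[1], 107)

  # decreasing in t for background 0
  expect_true(all(diff(y1[t >= 0]) < 0))

  expect_error(MultiExpParams(1, -1), "positive")
})

test_that("mean lifetime is the amplitude-weighted average and is invariant", {
  expect_equal(meanLifetime(MultiExpParams(1, 11.3)), 11.3)
  expect_equal(meanLifetime(MultiExpParams(c(0.5, 0.5), c(1, 2))), 1.5)
  expect_equal(meanLifetime(MultiExpParams(c(0.9, 0.1), c(0.05, 10))), 1.045)

  # permutation of components and joint amplitude rescaling don't matter
  expect_equal(meanLifetime(MultiExpParams(c(0.1, 0.9), c(10, 0.05))), 1.045)
  expect_warning(p <- MultiExpParams(c(18, 2), c(0.05, 10)), "normaliz")
  expect_equal(meanLifetime(p), 1.045)
})

test_that("IRF convolution is causal, linear, and conserves intensity", {
  g <- ChannelGrid(nChannels = 512, dwell = 0.04, t0Channel = 26L)
  m <- evaluateMultiExp(MultiExpParams(1, 1), g)

  # identity kernel
  expect_equal(convolveIrf(m, deltaIrf(g)), m, tolerance = 1e-10)

  # linearity to machine precision
  irf <- defaultIrf(ChannelGrid(nChannels = 512))
  m2 <- evaluateMultiExp(MultiExpParams(1, 3), g)
  lhs <- convolveIrf(2.5 * m + 0.7 * m2, irf)
  rhs <- 2.5 * convolveIrf(m, irf) + 0.7 * convolveIrf(m2, irf)
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # unit-area kernel conserves the integrated intensity
  expect_equal(sum(convolveIrf(m, irf)), sum(m), tolerance = 1e-9)

  # grid mismatch and empty kernel are rejected
  expect_error(convolveIrf(m[1:100], irf), "grid")
  zero <- DecayTrace(numeric(512), ChannelGrid(nChannels = 512), kind = "irf")
  expect_error(convolveIrf(m, zero), "zero")
})

test_that("convolution with a 40 ps Gaussian matches the closed-form tail", {
  # exponential (x) Gaussian has the closed form
  # E(t) = exp(s^2/(2 tau^2) - t/tau) * Phi(t/s - s/tau);
  # for t > 1 ns the convolved curve must match the bare exponential to 0.1%
  g <- ChannelGrid()
  tau <- 11.3
  m <- evaluateMultiExp(MultiExpParams(1, tau), g)
  out <- convolveIrf(m, defaultIrf(g))
  t <- channelTimes(g)
  tail <- t > 1 & t < 35
  expect_lt(max(abs(out[tail] / exp(-t[tail] / tau) - 1)), 1e-3)
})

test_that("fractional IRF shift moves the kernel by interpolation", {
  g <- ChannelGrid(nChannels = 256)
  m <- evaluateMultiExp(MultiExpParams(1, 2), g)
  out0 <- convolveIrf(m, deltaIrf(g), shift = 0)
  out1 <- convolveIrf(m, deltaIrf(g), shift = 1)
  # integer shift of a delta kernel displaces the curve by one channel
  expect_equal(out1[-1], out0[-length(out0)], tolerance = 1e-9)
  # half-channel shift averages adjacent channels (linear interpolation)
  outh <- convolveIrf(m, deltaIrf(g), shift = 0.5)
  expect_equal(outh[-1], (out0[-1] + out1[-1]) / 2, tolerance = 1e-9)
})

test_that("fit statistics implement Poisson-weighted chi-square and runs test", {
  obs <- c(10, 12, 9, 11, 10, 10, 8, 12, 11, 10)
  st <- fitStatistics(obs, obs, nFreeParams = 2)
  expect_equal(st$chi2Reduced, 0)

  # hand-computed chi-square with w = max(obs, 1)
  exp_ <- obs + 1
  st2 <- fitStatistics(obs, exp_, nFreeParams = 2)
  expect_equal(st2$chi2Reduced, sum(1 / pmax(obs, 1)) / (10 - 2))

  expect_error(fitStatistics(obs, obs, nFreeParams = 10), "freedom")

  # strictly alternating residual signs: far too many runs -> flagged
  resAlt <- rep(c(1, -1), 50)
  expect_lt(runsTest(resAlt), 0.05)
  # one long positive run followed by one negative run: too few runs
  expect_lt(runsTest(c(rep(1, 50), rep(-1, 50))), 0.05)
})

test_that("chi2_r of the true model on its own Poisson data averages 1", {
  spec <- simpleSpec(taus = 3, seed = 42)
  expected <- traceCounts(simulateDecay(spec, noise = FALSE))
  win <- fitWindow(simulateDecay(spec, noise = FALSE))
  set.seed(99)
  chis <- replicate(100, {
    obs <- rpois(length(expected), expected)
    fitStatistics(obs, expected, nFreeParams = 0, window = win)$chi2Reduced
  })
  expect_equal(mean(chis), 1.0, tolerance = 0.1)
})
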