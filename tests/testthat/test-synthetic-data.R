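test_that("simulated IRF has the requested width, peak, and determinism", {
  g <- ChannelGrid()
  spec <- simpleSpec(irfFwhm = 0.04, grid = g)
  irf <- makeIrf(spec)
  w <- traceCounts(irf)

  # peak at the time-zero channel, scaled to the requested peak counts
  expect_equal(which.max(w), t0Channel(g))
  expect_equal(max(w), 10000)

  # FWHM of the discrete profile is about one channel (40 ps dwell)
  half <- sum(w >= max(w) / 2) * dwellTime(g)
  expect_lt(abs(half - 0.04) / 0.04, 1.0)

  # unit-area variant integrates to 1
  expect_equal(sum(traceCounts(makeIrf(spec, unitArea = TRUE))), 1)

  # same seed -> identical noisy realization; RNG state untouched
  set.seed(123); before <- .Random.seed
  a <- traceCounts(makeIrf(simpleSpec(seed = 5), noise = TRUE))
  b <- traceCounts(makeIrf(simpleSpec(seed = 5), noise = TRUE))
  expect_identical(a, b)
  expect_identical(before, .Random.seed)

  expect_warning(makeIrf(simpleSpec(irfFwhm = 0.0001)), "undersampled")
})

test_that("simulated decay hits the target peak counts and stores the truth", {
  spec <- simpleSpec(alphas = c(0.6, 0.4), taus = c(0.5, 5), seed = 11)
  clean <- simulateDecay(spec, noise = FALSE)
  expect_equal(max(traceCounts(clean)), 10000 + 0)  # background 0

  noisy <- simulateDecay(spec, noise = TRUE)
  expect_true(abs(peakCount(noisy) - 10000) < 5 * sqrt(10000))
  expect_true(all(traceCounts(noisy) >= 0))
  expect_true(all(traceCounts(noisy) == round(traceCounts(noisy))))

  truth <- traceMeta(noisy)$truth
  expect_equal(truth$taus, c(0.5, 5))
  expect_equal(truth$alphas, c(0.6, 0.4))

  # reproducible by seed, different across seeds
  expect_identical(traceCounts(simulateDecay(spec)), traceCounts(noisy))
  spec2 <- simpleSpec(alphas = c(0.6, 0.4), taus = c(0.5, 5), seed = 12)
  expect_false(identical(traceCounts(simulateDecay(spec2)),
                         traceCounts(noisy)))

  # Poisson noise: variance tracks the mean in the tail
  e <- traceCounts(clean)
  sel <- which(e > 50 & e < 5000)
  z <- (traceCounts(noisy)[sel] - e[sel]) / sqrt(e[sel])
  expect_lt(abs(mean(z)), 0.2)
  expect_lt(abs(stats::sd(z) - 1), 0.2)
})

test_that("polarized pair obeys the additivity and anisotropy identities", {
  aniso <- AnisotropyParams(0.31, c(0.5, 0.5), c(0.3, 8))
  spec <- SimulationSpec(MultiExpParams(1, 2), anisotropy = aniso,
                         gFactor = 1.15, seed = 3)
  pair <- simulatePolarizedPair(spec, noise = FALSE)
  G <- 1.15
  P <- traceCounts(pair$parallel)
  Q <- traceCounts(pair$perpendicular)

  # total intensity I = Ipar + 2 G Iperp reproduces the magic-angle decay
  tot <- P + 2 * G * Q
  specI <- SimulationSpec(MultiExpParams(1, 2), seed = 3)
  I <- traceCounts(simulateDecay(specI, noise = FALSE))
  expect_equal(tot / max(tot), I / max(I), tolerance = 1e-9)

  # constructed r(t) matches the ground-truth model in the bright region
  df <- constructAnisotropy(pair, G)
  tpos <- df$time > 0.5 & df$time < 6 & !df$masked
  rTrue <- 0.31 * (0.5 * exp(-df$time[tpos] / 0.3) +
                   0.5 * exp(-df$time[tpos] / 8))
  expect_equal(df$r[tpos], rTrue, tolerance = 0.02)

  # r(t) from expected counts never exceeds r0
  expect_true(all(df$r[!df$masked] <= 0.31 + 1e-9))

  # two noisy channels use independent sub-streams but one master seed
  noisy1 <- simulatePolarizedPair(spec)
  noisy2 <- simulatePolarizedPair(spec)
  expect_identical(traceCounts(noisy1$parallel), traceCounts(noisy2$parallel))
  expect_false(identical(traceCounts(noisy1$parallel),
                         traceCounts(noisy1$perpendicular)))

  expect_error(simulatePolarizedPair(specI), "anisotropy")
})

test_that("quenching series follows Stern-Volmer exactly when noise-free", {
  s <- simulateQuenchingSeries(MultiExpParams(1, 11.3), kq = 1.9,
                               qConcentrations = c(0, 0.05, 0.1, 0.2))
  tau <- responses(s)
  expect_equal(tau[1], 11.3)
  # tau0/tau is linear in [Q] with slope kq*tau0
  y <- 11.3 / tau
  expect_equal(y, 1 + 1.9 * 11.3 * concentrations(s), tolerance = 1e-12)
  # quenched lifetime at 0.1 M for tau0 = 1 ns, kq = 16.3: 0.3802 ns
  s2 <- simulateQuenchingSeries(MultiExpParams(1, 1), 16.3, c(0, 0.1))
  expect_equal(responses(s2)[2], 1 / (1 + 16.3 * 0.1), tolerance = 1e-12)
  expect_equal(round(responses(s2)[2], 4), 0.3802)
})

test_that("binding series is a Langmuir isotherm with clipping", {
  s <- simulateBindingSeries(kd = 50, beta2Max = 0.8,
                             ribosomeConcs = c(0, 25, 50, 100, 400))
  b <- responses(s)
  expect_equal(b[1], 0)
  expect_equal(b[3], 0.4)          # half saturation at [R] = Kd
  expect_true(all(diff(b) > 0))    # monotone increasing
  expect_lt(max(b), 0.8)           # approaches but never exceeds beta2Max

  # additive noise is clipped to [0, 1]
  sn <- simulateBindingSeries(50, 0.999, c(0, 1e6), noiseSd = 0.5, seed = 2)
  expect_true(all(responses(sn) >= 0 & responses(sn) <= 1))

  expect_error(simulateBindingSeries(-1, 0.5, c(0, 10)), "kd")
  expect_error(simulateBindingSeries(50, 1.5, c(0, 10)), "beta2Max")
})
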