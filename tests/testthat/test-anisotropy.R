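test_that("G factor is recovered from a freely rotating standard", {
  # standard: long lifetime, sub-ns rotation fully decayed by 3 ns
  aniso <- AnisotropyParams(0.31, 1, 0.15)
  spec <- SimulationSpec(MultiExpParams(1, 11.3), anisotropy = aniso,
                         gFactor = 1.15, peakCounts = 20000, seed = 8)
  pair <- simulatePolarizedPair(spec)
  g <- estimateGFactor(pair, knownLifetime = 11.3)
  expect_equal(gValue(g), 1.15, tolerance = 0.01)

  # noiseless recovery is essentially exact
  gc <- estimateGFactor(simulatePolarizedPair(spec, noise = FALSE), 11.3)
  expect_equal(gValue(gc), 1.15, tolerance = 1e-6)
})

test_that("anisotropy construction masks shot-noise-dominated channels", {
  aniso <- AnisotropyParams(0.31, 1, 1.5)
  spec <- SimulationSpec(MultiExpParams(1, 2), anisotropy = aniso, seed = 4)
  pair <- simulatePolarizedPair(spec)
  df <- constructAnisotropy(pair, 1)
  expect_true(any(df$masked))             # dim tail channels masked
  expect_true(all(is.na(df$r[df$masked])))
  expect_true(all(!is.na(df$r[!df$masked])))
  expect_true(all(df$se[!df$masked] > 0))
  # near the peak the error is small and r is near r0
  peak <- which.max(traceCounts(pair$parallel))
  expect_lt(df$se[peak + 5], 0.05)
})

test_that("constrained fit recovers a single sub-ns correlation time", {
  # the NATA-in-glycerol regime: phi far below the lifetime, below the IRF
  aniso <- AnisotropyParams(0.31, 1, 0.315)
  spec <- SimulationSpec(MultiExpParams(1, 3), anisotropy = aniso,
                         peakCounts = 20000, seed = 15)
  pair <- simulatePolarizedPair(spec)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitAnisotropy(pair, irf, MultiExpParams(1, 3), r0 = 0.31, nRot = 1L)
  p <- fittedParams(fit)
  expect_equal(phis(p), 0.315, tolerance = 0.029)
  expect_false(phi2Capped(p))
  expect_lt(chi2Reduced(fit), 1.3)
})

test_that("biexponential rotation and free r0 are recovered", {
  aniso <- AnisotropyParams(0.31, c(0.5, 0.5), c(0.3, 8))
  spec <- SimulationSpec(MultiExpParams(1, 2), anisotropy = aniso,
                         peakCounts = 20000, seed = 16)
  pair <- simulatePolarizedPair(spec)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitAnisotropy(pair, irf, MultiExpParams(1, 2), r0Free = TRUE,
                       nRot = 2L)
  p <- fittedParams(fit)
  expect_equal(initialAnisotropy(p), 0.31, tolerance = 0.03)
  expect_equal(phis(p)[1], 0.3, tolerance = 0.15)
  expect_equal(phis(p)[2], 8, tolerance = 2)
  expect_equal(betas(p)[2], 0.5, tolerance = 0.1)
  expect_equal(sum(betas(p)), 1, tolerance = 1e-12)
})

test_that("a ribosome-scale slow rotation is capped, its amplitude kept", {
  # phi2 far beyond the ~41 ns window: only beta2 is identifiable
  aniso <- AnisotropyParams(0.31, c(0.6, 0.4), c(0.4, 300))
  spec <- SimulationSpec(MultiExpParams(1, 2), anisotropy = aniso,
                         peakCounts = 20000, seed = 17)
  pair <- simulatePolarizedPair(spec)
  irf <- makeIrf(spec, unitArea = TRUE)
  fit <- fitAnisotropy(pair, irf, MultiExpParams(1, 2), nRot = 2L)
  p <- fittedParams(fit)
  expect_true(phi2Capped(p))
  expect_equal(betas(p)[2], 0.4, tolerance = 0.05)
  # reported mean correlation time substitutes the 50 ns cap:
  # 0.6*phi1 + 0.4*50, not the unidentifiable fitted phi2
  m <- meanRotationalCorrelation(p)
  expect_equal(m, betas(p)[1] * phis(p)[1] + betas(p)[2] * 50,
               tolerance = 1e-12)
  expect_lt(m, 51)
})

test_that("mean rotational correlation arithmetic matches hand computation", {
  p <- AnisotropyParams(0.31, c(0.4, 0.6), c(0.5, 20))
  expect_equal(meanRotationalCorrelation(p), 0.4 * 0.5 + 0.6 * 20)
  pc <- AnisotropyParams(0.31, c(0.4, 0.6), c(0.5, 200), phi2Capped = TRUE)
  expect_equal(meanRotationalCorrelation(pc), 0.4 * 0.5 + 0.6 * 50)
  expect_equal(meanRotationalCorrelation(pc, capNs = 100),
               0.4 * 0.5 + 0.6 * 100)
})

test_that("correlation times scale linearly with viscosity (Stokes-Einstein)", {
  eta <- c(1.0, 2.1, 4.4, 5.4)
  phi <- c(0.060, 0.121, 0.224, 0.315)
  sdv <- c(0.027, 0.034, 0.029, 0.029)
  chk <- stokesEinsteinCheck(phi, eta, temperature = 293, errors = sdv)
  # every residual within the stated measurement uncertainty
  expect_true(all(abs(chk$residuals) < sdv))
  expect_gt(chk$rSquared, 0.98)
  # slope ~ 0.056 ns/cP corresponds to a ~0.23 nm^3 molecular volume
  expect_equal(chk$slope, 0.056, tolerance = 0.05)
  expect_gt(chk$volumeNm3, 0.1)
  expect_lt(chk$volumeNm3, 0.5)
})
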