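test_that("dispersion profile arithmetic matches a hand computation", {
  d <- data.frame(site = c(6L, 10L, 24L),
                  condition = "20C",
                  parameter = "tau_m",
                  value = c(1.06, 1.48, 1.70),
                  error = c(0.05, 0.06, 0.08))
  tab <- SiteParameterTable(d)
  prof <- dispersionProfile(tab, "tau_m", "20C")
  m <- mean(c(1.06, 1.48, 1.70))        # 1.413333...
  expect_equal(prof@deviations, (c(1.06, 1.48, 1.70) - m) / m)
  expect_equal(prof@deviations[1], 1.06 / m - 1, tolerance = 1e-12)
  expect_equal(prof@rmsFlatness, sqrt(mean(((c(1.06, 1.48, 1.70) - m) / m)^2)))
  expect_equal(prof@sites, c(6L, 10L, 24L))
})

test_that("dispersion is invariant to scale and zero for a flat profile", {
  d <- data.frame(site = 1:4, condition = "c", parameter = "p",
                  value = c(2, 4, 6, 8), error = NA_real_)
  d2 <- d; d2$value <- d$value * 1000
  p1 <- dispersionProfile(SiteParameterTable(d), "p", "c")
  p2 <- dispersionProfile(SiteParameterTable(d2), "p", "c")
  expect_equal(p1@deviations, p2@deviations)
  expect_equal(p1@rmsFlatness, p2@rmsFlatness)

  flat <- d; flat$value <- rep(3, 4)
  expect_equal(dispersionProfile(SiteParameterTable(flat), "p", "c")@rmsFlatness, 0)

  expect_error(dispersionProfile(SiteParameterTable(d), "p", "missing"),
               "fewer than 2")
})

test_that("urea denaturation flattens the free-RNA lifetime profile", {
  tab <- bundledSiteTable("free")
  native <- dispersionProfile(tab, "tau_m", "20C")
  urea <- dispersionProfile(tab, "tau_m", "45C_urea")
  expect_lt(urea@rmsFlatness, native@rmsFlatness)

  cmp <- flatnessCompare(tab, "tau_m", "45C_urea", "20C", nBoot = 500,
                         seed = 2)
  expect_lt(cmp$ratio, 1)
  # the bootstrap interval excludes 1: flattening survives the errors
  expect_lt(cmp$bootstrapInterval[2], 1)
})

test_that("heating the bound RNA flattens its quenching profile", {
  tab <- bundledSiteTable("bound")
  cmp <- flatnessCompare(tab, "kq", "45C", "20C", nBoot = 500, seed = 3)
  expect_lt(cmp$rmsA, cmp$rmsB)
  expect_lt(cmp$ratio, 1)
  expect_lt(cmp$bootstrapInterval[2], 1)
  # while the free RNA keeps substantial lifetime dispersion when heated
  free <- bundledSiteTable("free")
  hot <- dispersionProfile(free, "tau_m", "45C")
  expect_gt(hot@rmsFlatness, 0.1)
})

test_that("flatness bootstrap is deterministic in its seed", {
  tab <- bundledSiteTable("free")
  a <- flatnessCompare(tab, "tau_m", "45C_urea", "20C", nBoot = 200, seed = 7)
  b <- flatnessCompare(tab, "tau_m", "45C_urea", "20C", nBoot = 200, seed = 7)
  c <- flatnessCompare(tab, "tau_m", "45C_urea", "20C", nBoot = 200, seed = 8)
  expect_identical(a$bootstrapInterval, b$bootstrapInterval)
  expect_false(identical(a$bootstrapInterval, c$bootstrapInterval))
})

test_that("bundled tables carry the full site-by-condition data", {
  free <- bundledSiteTable("free")
  d <- siteData(free)
  expect_setequal(unique(d$site), c(6L, 10L, 24L, 27L, 35L, 38L, 41L))
  expect_setequal(unique(d$parameter), c("tau_m", "phi_m", "kq"))
  expect_setequal(unique(d$condition), c("20C", "45C", "45C_urea"))
  # spot values: heavily quenched internal site vs exposed loop site
  get <- function(site, par, cond)
    d$value[d$site == site & d$parameter == par & d$condition == cond]
  expect_equal(get(24, "tau_m", "20C"), 1.69)
  expect_equal(get(24, "kq", "20C"), 20.4)
  expect_equal(get(6, "tau_m", "20C"), 1.06)
  expect_equal(get(6, "kq", "20C"), 4.7)

  bound <- bundledSiteTable("bound")
  expect_true(all(c("20C", "45C") %in% siteData(bound)$condition))
  g15 <- bundledSiteTable("g15del")
  expect_setequal(unique(siteData(g15)$site), c(24L, 27L, 35L))
})

test_that("site tables round-trip through text", {
  tab <- bundledSiteTable("g15del")
  f <- tempfile(fileext = ".tsv")
  writeSiteTable(tab, f)
  back <- readSiteTable(f)
  expect_equal(siteData(back), siteData(tab))
  unlink(f)
})
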