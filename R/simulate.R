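## Derive k reproducible sub-seeds from a master seed.
.subSeeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

## Run expr with a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an instrument response function
#'
#' Gaussian IRF profile centered on the grid's time-zero channel.  Channel
#' values are bin-integrated (the integral of the Gaussian over each dwell
#' interval), so the zero-width limit degenerates cleanly to a single-channel
#' delta.  The measured IRF of a real instrument is asymmetric in detail;
#' only its width matters for the analyses here.
#'
#' @param spec a [SimulationSpec-class]; `irfFwhm` and `grid` are used.
#' @param peakCounts counts in the peak channel of the returned IRF trace;
#'   default 10000.  Ignored when `unitArea = TRUE`.
#' @param unitArea logical; return a unit-area profile instead of scaling to
#'   `peakCounts`.
#' @param noise logical; add Poisson noise (seeded from `spec@seed`).
#'   Only meaningful with `unitArea = FALSE`.
#' @return a [DecayTrace-class] of kind \code{"irf"}.
#' @export
makeIrf <- function(spec, peakCounts = 10000, unitArea = FALSE,
                    noise = FALSE) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  grid <- spec@grid
  d <- dwellTime(grid)
  if (spec@irfFwhm < d / 10)
    warning("IRF FWHM below dwell/10: kernel is undersampled")
  sigma <- spec@irfFwhm / (2 * sqrt(2 * log(2)))
  k <- seq_len(nChannels(grid))
  lo <- (k - 0.5 - t0Channel(grid)) * d
  hi <- (k + 0.5 - t0Channel(grid)) * d
  if (sigma <= 0) {
    w <- as.numeric(lo < 0 & hi >= 0)
  } else {
    w <- stats::pnorm(hi, 0, sigma) - stats::pnorm(lo, 0, sigma)
  }
  if (unitArea) {
    w <- w / sum(w)
  } else {
    w <- w / max(w) * peakCounts
    if (noise)
      w <- .withSeed(spec@seed, stats::rpois(length(w), w))
  }
  DecayTrace(w, grid, kind = "irf",
             meta = list(irfFwhm = spec@irfFwhm, unitArea = unitArea))
}

#' Simulate a magic-angle TCSPC decay trace
#'
#' Evaluates the ground-truth multi-exponential decay, convolves it with a
#' noiseless Gaussian IRF of the specified width, scales the curve so the
#' expected peak-channel count equals `spec@peakCounts`, adds the constant
#' background, and (by default) applies per-channel Poisson noise.  The
#' full ground truth is recorded in the trace metadata so recovery tests
#' need no side channel.
#'
#' @param spec a [SimulationSpec-class].
#' @param noise logical; `FALSE` returns the expected (noise-free) counts.
#' @return a [DecayTrace-class] of kind \code{"decay"}.
#' @examples
#' spec <- SimulationSpec(MultiExpParams(1, 11.3), seed = 7)
#' tr <- simulateDecay(spec)
#' peakCount(tr)
#' @export
simulateDecay <- function(spec, noise = TRUE) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  p <- spec@intensity
  unit <- MultiExpParams(p@alphas, p@taus, scale = 1, background = 0)
  model <- evaluateMultiExp(unit, spec@grid)
  irf <- makeIrf(spec, unitArea = TRUE)
  conv <- convolveIrf(model, irf, shift = 0)
  f <- spec@peakCounts / max(conv)
  expected <- pmax(f * conv, 0) + p@background
  counts <- if (noise)
    .withSeed(spec@seed, stats::rpois(length(expected), expected))
  else expected
  DecayTrace(counts, spec@grid, kind = "decay",
             meta = list(truth = list(alphas = p@alphas, taus = p@taus,
                                      scale = f, background = p@background),
                         irfFwhm = spec@irfFwhm, seed = spec@seed,
                         peakCounts = spec@peakCounts))
}

## r(t) of the (bi)exponential anisotropy model on t >= 0.
.anisoRt <- function(aniso, t) {
  r <- numeric(length(t))
  for (i in seq_along(aniso@phis))
    r <- r + aniso@betas[i] * exp(-t / aniso@phis[i])
  aniso@r0 * r
}

#' Simulate a polarized decay pair
#'
#' Builds the parallel and perpendicular emission components
#' \deqn{I_\parallel(t) = \tfrac13 I(t)[1 + 2r(t)], \quad
#'       I_\perp(t) = \tfrac13 I(t)[1 - r(t)]}
#' from the ground-truth intensity decay and anisotropy model, convolves
#' each with the IRF, divides the detected perpendicular channel by the G
#' factor (detection-efficiency model), scales so the expected parallel
#' peak equals `spec@peakCounts`, and applies independent Poisson noise per
#' channel with sub-seeds drawn from the master seed.
#'
#' @param spec a [SimulationSpec-class] with a non-NULL anisotropy slot.
#' @param noise logical; `FALSE` returns expected counts.
#' @return list with [DecayTrace-class] elements \code{parallel} and
#'   \code{perpendicular}.
#' @export
simulatePolarizedPair <- function(spec, noise = TRUE) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  if (is.null(spec@anisotropy))
    stop("spec has no anisotropy parameters")
  aniso <- spec@anisotropy
  p <- spec@intensity
  unit <- MultiExpParams(p@alphas, p@taus, scale = 1, background = 0)
  grid <- spec@grid
  t <- channelTimes(grid)
  I <- evaluateMultiExp(unit, grid)
  r <- numeric(length(t))
  r[t >= 0] <- .anisoRt(aniso, t[t >= 0])
  if (any(r < -0.5 | r > 1))
    stop("anisotropy r(t) outside (-0.5, 1]")
  mPar <- I * (1 + 2 * r) / 3
  mPerp <- I * (1 - r) / 3
  irf <- makeIrf(spec, unitArea = TRUE)
  cPar <- convolveIrf(mPar, irf)
  cPerp <- convolveIrf(mPerp, irf) / spec@gFactor
  f <- spec@peakCounts / max(cPar)
  ePar <- pmax(f * cPar, 0)
  ePerp <- pmax(f * cPerp, 0)
  seeds <- .subSeeds(spec@seed, 2L)
  truth <- list(alphas = p@alphas, taus = p@taus, r0 = aniso@r0,
                betas = aniso@betas, phis = aniso@phis,
                gFactor = spec@gFactor, scale = f, seed = spec@seed)
  mk <- function(e, s, kind) {
    counts <- if (noise) .withSeed(s, stats::rpois(length(e), e)) else e
    DecayTrace(counts, grid, kind = kind,
               meta = list(truth = truth, irfFwhm = spec@irfFwhm))
  }
  list(parallel = mk(ePar, seeds[1], "parallel"),
       perpendicular = mk(ePerp, seeds[2], "perpendicular"))
}

#' Simulate an acrylamide quenching titration
#'
#' For each quencher concentration the ground-truth lifetimes are uniformly
#' scaled so the mean lifetime obeys the Stern-Volmer relation
#' \eqn{\tau_0/\tau = 1 + k_q \tau_0 [Q]}.  Optional multiplicative
#' Gaussian noise emulates fit-to-fit scatter of measured lifetimes.
#'
#' @param tau0Params a [MultiExpParams-class]: the unquenched decay.
#' @param kq bimolecular quenching constant in 1e9 / M / s.
#' @param qConcentrations quencher concentrations in M, increasing.
#' @param noiseSd multiplicative noise s.d. on the lifetimes (e.g. 0.02 for
#'   2 percent); default 0 (noise-free).
#' @param seed integer seed used when `noiseSd > 0`.
#' @return a [TitrationSeries-class] of kind \code{"quenching"} whose
#'   responses are mean lifetimes in ns.
#' @examples
#' simulateQuenchingSeries(MultiExpParams(1, 1.69), kq = 20.4,
#'                         qConcentrations = c(0, 0.05, 0.1))
#' @export
simulateQuenchingSeries <- function(tau0Params, kq, qConcentrations,
                                    noiseSd = 0, seed = 1L) {
  stopifnot(is(tau0Params, "MultiExpParams"))
  if (kq < 0) stop("kq must be non-negative")
  if (any(qConcentrations < 0)) stop("concentrations must be non-negative")
  tau0 <- meanLifetime(tau0Params)
  tau <- tau0 / (1 + kq * tau0 * qConcentrations)
  if (noiseSd > 0)
    tau <- .withSeed(seed,
      tau * (1 + stats::rnorm(length(tau), 0, noiseSd)))
  TitrationSeries(qConcentrations, tau,
                  responseErrors = rep(noiseSd * tau0, length(tau)),
                  kind = "quenching")
}

#' Simulate a ribosome-binding titration of the slow-anisotropy amplitude
#'
#' The amplitude beta2 of the very long (beyond-window) rotational
#' correlation time grows with ribosome concentration as a 1:1 Langmuir
#' isotherm \eqn{\beta_2([R]) = \beta_{max} [R]/(K_d + [R])}, plus additive
#' Gaussian noise, clipped to [0, 1].
#'
#' @param kd dissociation constant in nM (> 0).
#' @param beta2Max saturating amplitude in (0, 1].
#' @param ribosomeConcs ribosome concentrations in nM, increasing.
#' @param noiseSd additive Gaussian noise s.d. on beta2; default 0.
#' @param seed integer seed used when `noiseSd > 0`.
#' @return a [TitrationSeries-class] of kind \code{"binding"}.
#' @export
simulateBindingSeries <- function(kd, beta2Max, ribosomeConcs, noiseSd = 0,
                                  seed = 1L) {
  if (kd <= 0) stop("kd must be positive")
  if (beta2Max <= 0 || beta2Max > 1) stop("beta2Max must be in (0, 1]")
  b <- beta2Max * ribosomeConcs / (kd + ribosomeConcs)
  if (noiseSd > 0)
    b <- .withSeed(seed, b + stats::rnorm(length(b), 0, noiseSd))
  b <- pmin(pmax(b, 0), 1)
  TitrationSeries(ribosomeConcs, b,
                  responseErrors = rep(noiseSd, length(b)),
                  kind = "binding")
}
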