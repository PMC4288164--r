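#' Estimate the G factor from a freely rotating standard
#'
#' For a standard fluorophore whose anisotropy has fully decayed well within
#' the measurement window (e.g. 2-AP free in water, lifetime 11.3 ns,
#' sub-ns rotation), the tail of the polarized pair satisfies
#' \eqn{I_\parallel = G I_\perp}.  The G factor is chosen so the tail-region
#' anisotropy averages zero: \eqn{G = \sum I_\parallel / \sum I_\perp} over
#' the tail window.
#'
#' @param pair list with [DecayTrace-class] elements \code{parallel} and
#'   \code{perpendicular} on a common grid.
#' @param knownLifetime fluorescence lifetime of the standard in ns (used
#'   only to sanity-check that the tail window retains signal).
#' @param tailStart start of the tail window in ns after time zero; default
#'   3 ns (at least ten times any plausible correlation time of a free dye).
#' @param emissionWavelength optional wavelength label in nm.
#' @return a [GFactor-class].
#' @export
estimateGFactor <- function(pair, knownLifetime, tailStart = 3,
                            emissionWavelength = NA_real_) {
  par <- pair$parallel; perp <- pair$perpendicular
  stopifnot(is(par, "DecayTrace"), is(perp, "DecayTrace"))
  if (nChannels(par) != nChannels(perp))
    stop("polarized pair must share a grid")
  t <- channelTimes(par)
  tail <- which(t >= tailStart)
  if (!length(tail)) stop("tail window is empty: tailStart beyond the grid")
  if (mean(traceCounts(par)[tail]) < 100)
    warning("mean tail counts < 100/channel: G-factor precision is limited")
  g <- sum(traceCounts(par)[tail]) / sum(traceCounts(perp)[tail])
  GFactor(g, emissionWavelength,
          method = sprintf("tail matching (t >= %.3g ns, standard lifetime %.3g ns)",
                           tailStart, knownLifetime))
}

#' Construct the anisotropy decay from a polarized pair
#'
#' Computes per channel
#' \deqn{r = \frac{I_\parallel - G I_\perp}{I_\parallel + 2 G I_\perp}}
#' with a Poisson-propagated standard error.  Channels whose total-intensity
#' denominator falls below `minDenominator` counts are masked (returned as
#' NA), since the ratio there is dominated by shot noise.
#'
#' @param pair list with elements \code{parallel} and \code{perpendicular}.
#' @param g a [GFactor-class] or a bare positive number.
#' @param minDenominator counts threshold for masking; default 20.
#' @return data.frame with columns \code{time}, \code{r}, \code{se},
#'   \code{masked}.
#' @export
constructAnisotropy <- function(pair, g, minDenominator = 20) {
  par <- pair$parallel; perp <- pair$perpendicular
  stopifnot(is(par, "DecayTrace"), is(perp, "DecayTrace"))
  if (nChannels(par) != nChannels(perp))
    stop("polarized pair must share a grid")
  G <- if (is(g, "GFactor")) gValue(g) else as.numeric(g)
  P <- traceCounts(par)
  Q <- traceCounts(perp)
  D <- P + 2 * G * Q
  masked <- D < minDenominator
  if (all(masked))
    stop("all channels masked: denominator below threshold everywhere")
  r <- (P - G * Q) / D
  ## delta method with Var = counts (Poisson): dr/dP = 3GQ/D^2, dr/dQ = -3GP/D^2
  se <- sqrt((3 * G * Q / D^2)^2 * pmax(P, 1) +
             (3 * G * P / D^2)^2 * pmax(Q, 1) * G^0)
  r[masked] <- NA_real_
  se[masked] <- NA_real_
  data.frame(time = channelTimes(par), r = r, se = se, masked = masked)
}

## Pack/unpack anisotropy fit parameters:
## (log phis[1..n], beta-logits[1..n-1], logS, [logit-ish r0 if free])
.expectedPolarized <- function(phisv, betasv, r0, S, intensityParams, grid,
                               irf, gFactor, shift) {
  t <- channelTimes(grid)
  pos <- t >= 0
  tp <- t[pos]
  I <- numeric(length(t))
  acc <- numeric(length(tp))
  for (i in seq_along(intensityParams@taus))
    acc <- acc + intensityParams@alphas[i] * exp(-tp / intensityParams@taus[i])
  I[pos] <- acc
  r <- numeric(length(t))
  rr <- numeric(length(tp))
  for (j in seq_along(phisv))
    rr <- rr + betasv[j] * exp(-tp / phisv[j])
  r[pos] <- r0 * rr
  ePar <- S * convolveIrf(I * (1 + 2 * r) / 3, irf, shift)
  ePerp <- S * convolveIrf(I * (1 - r) / 3, irf, shift) / gFactor
  list(par = ePar, perp = ePerp)
}

#' Fit the anisotropy decay of a polarized pair
#'
#' Simultaneous reconvolution fit of the parallel and perpendicular
#' histograms to the polarized-component model
#' \eqn{I_\parallel = \tfrac13 I(t)[1+2r(t)]},
#' \eqn{I_\perp = \tfrac13 I(t)[1-r(t)]/G} with
#' \eqn{r(t) = r_0\{\beta_1 e^{-t/\phi_1} + \beta_2 e^{-t/\phi_2}\}}.
#' Following the constrained protocol, the intensity decay parameters
#' (previously fitted from the magic-angle trace) and the initial
#' anisotropy r0 are held fixed; only the rotational amplitudes and
#' correlation times (and an overall photon scale) vary.  Set
#' `r0Free = TRUE` to release r0, e.g. for protocol-validation fits.
#'
#' The long correlation time is bounded above at 1000 ns; a fitted value of
#' 50 ns or more is flagged `phi2Capped` -- within a ~41 ns window such a
#' component is indistinguishable from any slower rotation (the
#' ribosome-bound regime), so only its amplitude is meaningful and
#' [meanRotationalCorrelation()] substitutes the 50 ns reporting cap.
#'
#' @param pair list with elements \code{parallel} and \code{perpendicular}.
#' @param irf measured IRF on the same grid.
#' @param intensityParams [MultiExpParams-class] held fixed (its shift is
#'   reused for the IRF alignment).
#' @param r0 fixed initial anisotropy; default 0.31 (2-AP in 50 percent
#'   glycerol).
#' @param nRot number of rotational components, 1 or 2.
#' @param r0Free logical; release r0 as a fitted parameter.
#' @param gFactor detection G factor (a [GFactor-class] or number).
#' @param init optional [AnisotropyParams-class] initialization.
#' @param window integer channels to fit; default [fitWindow()] of the
#'   parallel trace.
#' @param maxIter maximum LM iterations.
#' @return a [FitResult-class] whose `params` is an
#'   [AnisotropyParams-class].
#' @export
fitAnisotropy <- function(pair, irf, intensityParams, r0 = 0.31,
                          nRot = 2L, r0Free = FALSE, gFactor = 1,
                          init = NULL, window = NULL, maxIter = 200L) {
  par <- pair$parallel; perp <- pair$perpendicular
  stopifnot(is(par, "DecayTrace"), is(perp, "DecayTrace"),
            is(irf, "DecayTrace"), is(intensityParams, "MultiExpParams"))
  if (nChannels(par) != nChannels(perp) ||
      nChannels(par) != nChannels(irf))
    stop("pair and IRF must share a grid")
  n <- as.integer(nRot)
  if (n < 1L || n > 2L) stop("nRot must be 1 or 2")
  G <- if (is(gFactor, "GFactor")) gValue(gFactor) else as.numeric(gFactor)
  grid <- traceGrid(par)
  if (is.null(window)) window <- fitWindow(par)
  oPar <- traceCounts(par)
  oPerp <- traceCounts(perp)
  wPar <- sqrt(pmax(oPar[window], 1))
  wPerp <- sqrt(pmax(oPerp[window], 1))
  shift <- intensityParams@shift

  if (is.null(init)) {
    phinit <- if (n == 1L) 1.5 else c(0.3, 10)
    binit <- rep(1 / n, n)
  } else {
    phinit <- init@phis; binit <- init@betas
  }
  e0 <- .expectedPolarized(phinit, binit, r0, 1, intensityParams, grid,
                           irf, G, shift)
  sinit <- max(sum(oPar[window]) + 2 * G * sum(oPerp[window]), 1) /
           max(sum(e0$par[window] + 2 * G * e0$perp[window]), 1e-9)

  p0 <- c(log(phinit), if (n > 1L) .logitsFromAlphas(binit), log(sinit),
          if (r0Free) r0)
  lower <- c(rep(log(1e-3), n), rep(-20, n - 1L), -30, if (r0Free) 0.01)
  upper <- c(rep(log(1000), n), rep(20, n - 1L), 60, if (r0Free) 0.4)

  unpack <- function(p) {
    phisv <- exp(p[seq_len(n)])
    betasv <- if (n == 1L) 1 else .softmax(p[n + seq_len(n - 1L)])
    S <- exp(p[2L * n])
    r0v <- if (r0Free) p[length(p)] else r0
    list(phis = phisv, betas = betasv, S = S, r0 = r0v)
  }

  resid <- function(p) {
    u <- unpack(p)
    e <- .expectedPolarized(u$phis, u$betas, u$r0, u$S, intensityParams,
                            grid, irf, G, shift)
    c((oPar[window] - e$par[window]) / wPar,
      (oPerp[window] - e$perp[window]) / wPerp)
  }

  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxIter, maxfev = 100000L))
  if (fit$info == 0 || fit$info == 9)
    stop(sprintf("anisotropy fit did not converge: %s", fit$message))

  u <- unpack(fit$par)
  ord <- order(u$phis)
  capped <- u$phis[ord][n] >= 50
  params <- new("AnisotropyParams", r0 = u$r0, betas = u$betas[ord],
                phis = u$phis[ord], phi2Capped = capped)

  e <- .expectedPolarized(u$phis, u$betas, u$r0, u$S, intensityParams,
                          grid, irf, G, shift)
  obsAll <- c(oPar[window], oPerp[window])
  expAll <- c(e$par[window], e$perp[window])
  nFree <- length(p0)
  st <- fitStatistics(obsAll, expAll, nFree)

  se <- rep(NA_real_, length(fit$par))
  cv <- tryCatch(st$chi2Reduced * solve(fit$hessian),
                 error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  sePhi <- (se[seq_len(n)] * u$phis)[ord]
  names(sePhi) <- paste0("phi", seq_len(n))
  seOut <- c(sePhi, scale = unname(se[2L * n] * u$S))
  if (r0Free) seOut <- c(seOut, r0 = unname(se[length(se)]))

  new("FitResult", params = params, chi2Reduced = st$chi2Reduced,
      residuals = st$residuals, runsTestP = st$runsTestP,
      stderr = seOut, nEvalChannels = st$nEval,
      info = list(message = fit$message, niter = fit$niter,
                  window = window, scale = u$S, gFactor = G,
                  longComponentBeyondWindow = capped))
}

#' Stokes-Einstein consistency check for rotational correlation times
#'
#' Weighted linear fit of measured correlation times against solvent
#' viscosity through the origin, per the Stokes-Einstein relation
#' \eqn{\phi = \eta V / kT}.  Used to validate recovery of sub-IRF
#' correlation times with a small-molecule standard (NATA in
#' glycerol-water).
#'
#' @param phis correlation times in ns (>= 2 values).
#' @param viscosities matched solvent viscosities in cP.
#' @param temperature absolute temperature in K; default 298.
#' @param errors optional standard errors of `phis` used as weights
#'   (1/error^2); unweighted when absent.
#' @return list with `slope` (ns/cP, = V/kT in those units),
#'   `volumeNm3` (hydrodynamic volume in nm^3), `residuals` (ns),
#'   `rSquared` (through-origin definition), and `fit` (the lm object).
#' @export
stokesEinsteinCheck <- function(phis, viscosities, temperature = 298,
                                errors = NULL) {
  if (length(phis) < 2L) stop("need at least 2 points")
  if (length(phis) != length(viscosities))
    stop("phis and viscosities must have equal length")
  w <- if (is.null(errors)) rep(1, length(phis)) else 1 / errors^2
  fit <- stats::lm(phis ~ 0 + viscosities, weights = w)
  slope <- unname(stats::coef(fit)[1])
  ## slope ns/cP -> SI s/(Pa s) is 1e-6; V = slope_SI * kB * T
  volume <- slope * 1e-6 * 1.380649e-23 * temperature  # m^3
  res <- phis - slope * viscosities
  r2 <- 1 - sum(w * res^2) / sum(w * phis^2)
  list(slope = slope, volumeNm3 = volume * 1e27, residuals = res,
       rSquared = r2, fit = fit)
}
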