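## Softmax with first logit fixed at 0: maps (n-1) unconstrained numbers to
## an n-vector on the simplex, so the amplitude constraint sum(alpha) = 1
## holds exactly during optimization.
.softmax <- function(g) {
  e <- exp(c(0, g) - max(0, g))
  e / sum(e)
}

.logitsFromAlphas <- function(a) {
  a <- pmax(a, 1e-8)
  log(a[-1]) - log(a[1])
}

## Pack/unpack the intensity-fit parameter vector:
## (log taus[1..n], logits[1..n-1], logS, bg, shift)
.packIntensity <- function(taus, alphas, scale, background, shift,
                           fitShift, fitBackground) {
  p <- c(log(taus), .logitsFromAlphas(alphas), log(scale))
  if (fitBackground) p <- c(p, background)
  if (fitShift) p <- c(p, shift)
  p
}

.unpackIntensity <- function(p, n, fitShift, fitBackground) {
  taus <- exp(p[seq_len(n)])
  alphas <- if (n == 1L) 1 else .softmax(p[n + seq_len(n - 1L)])
  i <- 2L * n
  scale <- exp(p[i])
  background <- if (fitBackground) p[i <- i + 1L] else 0
  shift <- if (fitShift) p[i + 1L] else 0
  list(taus = taus, alphas = alphas, scale = scale,
       background = background, shift = shift)
}

## Expected counts for an intensity fit given unpacked parameters.
.expectedIntensity <- function(u, grid, irf) {
  t <- channelTimes(grid)
  m <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  acc <- numeric(length(tp))
  for (i in seq_along(u$taus))
    acc <- acc + u$alphas[i] * exp(-tp / u$taus[i])
  m[pos] <- acc
  u$scale * convolveIrf(m, irf, u$shift) + u$background
}

#' Fit a multi-exponential decay by iterative reconvolution
#'
#' Levenberg-Marquardt minimization of the Poisson-weighted chi-square
#' between the observed histogram and the model decay convolved with the
#' measured IRF.  Amplitudes are optimized on the simplex (sum exactly 1),
#' lifetimes on a log scale within [0.01, 100] ns, and the IRF channel
#' shift (bounded to +/-5 channels) and a constant background are fitted as
#' nuisance parameters by default.
#'
#' @param trace observed [DecayTrace-class].
#' @param irf measured IRF [DecayTrace-class] on the same grid.
#' @param nComponents number of exponential components, 1 to 4.
#' @param init optional [MultiExpParams-class] initialization; by default
#'   lifetimes start log-spaced over \code{[2 dwell, window/3]} with equal
#'   amplitudes.
#' @param fitShift,fitBackground logical, fit these nuisance parameters.
#' @param window integer channel indices to fit; default [fitWindow()].
#' @param maxIter maximum LM iterations.
#' @return a [FitResult-class] whose `params` is a [MultiExpParams-class]
#'   in canonical (increasing-lifetime) order.  `fitInfo()` carries the
#'   optimizer message, the window, and a `degenerate` flag when two fitted
#'   lifetimes differ by less than 5 percent.
#' @export
fitIntensityDecay <- function(trace, irf, nComponents = 1L, init = NULL,
                              fitShift = TRUE, fitBackground = TRUE,
                              window = fitWindow(trace), maxIter = 200L) {
  stopifnot(is(trace, "DecayTrace"), is(irf, "DecayTrace"))
  if (nChannels(trace) != nChannels(irf))
    stop("trace and IRF must share a grid")
  n <- as.integer(nComponents)
  if (n < 1L || n > 4L) stop("nComponents must be between 1 and 4")
  grid <- traceGrid(trace)
  obs <- traceCounts(trace)
  w <- sqrt(pmax(obs[window], 1))

  d <- dwellTime(grid)
  winNs <- length(window) * d
  binit0 <- max(stats::median(obs[seq_len(max(1L, t0Channel(grid) - 15L))]), 0)

  ## candidate lifetime initializations: multi-exponential LM fits are
  ## sensitive to starting lifetimes, so several geometric spreads around a
  ## center-of-mass estimate are tried and the lowest chi-square kept
  if (is.null(init)) {
    t <- channelTimes(grid)
    post <- window[t[window] >= 0]
    cw <- pmax(obs[post] - binit0, 0)
    tauCom <- sum(cw * t[post]) / max(sum(cw), 1)
    tauCom <- min(max(tauCom, 2 * d), winNs / 3)
    cands <- list()
    if (n == 1L) {
      cands <- list(tauCom, tauCom / 3)
    } else {
      ## the intensity-weighted center of mass sits near the longest
      ## lifetime; ladder the remaining components downward from it
      for (spread in c(3, 6, 12)) {
        tc <- tauCom * spread^(seq_len(n) - n)
        cands[[length(cands) + 1L]] <- pmin(pmax(tc, 0.011), 99)
      }
      cands[[length(cands) + 1L]] <-
        exp(seq(log(2 * d), log(winNs / 3), length.out = n))
    }
    starts <- lapply(cands, function(tc)
      list(taus = sort(tc), alphas = rep(1 / n, n), background = binit0,
           shift = 0))
  } else {
    starts <- list(list(taus = init@taus, alphas = init@alphas,
                        background = init@background, shift = init@shift,
                        scale = init@scale))
  }

  lower <- c(rep(log(0.01), n), rep(-20, n - 1L), -30)
  upper <- c(rep(log(100), n), rep(20, n - 1L), 60)
  if (fitBackground) { lower <- c(lower, 0); upper <- c(upper, Inf) }
  if (fitShift) { lower <- c(lower, -5); upper <- c(upper, 5) }

  resid <- function(p) {
    u <- .unpackIntensity(p, n, fitShift, fitBackground)
    e <- .expectedIntensity(u, grid, irf)
    (obs[window] - e[window]) / w
  }

  fit <- NULL
  for (stt in starts) {
    sinit <- stt$scale
    if (is.null(sinit)) {
      e1 <- .expectedIntensity(list(taus = stt$taus, alphas = stt$alphas,
                                    scale = 1, background = 0, shift = 0),
                               grid, irf)
      sinit <- max(sum(obs[window]) - stt$background * length(window), 1) /
               max(sum(e1[window]), 1e-12)
    }
    p0 <- .packIntensity(stt$taus, stt$alphas, max(sinit, 1e-6),
                         stt$background, stt$shift, fitShift, fitBackground)
    cand <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                               fn = resid,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = maxIter, maxfev = 100000L))
    if (cand$info == 0 || cand$info == 9) next
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  if (is.null(fit))
    stop("reconvolution fit did not converge from any initialization")

  u <- .unpackIntensity(fit$par, n, fitShift, fitBackground)
  ord <- order(u$taus)
  params <- new("MultiExpParams", alphas = u$alphas[ord] / sum(u$alphas),
                taus = u$taus[ord], scale = u$scale,
                background = max(u$background, 0), shift = u$shift)
  e <- .expectedIntensity(u, grid, irf)
  nFree <- length(p0)
  st <- fitStatistics(obs, e, nFree, window)

  ## standard errors: covariance in internal coordinates, delta method to
  ## the natural scale for log / softmax transformed parameters
  se <- rep(NA_real_, length(fit$par))
  cv <- tryCatch(st$chi2Reduced * solve(fit$hessian),
                 error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  seTau <- (se[seq_len(n)] * u$taus)[ord]
  names(seTau) <- paste0("tau", seq_len(n))
  seOut <- c(seTau, scale = unname(se[2L * n] * u$scale))
  if (fitBackground) seOut <- c(seOut, background = unname(se[2L * n + 1L]))
  if (fitShift) seOut <- c(seOut, shift = unname(se[length(se)]))

  degenerate <- n > 1L && any(params@taus[-1] / params@taus[-n] < 1.05)
  if (degenerate)
    warning("fitted lifetimes nearly degenerate (ratio < 1.05)")

  new("FitResult", params = params, chi2Reduced = st$chi2Reduced,
      residuals = st$residuals, runsTestP = st$runsTestP,
      stderr = seOut, nEvalChannels = st$nEval,
      info = list(message = fit$message, niter = fit$niter,
                  window = window, degenerate = degenerate,
                  deviance = fit$deviance))
}

#' Choose the number of decay components
#'
#' Fits 1..`maxN` components sequentially and returns the smallest n whose
#' reduced chi-square improvement over n+1 falls below `chi2Threshold` and
#' whose runs-test p-value exceeds `runsAlpha` -- i.e. the most parsimonious
#' model that already describes the data with random residuals.  When no n
#' qualifies, `maxN` is returned with a quality warning.
#'
#' @param trace,irf as in [fitIntensityDecay()].
#' @param maxN largest number of components to consider (<= 4).
#' @param chi2Threshold improvement in reduced chi-square regarded as
#'   negligible; default 0.1.
#' @param runsAlpha residual-randomness significance level; default 0.05.
#' @param ... passed on to [fitIntensityDecay()].
#' @return list with `bestN` (integer) and `fits` (list of
#'   [FitResult-class], one per n).
#' @export
selectNComponents <- function(trace, irf, maxN = 4L, chi2Threshold = 0.1,
                              runsAlpha = 0.05, ...) {
  maxN <- as.integer(maxN)
  if (maxN < 1L || maxN > 4L) stop("maxN must be between 1 and 4")
  fits <- vector("list", maxN)
  for (k in seq_len(maxN))
    fits[[k]] <- tryCatch(fitIntensityDecay(trace, irf, k, ...),
                          warning = function(w) suppressWarnings(
                            fitIntensityDecay(trace, irf, k, ...)))
  chi2 <- vapply(fits, chi2Reduced, numeric(1))
  bestN <- NA_integer_
  for (k in seq_len(maxN)) {
    improvement <- if (k < maxN) chi2[k] - chi2[k + 1L] else 0
    if (improvement < chi2Threshold && runsTestP(fits[[k]]) > runsAlpha) {
      bestN <- k
      break
    }
  }
  if (is.na(bestN)) {
    warning("no component count gave random residuals; returning maxN")
    bestN <- maxN
  }
  list(bestN = bestN, fits = fits)
}
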