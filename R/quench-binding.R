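#' Stern-Volmer analysis of a quenching titration
#'
#' Linear regression of \eqn{\tau_0/\tau} on quencher concentration per the
#' Stern-Volmer relation \eqn{\tau_0/\tau = 1 + k_q \tau_0 [Q]}, yielding
#' the bimolecular quenching constant \eqn{k_q} = slope / \eqn{\tau_0}.
#' With lifetimes in ns and concentrations in M the slope/tau0 ratio is
#' directly in units of 1e9 / M / s.  The regression is weighted by the
#' propagated lifetime errors when the series carries them
#' (\eqn{\sigma_y = \tau_0 \sigma_\tau / \tau^2}), ordinary least squares
#' otherwise.  The intercept is fitted, not fixed at 1: a deviation beyond
#' 0.1 raises a warning, since purely collisional quenching predicts an
#' intercept of 1 and larger deviations suggest a static component.
#'
#' @param series a [TitrationSeries-class] of kind \code{"quenching"}
#'   (concentrations in M, responses = lifetimes in ns).
#' @param tau0 unquenched lifetime in ns; default the response at the
#'   lowest (zero) concentration.
#' @return a [QuenchingResult-class].
#' @examples
#' s <- simulateQuenchingSeries(MultiExpParams(1, 1.69), 20.4,
#'                              c(0, 0.05, 0.1, 0.2))
#' sternVolmerFit(s)
#' @export
sternVolmerFit <- function(series, tau0 = NULL) {
  stopifnot(is(series, "TitrationSeries"))
  if (seriesKind(series) != "quenching")
    stop("series kind must be 'quenching'")
  q <- concentrations(series)
  tau <- responses(series)
  if (length(q) < 3L) stop("need at least 3 titration points")
  if (any(tau <= 0)) stop("lifetimes must be positive")
  if (is.null(tau0)) tau0 <- tau[1]
  if (tau0 <= 0) stop("tau0 must be positive")
  y <- tau0 / tau
  err <- responseErrors(series)
  w <- if (length(err) && all(err > 0)) (tau^2 / (tau0 * err))^2 else NULL
  fit <- if (is.null(w)) stats::lm(y ~ q) else stats::lm(y ~ q, weights = w)
  co <- stats::coef(fit)
  ## summary.lm warns on noiseless (perfect) input; the fit itself is fine
  sm <- suppressWarnings(summary(fit))
  slope <- unname(co[2])
  slopeSe <- sm$coefficients[2, 2]
  intercept <- unname(co[1])
  if (slope < 0) {
    warning("negative Stern-Volmer slope; kq set to 0")
    kq <- 0; kqSe <- 0
  } else {
    kq <- slope / tau0
    kqSe <- slopeSe / tau0
  }
  if (abs(intercept - 1) > 0.1)
    warning(sprintf(
      "Stern-Volmer intercept %.3f deviates from 1: possible static quenching",
      intercept))
  new("QuenchingResult", kq = kq, kqStderr = kqSe, tau0 = tau0,
      intercept = intercept, rSquared = sm$r.squared)
}

#' Predict quenched lifetimes from a Stern-Volmer result
#'
#' @param result a [QuenchingResult-class].
#' @param q quencher concentrations in M.
#' @return lifetimes in ns.
#' @export
predictLifetime <- function(result, q) {
  stopifnot(is(result, "QuenchingResult"))
  result@tau0 / (result@intercept + result@kq * result@tau0 * q)
}

#' Fit a 1:1 binding isotherm to a slow-anisotropy amplitude titration
#'
#' Least-squares fit of the Langmuir model
#' \eqn{\beta_2([R]) = \beta_{max} [R] / (K_d + [R])} to the amplitude of
#' the beyond-window rotational correlation time versus ribosome
#' concentration, the readout from which the minimum saturating ribosome
#' level is chosen.  The minimum saturating concentration is the smallest
#' concentration whose predicted amplitude reaches
#' `saturation * beta2Max` (with the 0.95 default, algebraically 19 Kd).
#'
#' @param series a [TitrationSeries-class] of kind \code{"binding"}
#'   (concentrations in nM, responses = beta2 amplitudes).
#' @param saturation fraction of `beta2Max` regarded as saturated;
#'   default 0.95.
#' @return list with `kd` (nM), `beta2Max`, `minSaturating` (nM),
#'   `kdStderr`, `beta2MaxStderr`, `rSquared`, `degenerate` (TRUE when the
#'   series shows no binding signal) and `fit` (the nls.lm object, NULL if
#'   degenerate).
#' @export
bindingIsothermFit <- function(series, saturation = 0.95) {
  stopifnot(is(series, "TitrationSeries"))
  if (seriesKind(series) != "binding")
    stop("series kind must be 'binding'")
  conc <- concentrations(series)
  b <- responses(series)
  if (length(conc) < 4L) stop("need at least 4 titration points")
  if (max(b) <= 10 * .Machine$double.eps) {
    warning("amplitudes are all ~0: no binding detected; fit is degenerate")
    return(list(kd = NA_real_, beta2Max = 0, minSaturating = NA_real_,
                kdStderr = NA_real_, beta2MaxStderr = NA_real_,
                rSquared = NA_real_, degenerate = TRUE, fit = NULL))
  }
  half <- max(b) / 2
  kd0 <- conc[which.min(abs(b - half))]
  kd0 <- max(kd0, min(conc[conc > 0], na.rm = TRUE) / 2)
  p0 <- c(logKd = log(kd0), logBmax = log(max(b)))
  resid <- function(p) b - exp(p[2]) * conc / (exp(p[1]) + conc)
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  kd <- exp(fit$par[[1]])
  bmax <- exp(fit$par[[2]])
  rss <- sum(fit$fvec^2)
  dof <- length(b) - 2L
  se <- tryCatch(sqrt(pmax(diag(solve(fit$hessian)) * rss / dof, 0)),
                 error = function(e) rep(NA_real_, 2))
  minSat <- kd * saturation / (1 - saturation)
  if (minSat > max(conc))
    warning(sprintf(
      "predicted saturation (%.3g) beyond the titrated range (max %.3g): extrapolating",
      minSat, max(conc)))
  list(kd = kd, beta2Max = bmax, minSaturating = minSat,
       kdStderr = se[1] * kd, beta2MaxStderr = se[2] * bmax,
       rSquared = 1 - rss / sum((b - mean(b))^2),
       degenerate = FALSE, fit = fit)
}
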