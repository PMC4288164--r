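#' Evaluate a multi-exponential intensity decay on a channel grid
#'
#' Computes \eqn{I(t_k) = s \sum_i \alpha_i e^{-t_k/\tau_i} + b} on the
#' grid's time axis, with the decay zero for \eqn{t < 0} (before the
#' excitation pulse).  This is the un-convolved model; pass the result
#' through [convolveIrf()] to obtain expected detected counts.
#'
#' @param params a [MultiExpParams-class].
#' @param grid a [ChannelGrid-class].
#' @return numeric vector of per-channel model intensity.
#' @examples
#' g <- ChannelGrid(nChannels = 256, dwell = 0.1, t0Channel = 10L)
#' y <- evaluateMultiExp(MultiExpParams(1, 11.3), g)
#' y[10]  # 1 at t = 0
#' @export
evaluateMultiExp <- function(params, grid) {
  stopifnot(is(params, "MultiExpParams"), is(grid, "ChannelGrid"))
  validObject(params)
  validObject(grid)
  t <- channelTimes(grid)
  y <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  acc <- numeric(length(tp))
  for (i in seq_along(params@taus))
    acc <- acc + params@alphas[i] * exp(-tp / params@taus[i])
  y[pos] <- acc
  params@scale * y + params@background
}

## Shift a kernel by a fractional number of channels (linear interpolation;
## mass moved outside the window is dropped).
.shiftKernel <- function(w, shift) {
  if (shift == 0) return(w)
  n <- length(w)
  out <- stats::approx(x = seq_len(n), y = w, xout = seq_len(n) - shift,
                       method = "linear", rule = 1)$y
  out[is.na(out)] <- 0
  out
}

## Causal discrete convolution with kernel origin at channel `origin`
## (1-based).  Full linear convolution via FFT, then re-indexed so that a
## delta kernel at `origin` returns the input unchanged.
.convKernel <- function(m, w, origin) {
  full <- stats::convolve(w, rev(m), type = "open")
  full[origin:(origin + length(m) - 1L)]
}

#' Convolve a model decay with the instrument response function
#'
#' Discrete causal convolution of a per-channel model intensity with the
#' measured IRF, the forward operation that iterative reconvolution fitting
#' inverts.  The IRF is normalized to unit area (so total intensity is
#' conserved), optionally shifted by a fractional number of channels via
#' linear interpolation, and its time-zero channel is taken as the kernel
#' origin -- a delta IRF at \code{t0Channel} therefore returns the model
#' unchanged.
#'
#' @param model numeric vector of per-channel model intensity (e.g. from
#'   [evaluateMultiExp()] with zero background).
#' @param irf a [DecayTrace-class] of kind \code{"irf"} (kind is not
#'   enforced, the counts are used as the kernel) on the same grid.
#' @param shift fractional channel shift applied to the IRF; default 0.
#' @return numeric vector of expected counts, same length as `model`.
#' @export
convolveIrf <- function(model, irf, shift = 0) {
  stopifnot(is(irf, "DecayTrace"))
  w <- irf@counts
  if (length(model) != length(w))
    stop("model and IRF must be on the same grid (length mismatch)")
  w <- .shiftKernel(w, shift)
  s <- sum(w)
  if (s <= 0) stop("IRF is all zero (or shifted entirely out of the window)")
  .convKernel(model, w / s, t0Channel(irf))
}

#' Two-sided Wald-Wolfowitz runs test on residual signs
#'
#' Tests whether the sequence of residual signs is random, the standard
#' operational check of "randomness of residuals" for TCSPC fits.  Uses the
#' normal approximation to the null distribution of the number of runs;
#' zero residuals are dropped.  Both too few runs (trends, model misfit) and
#' too many runs (over-dispersion, alternation) give small p-values.
#'
#' @param x numeric vector of residuals.
#' @return two-sided p-value.
#' @export
runsTest <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n <- length(s)
  n1 <- sum(s > 0)
  n2 <- n - n1
  if (n1 == 0L || n2 == 0L) return(1)
  runs <- 1L + sum(s[-1] != s[-n])
  mu <- 1 + 2 * n1 * n2 / n
  v <- (mu - 1) * (mu - 2) / (n - 1)
  if (v <= 0) return(1)
  z <- (runs - mu) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Goodness-of-fit statistics for a TCSPC fit
#'
#' Reduced chi-square with Poisson weights \eqn{w_k = \max(o_k, 1)} and the
#' runs-test p-value of the weighted residuals.
#'
#' @param observed a [DecayTrace-class] (or numeric counts vector).
#' @param expected numeric vector of expected counts, same length.
#' @param nFreeParams number of fitted parameters.
#' @param window optional integer vector of channel indices to evaluate;
#'   default all channels.
#' @return list with elements \code{chi2Reduced}, \code{runsTestP},
#'   \code{residuals} (weighted, on the window) and \code{nEval}.
#' @export
fitStatistics <- function(observed, expected, nFreeParams, window = NULL) {
  obs <- if (is(observed, "DecayTrace")) observed@counts else observed
  if (length(obs) != length(expected))
    stop("observed and expected must have equal length")
  if (is.null(window)) window <- seq_along(obs)
  o <- obs[window]
  e <- expected[window]
  nEval <- length(o)
  if (nEval <= nFreeParams)
    stop("degrees of freedom <= 0: fit window smaller than parameter count")
  r <- (o - e) / sqrt(pmax(o, 1))
  list(chi2Reduced = sum(r^2) / (nEval - nFreeParams),
       runsTestP = runsTest(r), residuals = r, nEval = nEval)
}

#' Default fit window for a trace
#'
#' Channels from 10 before the IRF-peak channel to the last channel holding
#' at least `minCounts` counts; empty tail channels destabilize the Poisson
#' chi-square and are excluded.
#'
#' @param trace a [DecayTrace-class].
#' @param preRise channels to include before the time-zero channel.
#' @param minCounts tail cutoff in counts.
#' @return integer vector of channel indices.
#' @export
fitWindow <- function(trace, preRise = 10L, minCounts = 5) {
  stopifnot(is(trace, "DecayTrace"))
  start <- max(1L, t0Channel(trace) - as.integer(preRise))
  keep <- which(trace@counts >= minCounts)
  end <- if (length(keep)) max(keep) else nChannels(trace)
  end <- max(end, start + 1L)
  seq.int(start, end)
}
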