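#' @import methods
NULL

#' Uniform TCSPC channel grid
#'
#' Describes the time axis of a photon-counting histogram: a fixed number of
#' channels at a constant dwell time, with time zero anchored at the channel
#' holding the instrument-response peak.  Channel \code{k} (1-based) maps to
#' time \code{(k - t0Channel) * dwell} nanoseconds, so channels before
#' \code{t0Channel} carry negative times.
#'
#' @slot nChannels integer, number of channels (> 0).
#' @slot dwell numeric, time per channel in nanoseconds (> 0).
#' @slot t0Channel integer, 1-based index of the time-zero (IRF peak) channel.
#'
#' @seealso [ChannelGrid()] for the user-facing constructor,
#'   [channelTimes()] for the derived time axis.
#' @export
setClass("ChannelGrid",
  representation(nChannels = "integer", dwell = "numeric",
                 t0Channel = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@nChannels) != 1L || is.na(object@nChannels) ||
        object@nChannels < 1L)
      msg <- c(msg, "nChannels must be a single positive integer")
    if (length(object@dwell) != 1L || is.na(object@dwell) ||
        object@dwell <= 0)
      msg <- c(msg, "dwell must be a single positive number (ns)")
    if (length(object@t0Channel) != 1L || is.na(object@t0Channel) ||
        object@t0Channel < 1L ||
        (length(object@nChannels) == 1L && !is.na(object@nChannels) &&
         object@t0Channel > object@nChannels))
      msg <- c(msg, "t0Channel must lie within 1..nChannels")
    if (length(msg)) msg else TRUE
  })

#' Photon-count decay trace
#'
#' A single TCSPC histogram: per-channel photon counts on a [ChannelGrid].
#' The same class holds magic-angle intensity decays, measured instrument
#' response functions, and the parallel/perpendicular components of an
#' anisotropy measurement, distinguished by \code{kind}.
#'
#' @slot grid a [ChannelGrid-class].
#' @slot counts numeric vector of non-negative per-channel counts, length
#'   \code{nChannels(grid)}.
#' @slot kind one of \code{"decay"}, \code{"irf"}, \code{"parallel"},
#'   \code{"perpendicular"}.
#' @slot meta named list of free-form labels (probe position, temperature,
#'   condition, simulation ground truth, ...).
#'
#' @export
setClass("DecayTrace",
  representation(grid = "ChannelGrid", counts = "numeric", kind = "character",
                 meta = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@counts) != object@grid@nChannels)
      msg <- c(msg, "counts length must equal nChannels(grid)")
    if (any(!is.finite(object@counts)) || any(object@counts < 0))
      msg <- c(msg, "counts must be finite and non-negative")
    if (length(object@kind) != 1L ||
        !object@kind %in% c("decay", "irf", "parallel", "perpendicular"))
      msg <- c(msg,
        "kind must be one of 'decay', 'irf', 'parallel', 'perpendicular'")
    if (length(msg)) msg else TRUE
  })

#' Multi-exponential intensity-decay parameters
#'
#' Parameters of the intensity-decay model
#' \deqn{I(t) = \sum_i \alpha_i \exp(-t/\tau_i)}
#' with normalized amplitudes (\eqn{\sum_i \alpha_i = 1}), an overall photon
#' scale, a constant background per channel, and an IRF-to-decay channel
#' shift.  Components are stored in canonical order of strictly increasing
#' lifetime.
#'
#' @slot alphas numeric, non-negative amplitudes summing to 1 (1--4 values).
#' @slot taus numeric, lifetimes in ns, strictly increasing, all > 0.
#' @slot scale numeric, overall photon scale (>= 0).
#' @slot background numeric, constant counts offset per channel (>= 0).
#' @slot shift numeric, IRF shift in fractional channels.
#'
#' @export
setClass("MultiExpParams",
  representation(alphas = "numeric", taus = "numeric", scale = "numeric",
                 background = "numeric", shift = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@taus)
    if (n < 1L || n > 4L)
      msg <- c(msg, "between 1 and 4 lifetime components are supported")
    if (length(object@alphas) != n)
      msg <- c(msg, "alphas and taus must have equal length")
    if (any(object@taus <= 0) || any(!is.finite(object@taus)))
      msg <- c(msg, "all lifetimes must be positive and finite")
    if (n > 1L && any(diff(object@taus) <= 0))
      msg <- c(msg, "lifetimes must be strictly increasing (canonical order)")
    if (any(object@alphas < 0))
      msg <- c(msg, "amplitudes must be non-negative")
    if (abs(sum(object@alphas) - 1) > 1e-8)
      msg <- c(msg, "amplitudes must sum to 1 (use MultiExpParams() to normalize)")
    if (length(object@scale) != 1L || object@scale < 0)
      msg <- c(msg, "scale must be a single non-negative number")
    if (length(object@background) != 1L || object@background < 0)
      msg <- c(msg, "background must be a single non-negative number")
    if (length(object@shift) != 1L || !is.finite(object@shift))
      msg <- c(msg, "shift must be a single finite number")
    if (length(msg)) msg else TRUE
  })

#' Anisotropy-decay parameters
#'
#' Parameters of the (bi)exponential anisotropy model
#' \deqn{r(t) = r_0 \{\beta_1 e^{-t/\phi_1} + \beta_2 e^{-t/\phi_2}\}}
#' with fixed initial anisotropy \eqn{r_0}, normalized amplitudes
#' (\eqn{\sum \beta_i = 1}) and rotational correlation times \eqn{\phi_i}
#' in increasing order.  \code{phi2Capped} flags that the long correlation
#' time exceeded the resolvable window (the ribosome-bound ">50 ns" regime),
#' in which case [meanRotationalCorrelation()] substitutes the reporting cap.
#'
#' @slot r0 numeric, initial anisotropy, in (0, 0.4].
#' @slot betas numeric, non-negative amplitudes summing to 1 (1--2 values).
#' @slot phis numeric, rotational correlation times in ns, increasing, > 0.
#' @slot phi2Capped logical, TRUE when the long correlation time is beyond
#'   the observable window and is reported against a cap.
#'
#' @export
setClass("AnisotropyParams",
  representation(r0 = "numeric", betas = "numeric", phis = "numeric",
                 phi2Capped = "logical"),
  validity = function(object) {
    msg <- character()
    n <- length(object@phis)
    if (length(object@r0) != 1L || object@r0 <= 0 || object@r0 > 0.4)
      msg <- c(msg, "r0 must lie in (0, 0.4]")
    if (n < 1L || n > 2L)
      msg <- c(msg, "one or two rotational components are supported")
    if (length(object@betas) != n)
      msg <- c(msg, "betas and phis must have equal length")
    if (any(object@betas < 0))
      msg <- c(msg, "beta amplitudes must be non-negative")
    if (abs(sum(object@betas) - 1) > 1e-8)
      msg <- c(msg, "beta amplitudes must sum to 1")
    if (any(object@phis <= 0) || any(!is.finite(object@phis)))
      msg <- c(msg, "correlation times must be positive and finite")
    if (n > 1L && any(diff(object@phis) <= 0))
      msg <- c(msg, "correlation times must be strictly increasing")
    if (length(object@phi2Capped) != 1L || is.na(object@phi2Capped))
      msg <- c(msg, "phi2Capped must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
  })

#' Fit diagnostics container
#'
#' Carries the fitted parameter object together with the goodness-of-fit
#' statistics used throughout: the reduced chi-square of Poisson-weighted
#' residuals and the two-sided Wald-Wolfowitz runs-test p-value that
#' operationalizes "randomness of residuals".
#'
#' @slot params the fitted parameter object ([MultiExpParams-class] or
#'   [AnisotropyParams-class]).
#' @slot chi2Reduced numeric, reduced chi-square (> 0 for noisy data).
#' @slot residuals numeric, weighted residual per evaluated channel.
#' @slot runsTestP numeric, p-value of the residual-sign runs test.
#' @slot stderr named numeric, per-parameter standard errors.
#' @slot nEvalChannels integer, channels included in the fit window.
#' @slot info list of fitter diagnostics (convergence message, window, flags).
#'
#' @export
setClass("FitResult",
  representation(params = "ANY", chi2Reduced = "numeric",
                 residuals = "numeric", runsTestP = "numeric",
                 stderr = "numeric", nEvalChannels = "integer",
                 info = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@chi2Reduced) != 1L || object@chi2Reduced < 0)
      msg <- c(msg, "chi2Reduced must be a single non-negative number")
    if (length(object@residuals) != object@nEvalChannels)
      msg <- c(msg, "residuals length must equal nEvalChannels")
    if (length(msg)) msg else TRUE
  })

#' Polarization grating (G) factor
#'
#' Relative detection efficiency of the parallel versus perpendicular
#' emission channels at the observation wavelength, estimated from a freely
#' rotating standard whose anisotropy has fully decayed in the tail of the
#' measurement window.
#'
#' @slot value numeric, the G factor (> 0).
#' @slot emissionWavelength numeric, emission wavelength in nm (NA if unknown).
#' @slot method character, description of how the value was obtained.
#' @export
setClass("GFactor",
  representation(value = "numeric", emissionWavelength = "numeric",
                 method = "character"),
  validity = function(object) {
    if (length(object@value) != 1L || !is.finite(object@value) ||
        object@value <= 0)
      "value must be a single positive number"
    else TRUE
  })

#' Concentration-indexed titration series
#'
#' A quencher titration (acrylamide concentration in M against fluorescence
#' lifetime in ns) or a binding titration (ribosome concentration in nM
#' against the slow-anisotropy amplitude beta2).
#'
#' @slot concentrations numeric, non-negative, strictly increasing.
#' @slot responses numeric, lifetimes (ns) or beta2 amplitudes.
#' @slot responseErrors numeric, standard errors of responses (may be
#'   zero-length when unknown).
#' @slot kind \code{"quenching"} or \code{"binding"}.
#' @export
setClass("TitrationSeries",
  representation(concentrations = "numeric", responses = "numeric",
                 responseErrors = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@concentrations < 0))
      msg <- c(msg, "concentrations must be non-negative")
    if (length(object@concentrations) > 1L &&
        any(diff(object@concentrations) <= 0))
      msg <- c(msg, "concentrations must be strictly increasing")
    if (length(object@responses) != length(object@concentrations))
      msg <- c(msg, "responses and concentrations must have equal length")
    if (length(object@responseErrors) &&
        length(object@responseErrors) != length(object@responses))
      msg <- c(msg, "responseErrors must be empty or match responses")
    if (length(object@kind) != 1L ||
        !object@kind %in% c("quenching", "binding"))
      msg <- c(msg, "kind must be 'quenching' or 'binding'")
    if (length(msg)) msg else TRUE
  })

#' Stern-Volmer quenching-analysis result
#'
#' @slot kq numeric, bimolecular quenching constant in 1e9 / M / s.
#' @slot kqStderr numeric, standard error of kq in the same units.
#' @slot tau0 numeric, unquenched lifetime in ns.
#' @slot intercept numeric, fitted intercept of tau0/tau vs [Q] (near 1 for
#'   purely collisional quenching).
#' @slot rSquared numeric, coefficient of determination of the regression.
#' @export
setClass("QuenchingResult",
  representation(kq = "numeric", kqStderr = "numeric", tau0 = "numeric",
                 intercept = "numeric", rSquared = "numeric"),
  validity = function(object) {
    if (object@kq < 0) "kq must be non-negative" else TRUE
  })

#' Site-by-condition fluorescence parameter table
#'
#' Long-format table of a fluorescence observable (mean lifetime tau_m, mean
#' rotational correlation time phi_m, or quenching constant kq) per probe
#' site and experimental condition, with uncertainties.  This is the input
#' of the site-dispersion profiling that quantifies how "non-flat" an
#' observable is across labeling positions.
#'
#' @slot data data.frame with columns \code{site} (integer), \code{condition}
#'   (character), \code{parameter} (character), \code{value} (positive
#'   numeric), \code{error} (numeric, NA allowed).
#' @export
setClass("SiteParameterTable",
  representation(data = "data.frame"),
  validity = function(object) {
    d <- object@data
    need <- c("site", "condition", "parameter", "value", "error")
    if (!all(need %in% names(d)))
      return(paste("data must have columns:", paste(need, collapse = ", ")))
    if (any(!is.finite(d$value)) || any(d$value <= 0))
      return("all values must be positive and finite")
    key <- paste(d$site, d$condition, d$parameter)
    if (anyDuplicated(key))
      return("duplicate (site, condition, parameter) rows")
    TRUE
  })

#' Site-dispersion profile
#'
#' Per-site relative deviations \code{(observed - mean)/mean} of one
#' observable under one condition, plus their root-mean-square as a single
#' flatness figure.  A structured molecule shows large site-to-site
#' dispersion; a denatured or uniformly exposed one shows a flat profile.
#'
#' @slot sites integer vector of probe positions.
#' @slot deviations numeric, relative deviation per site.
#' @slot rmsFlatness numeric, root-mean-square of the deviations.
#' @slot parameter character, which observable was profiled.
#' @slot condition character, which condition.
#' @export
setClass("DispersionProfile",
  representation(sites = "integer", deviations = "numeric",
                 rmsFlatness = "numeric", parameter = "character",
                 condition = "character"),
  validity = function(object) {
    if (length(object@sites) != length(object@deviations))
      "sites and deviations must have equal length"
    else TRUE
  })

#' Simulation specification for synthetic TCSPC data
#'
#' Bundles everything the synthetic-data generator needs: the ground-truth
#' intensity decay, optional anisotropy decay, instrument response width,
#' channel grid, target peak counts, detection G factor and master seed.
#'
#' @slot intensity a [MultiExpParams-class], the ground-truth intensity decay.
#' @slot anisotropy an [AnisotropyParams-class] or NULL.
#' @slot irfFwhm numeric, IRF full width at half maximum in ns (> 0).
#' @slot grid a [ChannelGrid-class].
#' @slot peakCounts numeric, target expected counts in the peak channel.
#' @slot gFactor numeric, detection G factor applied to the perpendicular
#'   channel (> 0).
#' @slot seed integer, master random seed.
#' @export
setClass("SimulationSpec",
  representation(intensity = "MultiExpParams", anisotropy = "ANY",
                 irfFwhm = "numeric", grid = "ChannelGrid",
                 peakCounts = "numeric", gFactor = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is.null(object@anisotropy) &&
        !methods::is(object@anisotropy, "AnisotropyParams"))
      msg <- c(msg, "anisotropy must be NULL or an AnisotropyParams")
    if (length(object@irfFwhm) != 1L || object@irfFwhm <= 0)
      msg <- c(msg, "irfFwhm must be a single positive number (ns)")
    if (length(object@peakCounts) != 1L || object@peakCounts < 1)
      msg <- c(msg, "peakCounts must be >= 1")
    if (length(object@gFactor) != 1L || object@gFactor <= 0)
      msg <- c(msg, "gFactor must be positive")
    if (length(msg)) msg else TRUE
  })
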