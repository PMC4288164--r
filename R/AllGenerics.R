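#' @rdname ChannelGrid
#' @param object a ChannelGrid (or object carrying one).
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname ChannelGrid
#' @export
setGeneric("dwellTime", function(object) standardGeneric("dwellTime"))

#' @rdname ChannelGrid
#' @export
setGeneric("t0Channel", function(object) standardGeneric("t0Channel"))

#' @rdname ChannelGrid
#' @export
setGeneric("channelTimes", function(object) standardGeneric("channelTimes"))

#' @rdname DecayTrace
#' @param object a DecayTrace.
#' @export
setGeneric("traceCounts", function(object) standardGeneric("traceCounts"))

#' @rdname DecayTrace
#' @export
setGeneric("traceKind", function(object) standardGeneric("traceKind"))

#' @rdname DecayTrace
#' @export
setGeneric("traceMeta", function(object) standardGeneric("traceMeta"))

#' @rdname DecayTrace
#' @export
setGeneric("traceGrid", function(object) standardGeneric("traceGrid"))

#' @rdname DecayTrace
#' @export
setGeneric("peakCount", function(object) standardGeneric("peakCount"))

#' Amplitudes of a multi-exponential decay
#' @param object a MultiExpParams.
#' @export
setGeneric("alphas", function(object) standardGeneric("alphas"))

#' Lifetimes of a multi-exponential decay (ns)
#' @param object a MultiExpParams.
#' @export
setGeneric("taus", function(object) standardGeneric("taus"))

#' Amplitude-weighted mean fluorescence lifetime
#'
#' Computes the mean lifetime \eqn{\tau_m = \sum_i \alpha_i \tau_i} of a
#' multi-exponential intensity decay.  The mean lifetime is proportional to
#' the fluorescence quantum yield and is the observable tracked across probe
#' sites and conditions.  Amplitudes are normalized first (with a warning if
#' they did not already sum to 1).
#'
#' @param object a [MultiExpParams-class].
#' @return mean lifetime in ns.
#' @examples
#' meanLifetime(MultiExpParams(alphas = c(0.5, 0.5), taus = c(1, 2)))  # 1.5
#' @export
setGeneric("meanLifetime", function(object) standardGeneric("meanLifetime"))

#' @rdname AnisotropyParams
#' @param object an AnisotropyParams.
#' @export
setGeneric("initialAnisotropy",
           function(object) standardGeneric("initialAnisotropy"))

#' @rdname AnisotropyParams
#' @export
setGeneric("betas", function(object) standardGeneric("betas"))

#' @rdname AnisotropyParams
#' @export
setGeneric("phis", function(object) standardGeneric("phis"))

#' @rdname AnisotropyParams
#' @export
setGeneric("phi2Capped", function(object) standardGeneric("phi2Capped"))

#' Mean rotational correlation time
#'
#' Computes \eqn{\phi_m = \sum_i \beta_i \phi_i}, the amplitude-weighted
#' mean rotational correlation time.  When the long correlation time lies
#' beyond the observable window (\code{phi2Capped(params)} is TRUE, e.g. for
#' ribosome-bound RNA) it is replaced by the reporting cap \code{capNs}
#' before averaging, since its actual value is not identifiable.
#'
#' @param object an [AnisotropyParams-class].
#' @param capNs numeric, value substituted for the long correlation time
#'   when it is flagged as beyond the window.  Default 50 ns.
#' @return mean rotational correlation time in ns.
#' @export
setGeneric("meanRotationalCorrelation",
  function(object, capNs = 50) standardGeneric("meanRotationalCorrelation"))

#' @rdname FitResult
#' @param object a FitResult.
#' @export
setGeneric("fittedParams", function(object) standardGeneric("fittedParams"))

#' @rdname FitResult
#' @export
setGeneric("chi2Reduced", function(object) standardGeneric("chi2Reduced"))

#' @rdname FitResult
#' @export
setGeneric("runsTestP", function(object) standardGeneric("runsTestP"))

#' @rdname FitResult
#' @export
setGeneric("fitResiduals", function(object) standardGeneric("fitResiduals"))

#' @rdname FitResult
#' @export
setGeneric("stdErrors", function(object) standardGeneric("stdErrors"))

#' @rdname FitResult
#' @export
setGeneric("fitInfo", function(object) standardGeneric("fitInfo"))

#' @rdname GFactor
#' @param object a GFactor.
#' @export
setGeneric("gValue", function(object) standardGeneric("gValue"))

#' @rdname TitrationSeries
#' @param object a TitrationSeries.
#' @export
setGeneric("concentrations",
           function(object) standardGeneric("concentrations"))

#' @rdname TitrationSeries
#' @export
setGeneric("responses", function(object) standardGeneric("responses"))

#' @rdname TitrationSeries
#' @export
setGeneric("responseErrors",
           function(object) standardGeneric("responseErrors"))

#' @rdname TitrationSeries
#' @export
setGeneric("seriesKind", function(object) standardGeneric("seriesKind"))

#' @rdname SiteParameterTable
#' @param object a SiteParameterTable.
#' @export
setGeneric("siteData", function(object) standardGeneric("siteData"))
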