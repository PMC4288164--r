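#' @rdname ChannelGrid
#' @aliases nChannels,ChannelGrid-method
setMethod("nChannels", "ChannelGrid", function(object) object@nChannels)

#' @rdname ChannelGrid
setMethod("dwellTime", "ChannelGrid", function(object) object@dwell)

#' @rdname ChannelGrid
setMethod("t0Channel", "ChannelGrid", function(object) object@t0Channel)

#' @rdname ChannelGrid
setMethod("channelTimes", "ChannelGrid", function(object)
  (seq_len(object@nChannels) - object@t0Channel) * object@dwell)

#' @rdname DecayTrace
setMethod("nChannels", "DecayTrace", function(object) object@grid@nChannels)

#' @rdname DecayTrace
setMethod("dwellTime", "DecayTrace", function(object) object@grid@dwell)

#' @rdname DecayTrace
setMethod("t0Channel", "DecayTrace", function(object) object@grid@t0Channel)

#' @rdname DecayTrace
setMethod("channelTimes", "DecayTrace",
          function(object) channelTimes(object@grid))

#' @rdname DecayTrace
setMethod("traceCounts", "DecayTrace", function(object) object@counts)

#' @rdname DecayTrace
setMethod("traceKind", "DecayTrace", function(object) object@kind)

#' @rdname DecayTrace
setMethod("traceMeta", "DecayTrace", function(object) object@meta)

#' @rdname DecayTrace
setMethod("traceGrid", "DecayTrace", function(object) object@grid)

#' @rdname DecayTrace
setMethod("peakCount", "DecayTrace", function(object) max(object@counts))

setMethod("alphas", "MultiExpParams", function(object) object@alphas)
setMethod("taus", "MultiExpParams", function(object) object@taus)

#' @rdname meanLifetime
setMethod("meanLifetime", "MultiExpParams", function(object) {
  a <- object@alphas
  s <- sum(a)
  if (abs(s - 1) > 1e-8) {
    warning("amplitudes not normalized; normalizing for mean lifetime")
    a <- a / s
  }
  sum(a * object@taus)
})

#' @rdname AnisotropyParams
setMethod("initialAnisotropy", "AnisotropyParams", function(object) object@r0)

#' @rdname AnisotropyParams
setMethod("betas", "AnisotropyParams", function(object) object@betas)

#' @rdname AnisotropyParams
setMethod("phis", "AnisotropyParams", function(object) object@phis)

#' @rdname AnisotropyParams
setMethod("phi2Capped", "AnisotropyParams", function(object) object@phi2Capped)

#' @rdname meanRotationalCorrelation
setMethod("meanRotationalCorrelation", "AnisotropyParams",
  function(object, capNs = 50) {
    ph <- object@phis
    if (object@phi2Capped) ph[length(ph)] <- capNs
    sum(object@betas * ph)
  })

#' @rdname FitResult
setMethod("fittedParams", "FitResult", function(object) object@params)
#' @rdname FitResult
setMethod("chi2Reduced", "FitResult", function(object) object@chi2Reduced)
#' @rdname FitResult
setMethod("runsTestP", "FitResult", function(object) object@runsTestP)
#' @rdname FitResult
setMethod("fitResiduals", "FitResult", function(object) object@residuals)
#' @rdname FitResult
setMethod("stdErrors", "FitResult", function(object) object@stderr)
#' @rdname FitResult
setMethod("fitInfo", "FitResult", function(object) object@info)

#' @rdname GFactor
setMethod("gValue", "GFactor", function(object) object@value)

#' @rdname TitrationSeries
setMethod("concentrations", "TitrationSeries",
          function(object) object@concentrations)
#' @rdname TitrationSeries
setMethod("responses", "TitrationSeries", function(object) object@responses)
#' @rdname TitrationSeries
setMethod("responseErrors", "TitrationSeries",
          function(object) object@responseErrors)
#' @rdname TitrationSeries
setMethod("seriesKind", "TitrationSeries", function(object) object@kind)

#' @rdname SiteParameterTable
setMethod("siteData", "SiteParameterTable", function(object) object@data)

setMethod("show", "ChannelGrid", function(object) {
  cat(sprintf("ChannelGrid: %d channels x %.4g ns/channel (window %.4g ns), t0 at channel %d\n",
              object@nChannels, object@dwell,
              object@nChannels * object@dwell, object@t0Channel))
})

setMethod("show", "DecayTrace", function(object) {
  cat(sprintf("DecayTrace <%s>: %d channels, peak %.6g counts, total %.6g\n",
              object@kind, nChannels(object), peakCount(object),
              sum(object@counts)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "MultiExpParams", function(object) {
  cat("MultiExpParams:\n")
  for (i in seq_along(object@taus))
    cat(sprintf("  alpha%d = %.4f  tau%d = %.4g ns\n",
                i, object@alphas[i], i, object@taus[i]))
  cat(sprintf("  tau_m = %.4g ns; scale = %.4g, background = %.4g, shift = %.3g ch\n",
              sum(object@alphas * object@taus), object@scale,
              object@background, object@shift))
})

setMethod("show", "AnisotropyParams", function(object) {
  cat(sprintf("AnisotropyParams: r0 = %.3f\n", object@r0))
  for (i in seq_along(object@phis))
    cat(sprintf("  beta%d = %.4f  phi%d = %.4g ns%s\n", i, object@betas[i],
                i, object@phis[i],
                if (i == length(object@phis) && object@phi2Capped)
                  "  (beyond window; reported against cap)" else ""))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: chi2_r = %.4f, runs-test p = %.3g, %d channels\n",
              object@chi2Reduced, object@runsTestP, object@nEvalChannels))
  show(object@params)
})

setMethod("show", "GFactor", function(object) {
  cat(sprintf("GFactor: %.4f (%s)\n", object@value, object@method))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries <%s>: %d points, concentrations %.4g..%.4g\n",
              object@kind, length(object@concentrations),
              min(object@concentrations), max(object@concentrations)))
})

setMethod("show", "QuenchingResult", function(object) {
  cat(sprintf("QuenchingResult: kq = %.3g +/- %.2g x 1e9/M/s (tau0 = %.4g ns, intercept = %.3f, R2 = %.4f)\n",
              object@kq, object@kqStderr, object@tau0, object@intercept,
              object@rSquared))
})

setMethod("show", "SiteParameterTable", function(object) {
  d <- object@data
  cat(sprintf("SiteParameterTable: %d rows; sites %s; parameters %s; conditions %s\n",
              nrow(d), paste(sort(unique(d$site)), collapse = ","),
              paste(unique(d$parameter), collapse = ","),
              paste(unique(d$condition), collapse = ", ")))
})

setMethod("show", "DispersionProfile", function(object) {
  cat(sprintf("DispersionProfile [%s @ %s]: rms flatness = %.4f\n",
              object@parameter, object@condition, object@rmsFlatness))
  print(stats::setNames(round(object@deviations, 4),
                        paste0("site", object@sites)))
})
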