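#' Site-dispersion profile of a fluorescence observable
#'
#' For one observable under one condition, computes per-site relative
#' deviations \code{(observed - mean)/mean}, where the mean is taken over
#' all sites available for that condition, plus the root-mean-square of the
#' deviations as a single "non-flatness" figure.  A structured RNA shows
#' large site-to-site dispersion; loss of structure (urea denaturation, or
#' ribosome-bound RNA at high temperature) flattens the profile.
#'
#' @param table a [SiteParameterTable-class].
#' @param parameter observable name, e.g. \code{"tau_m"}, \code{"phi_m"},
#'   \code{"kq"}.
#' @param condition condition label, e.g. \code{"20C"}.
#' @return a [DispersionProfile-class].
#' @export
dispersionProfile <- function(table, parameter, condition) {
  stopifnot(is(table, "SiteParameterTable"))
  d <- siteData(table)
  d <- d[d$parameter == parameter & d$condition == condition, , drop = FALSE]
  d <- d[is.finite(d$value), , drop = FALSE]
  if (nrow(d) < 2L)
    stop(sprintf("fewer than 2 sites available for %s at %s",
                 parameter, condition))
  d <- d[order(d$site), , drop = FALSE]
  m <- mean(d$value)
  if (m <= 0) stop("mean value must be positive")
  dev <- (d$value - m) / m
  new("DispersionProfile", sites = as.integer(d$site), deviations = dev,
      rmsFlatness = sqrt(mean(dev^2)), parameter = parameter,
      condition = condition)
}

#' Compare profile flatness between two conditions
#'
#' Computes the rms flatness of one observable under two conditions and
#' their ratio, with a bootstrap interval obtained by resampling each site
#' value from a normal distribution centered on the reported value with the
#' reported standard error (sites without an error are held fixed).  Values
#' resampled to <= 0 are truncated to a small positive floor so relative
#' deviations stay defined.
#'
#' @param table a [SiteParameterTable-class].
#' @param parameter observable name.
#' @param conditionA,conditionB condition labels; the ratio reported is
#'   rms(A) / rms(B).
#' @param nBoot bootstrap resamples; default 1000.
#' @param seed integer seed for the bootstrap.
#' @param level interval coverage; default 0.95.
#' @return list with `rmsA`, `rmsB`, `ratio`, `bootstrapInterval` (length-2
#'   numeric) and `nBoot`.
#' @export
flatnessCompare <- function(table, parameter, conditionA, conditionB,
                            nBoot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(is(table, "SiteParameterTable"))
  d <- siteData(table)
  pick <- function(cond) {
    x <- d[d$parameter == parameter & d$condition == cond, , drop = FALSE]
    if (nrow(x) < 2L)
      stop(sprintf("condition '%s' not available for %s", cond, parameter))
    x[order(x$site), , drop = FALSE]
  }
  a <- pick(conditionA)
  b <- pick(conditionB)
  rms <- function(v) {
    m <- mean(v)
    sqrt(mean(((v - m) / m)^2))
  }
  rmsA <- rms(a$value)
  rmsB <- rms(b$value)
  boot <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      ra <- a$value + ifelse(is.na(a$error), 0, a$error) *
        stats::rnorm(nrow(a))
      rb <- b$value + ifelse(is.na(b$error), 0, b$error) *
        stats::rnorm(nrow(b))
      rms(pmax(ra, 1e-6)) / rms(pmax(rb, 1e-6))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  list(rmsA = rmsA, rmsB = rmsB, ratio = rmsA / rmsB,
       bootstrapInterval = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       nBoot = as.integer(nBoot))
}

#' Load a bundled site-parameter table
#'
#' The package ships the published site-by-condition fluorescence
#' parameters for 2-AP-labeled MiniROSE RNA: mean lifetime (tau_m, ns),
#' mean rotational correlation time (phi_m, ns) and bimolecular quenching
#' constant (kq, 1e9/M/s) at seven labeling positions.  Three tables are
#' available: the free RNA (20C, 45C, 45C + 7 M urea), the ribosome-bound
#' RNA (20C, 45C; phi_m computed with the long correlation time capped at
#' 50 ns), and the G15-deletion variant (tau_m only, three sites).
#'
#' @param which one of \code{"free"}, \code{"bound"}, \code{"g15del"}.
#' @return a [SiteParameterTable-class].
#' @examples
#' tab <- bundledSiteTable("free")
#' dispersionProfile(tab, "tau_m", "20C")
#' @export
bundledSiteTable <- function(which = c("free", "bound", "g15del")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("minirose_", which, ".tsv"),
                   package = "tcspcfit", mustWork = TRUE)
  readSiteTable(f)
}

#' Read / write a site-parameter table
#'
#' Tab-separated text with comment lines prefixed '#' and columns
#' \code{site}, \code{condition}, \code{parameter}, \code{value},
#' \code{error}.
#'
#' @param path file path.
#' @return a [SiteParameterTable-class].
#' @export
readSiteTable <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  SiteParameterTable(d)
}

#' @rdname readSiteTable
#' @param table a [SiteParameterTable-class] to write.
#' @export
writeSiteTable <- function(table, path) {
  stopifnot(is(table, "SiteParameterTable"))
  utils::write.table(siteData(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
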