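#' Write a decay trace to delimited text
#'
#' Two-column tab-delimited format (channel index, counts) with '#'-prefixed
#' header lines carrying the grid (dwell, t0_channel), the trace kind and
#' any scalar/character metadata.  [readTrace()] round-trips losslessly.
#'
#' @param trace a [DecayTrace-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "DecayTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dwell: %.17g", dwellTime(trace)), con)
  writeLines(sprintf("# t0_channel: %d", t0Channel(trace)), con)
  writeLines(sprintf("# kind: %s", traceKind(trace)), con)
  meta <- traceMeta(trace)
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.list(v))
      v <- jsonlite::toJSON(v, auto_unbox = TRUE, digits = NA)
    if (length(v) == 1L && (is.numeric(v) || is.character(v) ||
                            is.logical(v)))
      writeLines(sprintf("# meta.%s: %s", nm,
                         if (is.numeric(v)) sprintf("%.17g", v)
                         else as.character(v)), con)
  }
  writeLines(sprintf("%d\t%.17g", seq_len(nChannels(trace)),
                     traceCounts(trace)), con)
  invisible(path)
}

#' Read a decay trace from delimited text
#'
#' @param path file written by [writeTrace()] (or hand-assembled in the
#'   same format).
#' @return a [DecayTrace-class].
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  isHeader <- startsWith(lines, "#")
  header <- lines[isHeader]
  body <- lines[!isHeader & nzchar(lines)]
  getField <- function(key) {
    pat <- paste0("^#\\s*", key, ":\\s*")
    hit <- grep(pat, header, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(pat, "", hit[1])
  }
  dwell <- getField("dwell")
  if (is.null(dwell))
    stop(sprintf("parse error in '%s': missing '# dwell:' header", path))
  t0 <- getField("t0_channel")
  if (is.null(t0))
    stop(sprintf("parse error in '%s': missing '# t0_channel:' header", path))
  kind <- getField("kind")
  if (is.null(kind)) kind <- "decay"
  meta <- list()
  mh <- grep("^#\\s*meta\\.", header, value = TRUE)
  for (h in mh) {
    nm <- sub("^#\\s*meta\\.([^:]+):.*$", "\\1", h)
    val <- sub("^#\\s*meta\\.[^:]+:\\s*", "", h)
    if (startsWith(val, "{") || startsWith(val, "[")) {
      meta[[nm]] <- jsonlite::fromJSON(val)
    } else {
      num <- suppressWarnings(as.numeric(val))
      meta[[nm]] <- if (is.na(num)) val else num
    }
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("parse error in '%s' at data line %d: expected 2 columns",
                 path, bad[1]))
  counts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(counts))
    stop(sprintf("parse error in '%s': non-numeric counts at data line %d",
                 path, which(is.na(counts))[1]))
  if (any(counts < 0))
    stop(sprintf("invalid trace '%s': negative counts", path))
  grid <- ChannelGrid(nChannels = length(counts),
                      dwell = as.numeric(dwell),
                      t0Channel = as.integer(as.numeric(t0)))
  DecayTrace(counts, grid, kind = kind, meta = meta)
}

#' Write / read a titration series as delimited text
#'
#' Tab-separated columns \code{concentration}, \code{response},
#' \code{error}, with a '# kind:' header line.
#'
#' @param series a [TitrationSeries-class].
#' @param path file path.
#' @return `path` / a [TitrationSeries-class].
#' @export
writeTitrationSeries <- function(series, path) {
  stopifnot(is(series, "TitrationSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", seriesKind(series)), con)
  writeLines("concentration\tresponse\terror", con)
  err <- responseErrors(series)
  if (!length(err)) err <- rep(NA_real_, length(responses(series)))
  writeLines(sprintf("%.17g\t%.17g\t%.17g", concentrations(series),
                     responses(series), err), con)
  invisible(path)
}

#' @rdname writeTitrationSeries
#' @export
readTitrationSeries <- function(path) {
  lines <- readLines(path)
  kindLine <- grep("^#\\s*kind:", lines, value = TRUE)
  if (!length(kindLine))
    stop(sprintf("parse error in '%s': missing '# kind:' header", path))
  kind <- sub("^#\\s*kind:\\s*", "", kindLine[1])
  d <- utils::read.table(textConnection(lines[!startsWith(lines, "#")]),
                         header = TRUE, sep = "\t")
  err <- d$error
  if (all(is.na(err))) err <- numeric()
  TitrationSeries(d$concentration, d$response, err, kind = kind)
}
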