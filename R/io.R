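# Plain-text storage: CSV for traces, curves, histograms and dose-response
# tables (with minimal self-describing headers), JSON for fit reports.

#' Write / read a photon trace as CSV
#'
#' Schema: comment header lines carrying \code{bin_time_s} and
#' \code{duration_s}, then \code{bin_index,count}.
#'
#' @param trace a \code{\linkS4class{PhotonTrace}}
#' @param path file path
#' @return \code{readTraceCsv} returns a \code{\linkS4class{PhotonTrace}}
#' @export
writeTraceCsv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_time_s=%.17g", binTime(trace)),
               sprintf("# duration_s=%.17g", traceDuration(trace)),
               "bin_index,count"), con)
  write.table(data.frame(seq_along(counts(trace)) - 1L, counts(trace)),
              con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  bt <- as.numeric(sub("# bin_time_s=", "", hdr[1], fixed = TRUE))
  d <- read.csv(path, comment.char = "#")
  photonTrace(d$count, bt, metadata = list(source = path))
}

#' Write / read a correlation curve as CSV
#'
#' Schema: a comment header with the mean count rate and native bin time,
#' then \code{lag_s,G,npts}.
#'
#' @param curve a \code{\linkS4class{CorrelationCurve}}
#' @param path file path
#' @return \code{readCurveCsv} returns a
#'   \code{\linkS4class{CorrelationCurve}}
#' @export
writeCurveCsv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mean_rate_cps=%.17g", meanRate(curve)),
               sprintf("# bin_time_s=%.17g", binTime(curve)),
               "lag_s,G,npts"), con)
  write.table(data.frame(lagTimes(curve), corrValues(curve),
                         nPoints(curve)),
              con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCurveCsv
#' @export
readCurveCsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  mr <- as.numeric(sub("# mean_rate_cps=", "", hdr[1], fixed = TRUE))
  bt <- as.numeric(sub("# bin_time_s=", "", hdr[2], fixed = TRUE))
  d <- read.csv(path, comment.char = "#")
  new("CorrelationCurve", lags = d$lag_s, G = d$G, npts = d$npts,
      meanRate = mr, binTime = bt)
}

#' Write / read a dose-response dataset as CSV
#'
#' Schema: \code{concentration_M,response,replicate}.
#'
#' @param data data.frame from \code{\link{doseResponseDataset}}
#' @param path file path
#' @return \code{readDoseResponseCsv} returns the validated data.frame
#' @export
writeDoseResponseCsv <- function(data, path) {
  write.csv(data[, c("concentration_M", "response", "replicate")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeDoseResponseCsv
#' @export
readDoseResponseCsv <- function(path) {
  d <- read.csv(path)
  doseResponseDataset(d$concentration_M, d$response, d$replicate)
}

#' Write / read a photon counting histogram as CSV
#'
#' Schema: a comment header with the counting bin time and total bin count,
#' then \code{k,frequency}.
#'
#' @param hist a \code{\linkS4class{PCHistogram}}
#' @param path file path
#' @return \code{readPchCsv} returns a \code{\linkS4class{PCHistogram}}
#' @export
writePchCsv <- function(hist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_time_s=%.17g", hist@binTime),
               sprintf("# n_bins=%.17g", hist@nBins),
               "k,frequency"), con)
  write.table(data.frame(hist@k, hist@frequency), con, sep = ",",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePchCsv
#' @export
readPchCsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  bt <- as.numeric(sub("# bin_time_s=", "", hdr[1], fixed = TRUE))
  nb <- as.numeric(sub("# n_bins=", "", hdr[2], fixed = TRUE))
  d <- read.csv(path, comment.char = "#")
  new("PCHistogram", k = as.integer(d$k), frequency = d$frequency,
      binTime = bt, nBins = nb)
}

#' Serialize a fit result to JSON
#'
#' Produces a self-contained fit report (model, parameters, derived
#' quantities, goodness of fit) for any of the package's fit classes.
#'
#' @param fit an \code{\linkS4class{ACFFit}},
#'   \code{\linkS4class{CalibrationResult}}, \code{\linkS4class{PCHFit}} or
#'   \code{\linkS4class{EmaxFit}}
#' @param path optional file path; when NULL the JSON string is returned
#' @return JSON string (invisibly when written to a file)
#' @export
writeFitJson <- function(fit, path = NULL) {
  rep <- if (is(fit, "ACFFit")) {
    list(type = "acf_fit", model = fit@model, N_total = fit@Ntotal,
         components = fit@components, T_dark = fit@Tdark,
         tau_tr_s = fit@tauTr, S = fit@S, baseline = fit@offset,
         chisq = fit@chisq,
         converged = fit@converged, degenerate = fit@degenerate)
  } else if (is(fit, "CalibrationResult")) {
    list(type = "calibration", tau_D_s = fit@tauD, omega_um = fit@omega,
         beam_area_um2 = fit@beamArea, S = fit@S,
         D_ref_um2_s = fit@Dref)
  } else if (is(fit, "PCHFit")) {
    list(type = "pch_fit", components = fit@components, F = fit@F,
         chisq = fit@chisq, bin_time_s = fit@binTime,
         geometry = fit@geometry, converged = fit@converged,
         collapsed = fit@collapsed,
         correction = "first-order out-of-focus (k = 1 jump intensity)")
  } else if (is(fit, "EmaxFit")) {
    list(type = "emax_fit", no_response = fit@noResponse, emax = fit@emax,
         ec50_M = fit@ec50, pec50 = fit@pec50, basal = fit@basal,
         se_pec50 = fit@sePec50, rss = fit@rss, n = fit@n)
  } else stop("unsupported fit class: ", class(fit))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
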