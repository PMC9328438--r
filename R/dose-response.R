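# Emax concentration-response generation, normalization and fitting.

#' Build a validated dose-response dataset
#'
#' Concentration-response data are kept as a plain data.frame with columns
#' \code{concentration_M}, \code{response} and \code{replicate} (the CSV
#' schema of \code{\link{readDoseResponseCsv}}).
#'
#' @param concentrations agonist concentrations (molar, strictly positive)
#' @param responses responses (assay units), same length
#' @param replicates replicate index per row
#' @return data.frame sorted by concentration
#' @export
doseResponseDataset <- function(concentrations, responses,
                                replicates = rep(1L, length(concentrations))) {
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (length(responses) != length(concentrations) ||
      length(replicates) != length(concentrations))
    stop("concentrations, responses and replicates must have equal length")
  d <- data.frame(concentration_M = concentrations, response = responses,
                  replicate = as.integer(replicates))
  d[order(d$concentration_M), , drop = FALSE]
}

#' Generate synthetic Emax concentration-response data
#'
#' Responses follow \eqn{basal + E_{max} A / (A + EC_{50})} with
#' \eqn{EC_{50} = 10^{-pEC_{50}}}, plus Gaussian noise.
#'
#' @param emax maximal response
#' @param pec50 -log10 of the half-maximal concentration (molar)
#' @param concentrations agonist concentrations (molar, > 0)
#' @param noiseSd Gaussian noise standard deviation (response units)
#' @param basal basal response added to every point
#' @param replicates number of replicate measurements per concentration
#' @param seed integer RNG seed
#' @return data.frame as from \code{\link{doseResponseDataset}}
#' @examples
#' d <- generateDoseResponse(100, 7.35, 10^seq(-10, -6.5, 0.5), noiseSd = 0)
#' pec50(fitEmax(d))
#' @export
generateDoseResponse <- function(emax, pec50, concentrations, noiseSd = 0,
                                 basal = 0, replicates = 1L, seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  ec50 <- 10^(-pec50)
  conc <- rep(concentrations, each = replicates)
  repl <- rep(seq_len(replicates), times = length(concentrations))
  mu <- basal + emax * conc / (conc + ec50)
  y <- withLocalSeed(seed, function() mu + rnorm(length(mu), 0, noiseSd))
  doseResponseDataset(conc, y, repl)
}

#' Normalize responses to reference levels
#'
#' Expresses a raw response as a percentage of the window between a basal
#' reference (0%) and a maximal reference (100%), e.g. basal and the 10 uM
#' forskolin response: \code{100 * (raw - basalRef) / (maxRef - basalRef)}.
#'
#' @param raw raw response(s)
#' @param basalRef basal reference level
#' @param maxRef maximal reference level (must differ from basalRef)
#' @return percentage(s)
#' @export
normalizeResponse <- function(raw, basalRef, maxRef) {
  if (maxRef == basalRef)
    stop("maxRef must differ from basalRef (zero normalization window)")
  100 * (raw - basalRef) / (maxRef - basalRef)
}

# Profile RSS at a fixed pEC50: the model is then linear in (basal, emax).
emaxProfileRss <- function(pec50, conc, y, fitBasal) {
  x <- conc / (conc + 10^(-pec50))
  X <- if (fitBasal) cbind(1, x) else cbind(x)
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Fit the Emax concentration-response equation
#'
#' Nonlinear least-squares fit of
#' \deqn{Response = basal + E_{max} \frac{A}{A + EC_{50}}}
#' (Hill slope fixed at 1).  The concentration axis is handled in log space:
#' pEC50 is profiled (the model is linear in basal and Emax at fixed pEC50),
#' scanned on a grid two decades beyond the data and polished with
#' one-dimensional minimization, which is robust and deterministic.
#'
#' Flat data yield the "no response" (NR) outcome: an F-test of the Emax
#' model against a constant at level \code{alpha} decides whether Emax is
#' distinguishable from zero.
#'
#' @param data data.frame with columns \code{concentration_M} and
#'   \code{response} (at least 4 distinct concentrations spanning >= 2 log
#'   units)
#' @param fitBasal fit a basal offset (TRUE) or fix basal at 0
#' @param alpha significance level of the no-response test
#' @return an \code{\linkS4class{EmaxFit}}
#' @export
fitEmax <- function(data, fitBasal = TRUE, alpha = 0.05) {
  conc <- data$concentration_M
  y <- data$response
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations")
  if (log10(max(conc) / min(conc)) < 2)
    stop("concentrations must span at least 2 log units")
  n <- length(y)

  lo <- -log10(max(conc)) - 2
  hi <- -log10(min(conc)) + 2
  grid <- seq(lo, hi, length.out = 200)
  rss <- vapply(grid, function(p) emaxProfileRss(p, conc, y, fitBasal)$rss,
                numeric(1))
  i <- which.min(rss)
  bracket <- c(grid[max(i - 1, 1)], grid[min(i + 1, length(grid))])
  opt <- optimize(function(p) emaxProfileRss(p, conc, y, fitBasal)$rss,
                  interval = bracket, tol = 1e-10)
  pec <- opt$minimum
  prof <- emaxProfileRss(pec, conc, y, fitBasal)
  basal <- if (fitBasal) prof$coef[1] else 0
  emaxv <- if (fitBasal) prof$coef[2] else prof$coef[1]
  rss1 <- prof$rss

  # no-response test: Emax model vs constant
  npar1 <- 2 + fitBasal
  ybar_rss <- sum((y - mean(y))^2)
  if (ybar_rss < 1e-12 * max(1, mean(y)^2)) {
    return(new("EmaxFit", emax = NA_real_, ec50 = NA_real_,
               pec50 = NA_real_, basal = NA_real_, sePec50 = NA_real_,
               noResponse = TRUE, rss = rss1, n = n))
  }
  Fstat <- ((ybar_rss - rss1) / (npar1 - 1)) / (rss1 / max(n - npar1, 1))
  pNR <- if (rss1 < 1e-14 * ybar_rss) 0 else
    pf(Fstat, npar1 - 1, max(n - npar1, 1), lower.tail = FALSE)
  if (!is.finite(pNR) || pNR >= alpha || emaxv == 0) {
    return(new("EmaxFit", emax = NA_real_, ec50 = NA_real_,
               pec50 = NA_real_, basal = NA_real_, sePec50 = NA_real_,
               noResponse = TRUE, rss = rss1, n = n))
  }

  # standard error of pEC50 from the local quadratic of the profile RSS:
  # se = sqrt(2 sigma^2 / d2RSS/dpec^2)
  h <- 0.05
  d2 <- (emaxProfileRss(pec + h, conc, y, fitBasal)$rss - 2 * rss1 +
         emaxProfileRss(pec - h, conc, y, fitBasal)$rss) / h^2
  sigma2 <- rss1 / max(n - npar1, 1)
  se <- if (d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_

  new("EmaxFit", emax = unname(emaxv), ec50 = 10^(-pec), pec50 = pec,
      basal = unname(basal), sePec50 = se, noResponse = FALSE, rss = rss1,
      n = n)
}
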