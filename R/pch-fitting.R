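# Fitting PCH models to histograms.

# Deterministic jitter grid for (lambda, Nbar) starts.
PCH_START_JITTER <- list(c(1, 1), c(0.4, 2), c(2.5, 0.6), c(0.15, 4),
                         c(6, 0.3))

# Moment-based starting guess: for a single species
#   mean = gamma1 * Nbar * lambda,  var - mean = gamma2 * Nbar * lambda^2
# with gamma2 = 1/8 (3D-Gaussian) or 1/4 (2D).
pchMomentStart <- function(hist, geometry) {
  g1 <- PCH_GAMMA[[geometry]]
  g2 <- if (geometry == "3d") 1 / 8 else 1 / 4
  m <- sum(hist@k * hist@frequency) / hist@nBins
  v <- sum((hist@k - m)^2 * hist@frequency) / (hist@nBins - 1)
  lam <- max((v / m - 1) * g1 / g2, 0.02)
  list(lambda = lam, Nbar = max(m / (g1 * lam), 1e-3))
}

pchChisq <- function(obs, expd) sum((obs - expd)^2 / pmax(expd, 1e-10))

#' Fit a molecular-brightness model to a photon counting histogram
#'
#' Minimum chi-square fit (frequencies weighted by the square root of the
#' expected frequency) of a one- or two-component PCH model.  Brightness is
#' reported in counts molecule^-1 s^-1 (counts per bin divided by the bin
#' time).  For two components the brightnesses are parameterized as
#' \eqn{\epsilon_1} and a ratio \eqn{\ge 1}, so components are returned
#' sorted by increasing brightness; a fitted ratio below 2 is flagged as a
#' collapsed two-component fit.
#'
#' @param hist a \code{\linkS4class{PCHistogram}} (at least 1e4 bins for
#'   stable tails)
#' @param nComponents 1 or 2
#' @param Ffixed fix the first-order out-of-focus correction to this value
#'   (the frozen calibration value); NULL fits F freely in [0, 5]
#' @param geometry "3d" (default) or "2d" molecular detection function
#' @return a \code{\linkS4class{PCHFit}}
#' @seealso \code{\link{calibratePCHCorrection}}, \code{\link{selectPCHModel}}
#' @export
fitPCH <- function(hist, nComponents = 1L, Ffixed = NULL,
                   geometry = c("3d", "2d")) {
  geometry <- match.arg(geometry)
  nComponents <- as.integer(nComponents)
  if (!nComponents %in% 1:2) stop("nComponents must be 1 or 2")
  if (hist@nBins < 1e4)
    warning("fewer than 1e4 bins: PCH tails may be unstable")
  kfit <- max(hist@k) + 10L
  obs <- c(hist@frequency, rep(0, kfit - max(hist@k)))
  bt <- hist@binTime
  fitF <- is.null(Ffixed)

  objective <- function(p) {
    if (nComponents == 1L) {
      cmp <- data.frame(epsilon = exp(p[1]) / bt, Nbar = exp(p[2]))
      Fv <- if (fitF) p[3] else Ffixed
    } else {
      cmp <- data.frame(epsilon = c(exp(p[1]), exp(p[1] + p[2])) / bt,
                        Nbar = exp(p[3:4]))
      Fv <- if (fitF) p[5] else Ffixed
    }
    pm <- tryCatch(pchModel(cmp, Fv, bt, kfit, geometry),
                   error = function(e) NULL)
    if (is.null(pm)) return(1e12)
    pchChisq(obs, hist@nBins * pm)
  }

  ms <- pchMomentStart(hist, geometry)
  # one-component fits are well conditioned; three starts suffice
  jitters <- if (nComponents == 1L) PCH_START_JITTER[1:3] else
    PCH_START_JITTER
  starts <- lapply(jitters, function(j) {
    lam <- ms$lambda * j[1]; Nb <- ms$Nbar * j[2]
    if (nComponents == 1L) {
      p <- c(log(lam), log(Nb))
    } else {
      p <- c(log(lam / 3), log(9), log(Nb / 2), log(Nb / 2))
    }
    if (fitF) p <- c(p, 0.2)
    p
  })
  if (nComponents == 1L) {
    lower <- c(log(1e-6), log(1e-5))
    upper <- c(log(100), log(1e5))
  } else {
    lower <- c(log(1e-6), 0, log(1e-5), log(1e-5))
    upper <- c(log(100), log(1e4), log(1e5), log(1e5))
  }
  if (fitF) { lower <- c(lower, 0); upper <- c(upper, 5) }

  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      optim(p0, objective, method = "L-BFGS-B", lower = lower,
            upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("PCH fit did not converge from any initialization")
  p <- best$par
  if (nComponents == 1L) {
    cmp <- data.frame(epsilon = exp(p[1]) / bt, Nbar = exp(p[2]))
    Fv <- if (fitF) p[3] else Ffixed
    collapsed <- FALSE
    npar <- 2 + fitF
  } else {
    cmp <- data.frame(epsilon = c(exp(p[1]), exp(p[1] + p[2])) / bt,
                      Nbar = exp(p[3:4]))
    Fv <- if (fitF) p[5] else Ffixed
    collapsed <- exp(p[2]) < 2
    npar <- 4 + fitF
  }
  dof <- max(kfit + 1 - npar, 1)
  new("PCHFit", components = cmp, F = Fv, chisq = best$value / dof,
      converged = TRUE, collapsed = collapsed, binTime = bt,
      geometry = geometry)
}

#' Calibrate the first-order out-of-focus correction
#'
#' One-component fit of a calibration-dye histogram (typically Rhodamine 6G
#' at 20 nM, 20 us bins) with F free.  The returned fit's F value is frozen
#' and reused for all subsequent PCH fits of the session.
#'
#' @param histCalib a \code{\linkS4class{PCHistogram}} from a single-species
#'   solution trace
#' @param geometry molecular detection function of the calibration trace
#' @return a \code{\linkS4class{PCHFit}}; extract the correction with
#'   \code{\link{correctionF}}
#' @export
calibratePCHCorrection <- function(histCalib, geometry = "3d") {
  fit <- fitPCH(histCalib, 1L, Ffixed = NULL, geometry = geometry)
  if (correctionF(fit) > 5 - 1e-6)
    stop("first-order correction at its bound (F > 5): bad calibration data")
  fit
}

#' Choose between one- and two-component PCH models
#'
#' Fits both models and selects by an F-test on the chi-square reduction at
#' the given significance level; a two-component fit that collapsed
#' (brightness ratio < 2) never wins (parsimony).  Returns NA components
#' when either fit failed to converge (the selection abstains).
#'
#' @param hist a \code{\linkS4class{PCHistogram}}
#' @param Ffixed frozen first-order correction (NULL fits it freely)
#' @param geometry molecular detection function
#' @param alpha significance level of the F-test
#' @return list with elements \code{nComponents} (1, 2 or NA), \code{fit1},
#'   \code{fit2} and \code{pValue}
#' @export
selectPCHModel <- function(hist, Ffixed = NULL, geometry = "3d",
                           alpha = 0.01) {
  fit1 <- tryCatch(fitPCH(hist, 1L, Ffixed, geometry),
                   error = function(e) NULL)
  fit2 <- tryCatch(fitPCH(hist, 2L, Ffixed, geometry),
                   error = function(e) NULL)
  if (is.null(fit1) || is.null(fit2))
    return(list(nComponents = NA_integer_, fit1 = fit1, fit2 = fit2,
                pValue = NA_real_))
  kfit <- max(hist@k) + 10L
  npar1 <- 2L + is.null(Ffixed)
  npar2 <- 4L + is.null(Ffixed)
  dof1 <- max(kfit + 1L - npar1, 1L)
  dof2 <- max(kfit + 1L - npar2, 1L)
  raw1 <- chiSquared(fit1) * dof1
  raw2 <- chiSquared(fit2) * dof2
  Fstat <- ((raw1 - raw2) / (npar2 - npar1)) / (raw2 / dof2)
  pValue <- if (is.finite(Fstat) && Fstat > 0)
    pf(Fstat, npar2 - npar1, dof2, lower.tail = FALSE) else 1
  pick2 <- pValue < alpha && !fit2@collapsed
  list(nComponents = if (pick2) 2L else 1L, fit1 = fit1, fit2 = fit2,
       pValue = pValue)
}
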