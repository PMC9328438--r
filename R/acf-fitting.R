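# Nonlinear least-squares fitting of autocorrelation curves.
#
# All fits are bounded Levenberg-Marquardt (minpack.lm::nls.lm) with a small
# set of deterministically jittered initializations; the lowest-chisq
# converged solution wins, so results do not depend on start ordering.
# Residuals are weighted by sqrt(npts): the per-lag uncertainty is taken to
# scale as 1/sqrt(number of averaged products).
#
# The cell models (membrane, ligand) additionally fit a small free baseline:
# a finite trace of duration T biases the normalized ACF by roughly
# -(2/T) Int G dtau (the mean is estimated from the same trace), which is
# non-negligible for slowly decaying 2D membrane correlations and would
# otherwise shorten the fitted dwell times.  The baseline is bounded to
# +/- 30% of the amplitude guess; it converges to 0 on noiseless curves.

# Default fit window (s): excludes lags below the afterpulsing scale that the
# simulator does not model and the poorly averaged tail beyond 1 s.
ACF_FIT_WINDOW <- c(4e-6, 1)

# Bound on the dark-state relaxation time: keeps the photophysics term from
# absorbing diffusion decay.
TAU_TR_MAX <- 50e-6

# Deterministic multiplicative jitters applied to the time-scale and
# amplitude starts (5 initializations).
ACF_START_JITTER <- list(c(tau = 1, N = 1), c(tau = 0.3, N = 1.5),
                         c(tau = 3, N = 0.7), c(tau = 0.1, N = 1),
                         c(tau = 10, N = 1))

# Window + finiteness mask applied to a curve before fitting.
curveFitData <- function(curve, window) {
  lag <- lagTimes(curve)
  keep <- lag >= window[1] & lag <= window[2] & is.finite(corrValues(curve))
  if (sum(keep) < 8) stop("fewer than 8 usable lags in the fit window")
  list(lag = lag[keep], G = corrValues(curve)[keep],
       w = sqrt(nPoints(curve)[keep]))
}

# Heuristic amplitude / time-scale starts from the curve itself.
acfStartGuess <- function(fd) {
  G0 <- max(mean(head(fd$G, 3)), 1e-4)
  half <- which(fd$G <= G0 / 2)
  tau0 <- if (length(half)) fd$lag[half[1]] else stats::median(fd$lag)
  list(N0 = 1 / G0, tau0 = max(tau0, fd$lag[1]), G0 = G0)
}

# Run nls.lm over the start list; return the best converged solution.
# Box constraints are imposed through the smooth sine transform
# p = lower + (upper - lower) (sin z + 1)/2 and the problem solved
# unconstrained in z: nls.lm's clamped box handling can wedge trajectories
# into bound corners, while the transform leaves Levenberg-Marquardt free.
acfFitEngine <- function(fd, residFun, starts, lower, upper) {
  width <- upper - lower
  toZ <- function(p)
    asin(pmin(pmax(2 * (p - lower) / width - 1, -1), 1))
  toP <- function(z) lower + width * (sin(z) + 1) / 2
  residZ <- function(z, fd) residFun(toP(z), fd)
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = toZ(p0), fn = residZ, fd = fd,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 1000, maxfev = 20000, ftol = 1e-15,
                             ptol = 1e-15))),
      error = function(e) NULL)
    if (is.null(res) || !res$info %in% 1:4) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = unname(toP(res$par)), rss = rss,
                   nlag = length(fd$G))
  }
  if (is.null(best))
    stop("autocorrelation fit did not converge from any initialization")
  best
}

reducedChisq <- function(best, npar) best$rss / max(best$nlag - npar, 1)

#' Fit the calibration model and determine the detection volume
#'
#' Fits a single 3D diffusing component with a pre-exponential triplet term
#' to the autocorrelation of a dye standard of known diffusion coefficient,
#' then converts the dwell time to the beam-waist radius
#' \eqn{\omega = \sqrt{4 \tau_D D_{ref}}} and beam area
#' \eqn{A = \pi \omega^2}.  The structure parameter is fitted within [3, 10].
#'
#' @param curve a \code{\linkS4class{CorrelationCurve}} spanning at least 3
#'   decades of lag
#' @param Dref reference diffusion coefficient of the dye (um^2/s)
#' @param window lag fit window (s)
#' @return a \code{\linkS4class{CalibrationResult}}
#' @export
fitCalibration <- function(curve, Dref, window = ACF_FIT_WINDOW) {
  if (Dref <= 0) stop("Dref must be > 0")
  fd <- curveFitData(curve, window)
  if (max(fd$lag) / min(fd$lag) < 1e3)
    stop("calibration curve must span at least 3 decades of lag")
  sg <- acfStartGuess(fd)
  # p = (logN, logTauD, S, T, logTauTr)
  lower <- c(log(1e-4), log(1e-7), 3, 0, log(1e-7))
  upper <- c(log(1e7), log(0.1), 10, 0.8, log(TAU_TR_MAX))
  residFun <- function(p, fd) {
    (.acfEval(fd$lag, exp(p[1]), exp(p[2]), 1, TRUE, p[4], exp(p[5]),
              p[3]) - fd$G) * fd$w
  }
  starts <- lapply(ACF_START_JITTER, function(j)
    c(log(sg$N0 * j["N"]), log(sg$tau0 * j["tau"]), 5, 0.1, log(4e-6)))
  best <- acfFitEngine(fd, residFun, starts, lower, upper)
  p <- best$par
  tauD <- exp(p[2])
  if (tauD / exp(lower[2]) < 1.01 || exp(upper[2]) / tauD < 1.01)
    stop("calibration dwell time ran into a parameter bound")
  omega <- sqrt(4 * tauD * Dref)
  cmp <- data.frame(kind = "3D", tauD = tauD, fraction = 1, fixed = FALSE)
  fit <- new("ACFFit", model = "calibration", Ntotal = exp(p[1]),
             components = cmp, Tdark = p[4], tauTr = exp(p[5]), S = p[3],
             offset = 0, chisq = reducedChisq(best, 5), converged = TRUE,
             degenerate = FALSE)
  new("CalibrationResult", tauD = tauD, omega = omega,
      beamArea = pi * omega^2, S = p[3], Dref = Dref, fit = fit)
}

# Shared machinery for the cell models: a fixed-S fit with either one or two
# free 2D components, optionally preceded by a fixed 3D (free-ligand)
# component, plus a free baseline.  Falls back to the single-2D variant when
# the two dwell times collapse within a factor 2.
fitCellACF <- function(curve, S, model, tauD1Fixed = NULL,
                       window = ACF_FIT_WINDOW) {
  fd <- curveFitData(curve, window)
  sg <- acfStartGuess(fd)
  G0g <- sg$G0
  hasLigand <- identical(model, "ligand")
  if (hasLigand && (is.null(tauD1Fixed) || tauD1Fixed <= 0))
    stop("ligand fits require tauD1Fixed from a free-ligand calibration fit")

  finishFit <- function(Ntotal, tauD, frac, is3d, fixed, Tdark, tauTr,
                        off, chisq, degenerate) {
    cmp <- data.frame(kind = ifelse(is3d, "3D", "2D"), tauD = tauD,
                      fraction = frac, fixed = fixed)
    cmp <- cmp[order(cmp$tauD), , drop = FALSE]
    rownames(cmp) <- NULL
    new("ACFFit", model = model, Ntotal = Ntotal, components = cmp,
        Tdark = Tdark, tauTr = tauTr, S = S, offset = off, chisq = chisq,
        converged = TRUE, degenerate = degenerate)
  }

  if (hasLigand) {
    # p = (logN, f1, q, logTau2, logRatio, T, logTauTr, off)
    lower <- c(log(1e-4), 0, 0, log(1e-4), log(1), 0, log(1e-7), -0.3)
    upper <- c(log(1e7), 1, 1, log(5), log(1e5), 0.8, log(TAU_TR_MAX), 0.3)
    residFun <- function(p, fd) {
      f1 <- p[2]; f2 <- (1 - p[2]) * p[3]; f3 <- (1 - p[2]) * (1 - p[3])
      (.acfEval(fd$lag, exp(p[1]),
                c(tauD1Fixed, exp(p[4]), exp(p[4] + p[5])),
                c(f1, f2, f3), c(TRUE, FALSE, FALSE), p[6], exp(p[7]),
                S) + p[8] * G0g - fd$G) * fd$w
    }
    starts <- lapply(ACF_START_JITTER, function(j)
      c(log(sg$N0 * j["N"]), 0.4, 0.3, log(5e-3 * j["tau"]), log(20), 0.05,
        log(4e-6), 0))
    npar <- 8
    ratioIdx <- 5
  } else {
    # p = (logN, f2, logTau2, logRatio, T, logTauTr, off); f3 = 1 - f2
    lower <- c(log(1e-4), 0, log(1e-4), log(1), 0, log(1e-7), -0.3)
    upper <- c(log(1e7), 1, log(5), log(1e5), 0.8, log(TAU_TR_MAX), 0.3)
    residFun <- function(p, fd) {
      (.acfEval(fd$lag, exp(p[1]), c(exp(p[3]), exp(p[3] + p[4])),
                c(p[2], 1 - p[2]), c(FALSE, FALSE), p[5], exp(p[6]),
                S) + p[7] * G0g - fd$G) * fd$w
    }
    starts <- lapply(ACF_START_JITTER, function(j)
      c(log(sg$N0 * j["N"]), 0.5, log(sg$tau0 * 0.5 * j["tau"]), log(10),
        0.05, log(4e-6), 0))
    npar <- 7
    ratioIdx <- 4
  }
  best <- acfFitEngine(fd, residFun, starts, lower, upper)
  p <- best$par
  degenerate <- exp(p[[ratioIdx]]) < 2

  if (!degenerate) {
    if (hasLigand) {
      f1 <- p[2]; f2 <- (1 - p[2]) * p[3]; f3 <- (1 - p[2]) * (1 - p[3])
      return(finishFit(exp(p[1]),
                       c(tauD1Fixed, exp(p[4]), exp(p[4] + p[5])),
                       c(f1, f2, f3), c(TRUE, FALSE, FALSE),
                       c(TRUE, FALSE, FALSE), p[6], exp(p[7]), p[8] * G0g,
                       reducedChisq(best, npar), FALSE))
    }
    return(finishFit(exp(p[1]), c(exp(p[3]), exp(p[3] + p[4])),
                     c(p[2], 1 - p[2]), c(FALSE, FALSE), c(FALSE, FALSE),
                     p[5], exp(p[6]), p[7] * G0g,
                     reducedChisq(best, npar), FALSE))
  }

  # --- collapsed dwell times: refit with a single free 2D component
  if (hasLigand) {
    # p = (logN, f1, logTau, T, logTauTr, off); single 2D carries 1 - f1
    lower1 <- c(log(1e-4), 0, log(1e-4), 0, log(1e-7), -0.3)
    upper1 <- c(log(1e7), 1, log(5), 0.8, log(TAU_TR_MAX), 0.3)
    residFun1 <- function(p, fd) {
      (.acfEval(fd$lag, exp(p[1]), c(tauD1Fixed, exp(p[3])),
                c(p[2], 1 - p[2]), c(TRUE, FALSE), p[4], exp(p[5]),
                S) + p[6] * G0g - fd$G) * fd$w
    }
    starts1 <- lapply(ACF_START_JITTER, function(j)
      c(log(sg$N0 * j["N"]), 0.4, log(5e-2 * j["tau"]), 0.05, log(4e-6), 0))
    best1 <- acfFitEngine(fd, residFun1, starts1, lower1, upper1)
    p1 <- best1$par
    finishFit(exp(p1[1]), c(tauD1Fixed, exp(p1[3])), c(p1[2], 1 - p1[2]),
              c(TRUE, FALSE), c(TRUE, FALSE), p1[4], exp(p1[5]),
              p1[6] * G0g, reducedChisq(best1, 6), TRUE)
  } else {
    # p = (logN, logTau, T, logTauTr, off)
    lower1 <- c(log(1e-4), log(1e-4), 0, log(1e-7), -0.3)
    upper1 <- c(log(1e7), log(5), 0.8, log(TAU_TR_MAX), 0.3)
    residFun1 <- function(p, fd) {
      (.acfEval(fd$lag, exp(p[1]), exp(p[2]), 1, FALSE, p[3], exp(p[4]),
                S) + p[5] * G0g - fd$G) * fd$w
    }
    starts1 <- lapply(ACF_START_JITTER, function(j)
      c(log(sg$N0 * j["N"]), log(sg$tau0 * j["tau"]), 0.05, log(4e-6), 0))
    best1 <- acfFitEngine(fd, residFun1, starts1, lower1, upper1)
    p1 <- best1$par
    finishFit(exp(p1[1]), exp(p1[2]), 1, FALSE, FALSE, p1[3], exp(p1[4]),
              p1[5] * G0g, reducedChisq(best1, 5), TRUE)
  }
}

#' Fit the membrane (receptor-GFP / BiFC) autocorrelation model
#'
#' Two 2D diffusion components plus a pre-exponential term for fluorophore
#' photophysics, with the structure parameter fixed to the calibration value
#' and a free baseline absorbing the finite-measurement normalization bias.
#' The two dwell times are parameterized as \eqn{\tau_{D2}} and a ratio
#' \eqn{\tau_{D3}/\tau_{D2} \ge 1}, so returned components are always ordered
#' by increasing dwell time.  When the two dwell times collapse within a
#' factor of 2 the fit is flagged degenerate and refitted with a single 2D
#' component.
#'
#' @param curve a \code{\linkS4class{CorrelationCurve}}
#' @param volume a \code{\linkS4class{DetectionVolume}} or
#'   \code{\linkS4class{CalibrationResult}} (provides the fixed S)
#' @param window lag fit window (s)
#' @return an \code{\linkS4class{ACFFit}}
#' @export
fitMembraneACF <- function(curve, volume, window = ACF_FIT_WINDOW) {
  fitCellACF(curve, structureParameter(volume), "membrane", window = window)
}

#' Fit the fluorescent-ligand autocorrelation model
#'
#' One 3D component with fixed dwell time (the freely diffusing fluorescent
#' ligand, calibrated in buffer) plus two free 2D components (receptor-bound
#' ligand), plus a pre-exponential triplet term and a free baseline.  Binding
#' is represented by the slowest 2D component.
#'
#' @param curve a \code{\linkS4class{CorrelationCurve}}
#' @param volume provides the fixed structure parameter
#' @param tauD1Fixed fixed free-ligand dwell time (s), from a buffer
#'   calibration fit
#' @param window lag fit window (s)
#' @return an \code{\linkS4class{ACFFit}}
#' @export
fitLigandACF <- function(curve, volume, tauD1Fixed, window = ACF_FIT_WINDOW) {
  fitCellACF(curve, structureParameter(volume), "ligand",
             tauD1Fixed = tauD1Fixed, window = window)
}
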