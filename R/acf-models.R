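# Autocorrelation model functions.

# Single-component decay terms of the diffusion ACF.
g2D <- function(tau, tauD) 1 / (1 + tau / tauD)
g3D <- function(tau, tauD, S) 1 / ((1 + tau / tauD) * sqrt(1 + tau / (S^2 * tauD)))

# Fast evaluator used inside fit residuals (no data.frame overhead).
# is3d: logical per component; fractions assumed to sum to 1.
.acfEval <- function(lags, Ntotal, tauD, frac, is3d, Tdark, tauTr, S) {
  dec <- 0
  for (i in seq_along(tauD)) {
    gi <- if (is3d[i]) g3D(lags, tauD[i], S) else g2D(lags, tauD[i])
    dec <- dec + frac[i] * gi
  }
  (1 + Tdark / (1 - Tdark) * exp(-lags / tauTr)) * dec / Ntotal
}

#' Evaluate a multi-component autocorrelation model
#'
#' The fluctuation autocorrelation of a mixture of diffusing species with a
#' pre-exponential dark-state (triplet / photophysics) term:
#' \deqn{G(\tau) = \frac{1}{N}\left(1 + \frac{T}{1-T} e^{-\tau/\tau_{tr}}\right)
#'   \sum_i f_i\, g_i(\tau)}
#' with \eqn{g_{2D} = (1+\tau/\tau_{D,i})^{-1}} for membrane components and
#' \eqn{g_{3D} = (1+\tau/\tau_{D,i})^{-1} (1+\tau/(S^2 \tau_{D,i}))^{-1/2}}
#' for solution components.  The fractions \eqn{f_i} are amplitude fractions
#' and must sum to 1, so \eqn{G(0) = (1/N)(1 + T/(1-T))}.
#'
#' This single evaluator covers the three fit models: calibration (one 3D
#' component), ligand (one fixed 3D + two 2D components) and membrane (two 2D
#' components).
#'
#' @param lags lag times (s)
#' @param Ntotal mean particle number
#' @param components data.frame with columns \code{kind} ("2D"/"3D"),
#'   \code{tauD} (s) and \code{fraction}
#' @param Tdark dark-state fraction in [0, 1)
#' @param tauTr dark-state relaxation time (s)
#' @param S structure parameter (used by 3D components)
#' @return G values at \code{lags}
#' @examples
#' cmp <- data.frame(kind = "2D", tauD = 1e-3, fraction = 1)
#' acfModel(1e-3, Ntotal = 1, components = cmp)  # 0.5: half-decay at tauD
#' @export
acfModel <- function(lags, Ntotal, components, Tdark = 0, tauTr = 1e-5,
                     S = 5) {
  if (abs(sum(components$fraction) - 1) > 1e-8)
    stop("component fractions must sum to 1")
  dec <- rep(0, length(lags))
  for (i in seq_len(nrow(components))) {
    gi <- if (components$kind[i] == "3D")
      g3D(lags, components$tauD[i], S) else g2D(lags, components$tauD[i])
    dec <- dec + components$fraction[i] * gi
  }
  trip <- 1 + Tdark / (1 - Tdark) * exp(-lags / tauTr)
  trip * dec / Ntotal
}

#' Convert a dwell time to a diffusion coefficient
#'
#' \eqn{D = \omega^2 / (4 \tau_D)}: the average transit time through the
#' calibrated beam waist fixes the diffusion coefficient.
#'
#' @param tauD dwell time (s, > 0); vectorized
#' @param volume a \code{\linkS4class{DetectionVolume}} or
#'   \code{\linkS4class{CalibrationResult}}
#' @return diffusion coefficient(s), um^2/s
#' @examples
#' deriveDiffusion(50e-6, detectionVolume(0.2))  # 200 um^2/s
#' @export
deriveDiffusion <- function(tauD, volume) {
  if (any(tauD <= 0)) stop("tauD must be > 0")
  beamWaist(volume)^2 / (4 * tauD)
}

#' Convert a fitted particle number to a surface density
#'
#' The fractional amplitude of the selected diffusing component(s) times the
#' total particle number, divided by the beam area: N/um^2.  For ligand fits
#' the bound ligand is represented by the slowest 2D component alone; for
#' membrane (receptor-GFP or BiFC) fits the 2D amplitude fractions are
#' summed.
#'
#' @param fit an \code{\linkS4class{ACFFit}}
#' @param volume a \code{\linkS4class{DetectionVolume}} or
#'   \code{\linkS4class{CalibrationResult}} providing the beam area
#' @param component "auto" (slowest 2D for ligand fits, 2D sum for membrane
#'   fits), "sum2D", "slowest" or "dominant" (largest-fraction 2D component)
#' @return particles per um^2
#' @export
deriveDensity <- function(fit, volume,
                          component = c("auto", "sum2D", "slowest",
                                        "dominant")) {
  component <- match.arg(component)
  if (!converged(fit)) stop("cannot derive a density from an unconverged fit")
  if (component == "auto")
    component <- if (fit@model == "ligand") "slowest" else "sum2D"
  cmp <- components(fit)
  is2d <- cmp$kind == "2D"
  if (!any(is2d)) return(0)
  f <- switch(component,
    sum2D = sum(cmp$fraction[is2d]),
    slowest = cmp$fraction[max(which(is2d))],
    dominant = max(cmp$fraction[is2d]))
  f * nTotal(fit) / beamArea(volume)
}

#' The dominant (largest-fraction) 2D component of a fit
#'
#' The membrane receptor population reported in condition summaries: the 2D
#' diffusing component carrying the largest amplitude fraction.
#'
#' @param fit an \code{\linkS4class{ACFFit}}
#' @return one-row data.frame (kind, tauD, fraction, fixed)
#' @export
dominantComponent <- function(fit) {
  cmp <- components(fit)
  cmp <- cmp[cmp$kind == "2D", , drop = FALSE]
  if (nrow(cmp) == 0) stop("fit has no 2D component")
  cmp[which.max(cmp$fraction), , drop = FALSE]
}
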