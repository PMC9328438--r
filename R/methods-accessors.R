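# Accessor and show methods.

#' @describeIn PhotonTrace photon counts per bin
#' @param object an object of the documented class
#' @export
setMethod("counts", "PhotonTrace", function(object) object@counts)

#' @describeIn PhotonTrace bin width (s)
#' @export
setMethod("binTime", "PhotonTrace", function(object) object@binTime)

#' @describeIn PhotonTrace total duration (s)
#' @export
setMethod("traceDuration", "PhotonTrace", function(object) object@duration)

#' @describeIn PhotonTrace provenance metadata list
#' @export
setMethod("traceMetadata", "PhotonTrace", function(object) object@metadata)

#' @describeIn PhotonTrace mean detected count rate (counts/s)
#' @export
setMethod("meanRate", "PhotonTrace",
          function(object) sum(object@counts) / object@duration)

setMethod("show", "PhotonTrace", function(object) {
  cat(sprintf("PhotonTrace: %d bins of %.3g s (%.3g s total), mean rate %.4g counts/s\n",
              length(object@counts), object@binTime, object@duration,
              meanRate(object)))
})

#' @describeIn CorrelationCurve lag times (s)
#' @param object an object of the documented class
#' @export
setMethod("lagTimes", "CorrelationCurve", function(object) object@lags)

#' @describeIn CorrelationCurve G values
#' @export
setMethod("corrValues", "CorrelationCurve", function(object) object@G)

#' @describeIn CorrelationCurve averaging count per lag
#' @export
setMethod("nPoints", "CorrelationCurve", function(object) object@npts)

#' @describeIn CorrelationCurve mean count rate of the source trace
#' @export
setMethod("meanRate", "CorrelationCurve", function(object) object@meanRate)

#' @describeIn CorrelationCurve native bin width of the source trace (s)
#' @export
setMethod("binTime", "CorrelationCurve", function(object) object@binTime)

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve: %d lags from %.3g to %.3g s, G(first lag) = %.4g\n",
              length(object@lags), min(object@lags), max(object@lags),
              object@G[1]))
})

#' @describeIn DetectionVolume beam-waist radius (um)
#' @param object an object of the documented class
#' @export
setMethod("beamWaist", "DetectionVolume", function(object) object@omega)

#' @describeIn DetectionVolume structure parameter
#' @export
setMethod("structureParameter", "DetectionVolume", function(object) object@S)

#' @describeIn DetectionVolume beam area pi * omega^2 (um^2)
#' @export
setMethod("beamArea", "DetectionVolume", function(object) pi * object@omega^2)

setMethod("show", "DetectionVolume", function(object) {
  cat(sprintf("DetectionVolume: omega = %.4g um, S = %.3g, beam area = %.4g um^2\n",
              object@omega, object@S, beamArea(object)))
})

#' @describeIn ACFFit fitted total particle number
#' @param object an object of the documented class
#' @export
setMethod("nTotal", "ACFFit", function(object) object@Ntotal)

#' @describeIn ACFFit component table (kind, tauD, fraction, fixed)
#' @export
setMethod("components", "ACFFit", function(object) object@components)

#' @describeIn ACFFit reduced chi-square
#' @export
setMethod("chiSquared", "ACFFit", function(object) object@chisq)

#' @describeIn ACFFit convergence flag
#' @export
setMethod("converged", "ACFFit", function(object) object@converged)

setMethod("show", "ACFFit", function(object) {
  cat(sprintf("ACFFit (%s model): N = %.4g, T = %.3g, tauTr = %.3g s, chisq = %.4g%s\n",
              object@model, object@Ntotal, object@Tdark, object@tauTr,
              object@chisq,
              if (object@degenerate) " [degenerate, refit single 2D]" else ""))
  print(object@components, row.names = FALSE)
})

#' @describeIn CalibrationResult calibration dwell time (s)
#' @param object an object of the documented class
#' @export
setMethod("dwellTime", "CalibrationResult", function(object) object@tauD)

#' @describeIn CalibrationResult calibrated beam waist (um)
#' @export
setMethod("beamWaist", "CalibrationResult", function(object) object@omega)

#' @describeIn CalibrationResult calibrated beam area (um^2)
#' @export
setMethod("beamArea", "CalibrationResult", function(object) object@beamArea)

#' @describeIn CalibrationResult fitted structure parameter
#' @export
setMethod("structureParameter", "CalibrationResult", function(object) object@S)

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: tauD = %.4g us, omega = %.4g um, A = %.4g um^2, S = %.3g (Dref = %.4g um^2/s)\n",
    1e6 * object@tauD, object@omega, object@beamArea, object@S, object@Dref))
})

#' @describeIn PCHFit brightness/particle-number component table
#' @param object an object of the documented class
#' @export
setMethod("components", "PCHFit", function(object) object@components)

#' @describeIn PCHFit molecular brightness values (counts molecule^-1 s^-1)
#' @export
setMethod("brightnessValues", "PCHFit",
          function(object) object@components$epsilon)

#' @describeIn PCHFit first-order out-of-focus correction
#' @export
setMethod("correctionF", "PCHFit", function(object) object@F)

#' @describeIn PCHFit reduced chi-square
#' @export
setMethod("chiSquared", "PCHFit", function(object) object@chisq)

#' @describeIn PCHFit convergence flag
#' @export
setMethod("converged", "PCHFit", function(object) object@converged)

#' @describeIn PCHFit counting bin width (s)
#' @export
setMethod("binTime", "PCHFit", function(object) object@binTime)

setMethod("show", "PCHFit", function(object) {
  cat(sprintf("PCHFit (%d component%s, %s MDF): F = %.3g, chisq = %.4g%s\n",
              nrow(object@components),
              if (nrow(object@components) > 1) "s" else "",
              object@geometry, object@F, object@chisq,
              if (object@collapsed) " [collapsed]" else ""))
  print(object@components, row.names = FALSE)
})

#' @describeIn PCHistogram counting bin width (s)
#' @param object an object of the documented class
#' @export
setMethod("binTime", "PCHistogram", function(object) object@binTime)

setMethod("show", "PCHistogram", function(object) {
  cat(sprintf("PCHistogram: %g bins of %.3g s, counts 0..%d, mean %.4g counts/bin\n",
              object@nBins, object@binTime, max(object@k),
              sum(object@k * object@frequency) / object@nBins))
})

#' @describeIn EmaxFit maximal response
#' @param object an object of the documented class
#' @export
setMethod("emax", "EmaxFit", function(object) object@emax)

#' @describeIn EmaxFit half-maximal concentration (molar)
#' @export
setMethod("ec50", "EmaxFit", function(object) object@ec50)

#' @describeIn EmaxFit -log10 EC50
#' @export
setMethod("pec50", "EmaxFit", function(object) object@pec50)

#' @describeIn EmaxFit TRUE for the "no response" outcome
#' @export
setMethod("noResponse", "EmaxFit", function(object) object@noResponse)

setMethod("show", "EmaxFit", function(object) {
  if (object@noResponse) {
    cat("EmaxFit: no response (Emax indistinguishable from 0)\n")
  } else {
    cat(sprintf("EmaxFit: Emax = %.4g, pEC50 = %.4g (se %.3g), basal = %.4g\n",
                object@emax, object@pec50, object@sePec50, object@basal))
  }
})
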