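# S4 classes for the simulation and analysis containers.

#' DetectionVolume: the confocal observation volume
#'
#' Describes the 3D-Gaussian molecular detection function (MDF) of a confocal
#' spectrometer by its lateral beam-waist radius \eqn{\omega} (the 1/e^2
#' radius at focus, in micrometres) and the dimensionless structure parameter
#' \eqn{S} (the axial-to-lateral ratio, so the axial 1/e^2 radius is
#' \eqn{S\omega}).  The beam area at the waist, \eqn{A = \pi\omega^2}, is
#' derived and available through \code{\link{beamArea}}.
#'
#' @slot omega lateral beam-waist radius at focus (micrometres)
#' @slot S structure parameter (axial/lateral ratio, >= 1)
#'
#' @seealso \code{\link{detectionVolume}}, \code{\link{fitCalibration}}
#' @export
setClass("DetectionVolume",
  representation(omega = "numeric", S = "numeric"))

setValidity("DetectionVolume", function(object) {
  msg <- character()
  if (length(object@omega) != 1L || !is.finite(object@omega) || object@omega <= 0)
    msg <- c(msg, "omega must be a single positive number")
  if (length(object@S) != 1L || !is.finite(object@S) || object@S < 1)
    msg <- c(msg, "S must be a single number >= 1")
  if (length(msg)) msg else TRUE
})

#' SpeciesSpec: one diffusing fluorescent species
#'
#' Ground-truth description of a single species for the forward simulator:
#' either a membrane species diffusing in the focal plane ("2D") or a solution
#' species diffusing in three dimensions ("3D").
#'
#' @slot dimensionality "2D" (membrane, confined to z = 0) or "3D" (solution)
#' @slot D diffusion coefficient (um^2/s)
#' @slot density mean particle density: particles/um^2 (2D) or particles/um^3
#'   (3D)
#' @slot epsilon molecular brightness at the centre of the detection volume
#'   (counts molecule^-1 s^-1)
#' @slot Tdark stationary dark-state (triplet/blink) occupancy, in [0, 1)
#' @slot tauDark dark-state relaxation time (s)
#'
#' @seealso \code{\link{speciesSpec}}
#' @export
setClass("SpeciesSpec",
  representation(dimensionality = "character", D = "numeric",
                 density = "numeric", epsilon = "numeric",
                 Tdark = "numeric", tauDark = "numeric"))

setValidity("SpeciesSpec", function(object) {
  msg <- character()
  if (!object@dimensionality %in% c("2D", "3D"))
    msg <- c(msg, "dimensionality must be \"2D\" or \"3D\"")
  if (object@D < 0) msg <- c(msg, "D must be >= 0")
  if (object@density < 0) msg <- c(msg, "density must be >= 0")
  if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
  if (object@Tdark < 0 || object@Tdark >= 1)
    msg <- c(msg, "Tdark must be in [0, 1)")
  if (object@tauDark <= 0) msg <- c(msg, "tauDark must be > 0")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: a complete forward-simulation request
#'
#' Bundles the detection volume, the species list and the acquisition settings
#' for one simulated read.  The simulation box is periodic with lateral
#' half-width \code{boxScale * omega}; a fixed seed gives a bit-identical
#' trace.
#'
#' @slot volume a \code{\linkS4class{DetectionVolume}}
#' @slot species list of \code{\linkS4class{SpeciesSpec}} objects
#' @slot duration total acquisition time (s)
#' @slot binTime width of one photon-counting bin (s)
#' @slot background uncorrelated background count rate (counts/s)
#' @slot boxScale simulation-box half-width in units of omega (>= 5)
#' @slot dt Brownian propagation time step (s, <= binTime)
#' @slot seed integer RNG seed
#'
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateTrace}}
#' @export
setClass("SimulationConfig",
  representation(volume = "DetectionVolume", species = "list",
                 duration = "numeric", binTime = "numeric",
                 background = "numeric", boxScale = "numeric",
                 dt = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!all(vapply(object@species, function(s) is(s, "SpeciesSpec"), logical(1))))
    msg <- c(msg, "species must be a list of SpeciesSpec objects")
  if (object@binTime <= 0) msg <- c(msg, "binTime must be > 0")
  if (object@duration < object@binTime)
    msg <- c(msg, "duration must be >= binTime")
  if (object@dt <= 0 || object@dt > object@binTime)
    msg <- c(msg, "dt must satisfy 0 < dt <= binTime")
  if (object@boxScale < 5) msg <- c(msg, "boxScale must be >= 5")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhotonTrace: a binned photon-count time series
#'
#' The raw observable of every analysis stage: non-negative integer photon
#' counts in contiguous time bins.
#'
#' @slot counts non-negative integer counts per bin
#' @slot binTime bin width (s)
#' @slot duration total duration (s); \code{length(counts) ==
#'   round(duration/binTime)}
#' @slot metadata free-form provenance list (simulation parameters, rates, ...)
#'
#' @seealso \code{\link{simulateTrace}}, \code{\link{autocorrelate}},
#'   \code{\link{computePCH}}
#' @export
setClass("PhotonTrace",
  representation(counts = "numeric", binTime = "numeric",
                 duration = "numeric", metadata = "list"))

setValidity("PhotonTrace", function(object) {
  msg <- character()
  if (length(object@counts) != round(object@duration / object@binTime))
    msg <- c(msg, "length(counts) must equal round(duration/binTime)")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' CorrelationCurve: a normalized autocorrelation function
#'
#' G(tau) on a (quasi-logarithmic or linear) lag grid, normalized so that
#' G(infinity) = 0 and, for an ideal single species, G(0+) = 1/N.
#'
#' @slot lags lag times (s), strictly increasing
#' @slot G autocorrelation amplitude per lag (dimensionless)
#' @slot npts number of averaged products per lag (fit weighting uses
#'   1/sqrt(npts))
#' @slot meanRate mean detected count rate of the underlying trace (counts/s)
#' @slot binTime native bin width of the underlying trace (s)
#'
#' @seealso \code{\link{autocorrelate}}, \code{\link{fitMembraneACF}}
#' @export
setClass("CorrelationCurve",
  representation(lags = "numeric", G = "numeric", npts = "numeric",
                 meanRate = "numeric", binTime = "numeric"))

setValidity("CorrelationCurve", function(object) {
  msg <- character()
  n <- length(object@lags)
  if (length(object@G) != n || length(object@npts) != n)
    msg <- c(msg, "lags, G and npts must have equal length")
  if (n > 1 && any(diff(object@lags) <= 0))
    msg <- c(msg, "lags must be strictly increasing")
  if (n > 0 && object@lags[1] < object@binTime * (1 - 1e-9))
    msg <- c(msg, "smallest lag must be >= binTime")
  if (any(!is.finite(object@G))) msg <- c(msg, "G must be finite")
  if (any(object@npts <= 0)) msg <- c(msg, "npts must be > 0")
  if (length(msg)) msg else TRUE
})

#' PCHistogram: a photon counting histogram
#'
#' Frequencies of observed photon counts per bin, for contiguous count values
#' k = 0, 1, ..., k_max.
#'
#' @slot k photon-count values (0..k_max, contiguous)
#' @slot frequency observed number of bins with each count
#' @slot binTime counting bin width used (s)
#' @slot nBins total number of bins histogrammed (= sum(frequency))
#'
#' @seealso \code{\link{computePCH}}, \code{\link{fitPCH}}
#' @export
setClass("PCHistogram",
  representation(k = "integer", frequency = "numeric",
                 binTime = "numeric", nBins = "numeric"))

setValidity("PCHistogram", function(object) {
  msg <- character()
  if (!identical(object@k, seq.int(0L, length.out = length(object@k))))
    msg <- c(msg, "k must be contiguous from 0")
  if (length(object@frequency) != length(object@k))
    msg <- c(msg, "k and frequency must have equal length")
  if (!isTRUE(all.equal(sum(object@frequency), object@nBins)))
    msg <- c(msg, "sum(frequency) must equal nBins")
  if (length(msg)) msg else TRUE
})

#' ACFFit: result of an autocorrelation model fit
#'
#' Holds the fitted total particle number, the diffusing components (sorted by
#' increasing dwell time), the pre-exponential dark-state (triplet /
#' photophysics) term and goodness of fit.
#'
#' @slot model "calibration", "ligand" or "membrane"
#' @slot Ntotal fitted mean particle number in the detection volume/area
#' @slot components data.frame with columns \code{kind} ("2D"/"3D"),
#'   \code{tauD} (s), \code{fraction} (amplitude fraction, sums to 1) and
#'   \code{fixed} (logical), ordered by increasing \code{tauD}
#' @slot Tdark fitted dark-state fraction
#' @slot tauTr fitted dark-state relaxation time (s)
#' @slot S structure parameter used (fixed during cell fits)
#' @slot offset fitted additive baseline (the cell models fit a small free
#'   baseline to absorb the finite-measurement normalization bias of slowly
#'   decaying membrane ACFs; 0 for calibration fits)
#' @slot chisq reduced weighted chi-square of the fit
#' @slot converged logical
#' @slot degenerate logical: TRUE when a two-component fit collapsed (dwell
#'   times within a factor 2) and the curve was refitted with one component
#'
#' @seealso \code{\link{fitMembraneACF}}, \code{\link{fitLigandACF}},
#'   \code{\link{deriveDiffusion}}, \code{\link{deriveDensity}}
#' @export
setClass("ACFFit",
  representation(model = "character", Ntotal = "numeric",
                 components = "data.frame", Tdark = "numeric",
                 tauTr = "numeric", S = "numeric", offset = "numeric",
                 chisq = "numeric", converged = "logical",
                 degenerate = "logical"))

setValidity("ACFFit", function(object) {
  msg <- character()
  cmp <- object@components
  need <- c("kind", "tauD", "fraction", "fixed")
  if (!all(need %in% names(cmp)))
    msg <- c(msg, "components must have columns kind, tauD, fraction, fixed")
  else {
    if (nrow(cmp) > 1 && any(diff(cmp$tauD) < 0))
      msg <- c(msg, "components must be sorted by increasing tauD")
    if (abs(sum(cmp$fraction) - 1) > 1e-6)
      msg <- c(msg, "component fractions must sum to 1")
  }
  if (object@Ntotal <= 0) msg <- c(msg, "Ntotal must be > 0")
  if (length(msg)) msg else TRUE
})

#' CalibrationResult: detection-volume calibration from a dye standard
#'
#' The dwell time of a reference dye of known diffusion coefficient fixes the
#' beam waist through \eqn{\omega = \sqrt{4 \tau_D D_{ref}}} and the beam area
#' through \eqn{A = \pi \omega^2}.
#'
#' @slot tauD calibration dwell time (s)
#' @slot omega beam-waist radius (um)
#' @slot beamArea beam area at the waist (um^2)
#' @slot S fitted structure parameter
#' @slot Dref reference diffusion coefficient (um^2/s)
#' @slot fit the underlying \code{\linkS4class{ACFFit}}
#'
#' @seealso \code{\link{fitCalibration}}
#' @export
setClass("CalibrationResult",
  representation(tauD = "numeric", omega = "numeric", beamArea = "numeric",
                 S = "numeric", Dref = "numeric", fit = "ACFFit"))

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (abs(object@omega - sqrt(4 * object@tauD * object@Dref)) >
      1e-9 * object@omega)
    msg <- c(msg, "omega must equal sqrt(4 * tauD * Dref)")
  if (abs(object@beamArea - pi * object@omega^2) > 1e-9 * object@beamArea)
    msg <- c(msg, "beamArea must equal pi * omega^2")
  if (length(msg)) msg else TRUE
})

#' PCHFit: result of a photon counting histogram fit
#'
#' One or two molecular-brightness components plus the first-order
#' out-of-focus correction F.
#'
#' @slot components data.frame with columns \code{epsilon} (counts
#'   molecule^-1 s^-1) and \code{Nbar} (mean particles in the reference
#'   volume), sorted by increasing epsilon
#' @slot F first-order out-of-focus correction (dimensionless, >= 0)
#' @slot chisq reduced chi-square
#' @slot converged logical
#' @slot collapsed logical: TRUE when a requested two-component fit collapsed
#'   (brightness ratio < 2)
#' @slot binTime counting bin width (s)
#' @slot geometry "3d" or "2d" molecular detection function
#'
#' @seealso \code{\link{fitPCH}}, \code{\link{pchModel}}
#' @export
setClass("PCHFit",
  representation(components = "data.frame", F = "numeric", chisq = "numeric",
                 converged = "logical", collapsed = "logical",
                 binTime = "numeric", geometry = "character"))

setValidity("PCHFit", function(object) {
  msg <- character()
  cmp <- object@components
  if (!all(c("epsilon", "Nbar") %in% names(cmp)))
    msg <- c(msg, "components must have columns epsilon, Nbar")
  else {
    if (nrow(cmp) > 1 && any(diff(cmp$epsilon) < 0))
      msg <- c(msg, "components must be sorted by increasing epsilon")
    if (any(cmp$epsilon < 0)) msg <- c(msg, "epsilon must be >= 0")
    if (any(cmp$Nbar <= 0)) msg <- c(msg, "Nbar must be > 0")
  }
  if (object@F < 0) msg <- c(msg, "F must be >= 0")
  if (length(msg)) msg else TRUE
})

#' EmaxFit: result of an Emax concentration-response fit
#'
#' Parameters of Response = basal + Emax * A / (A + EC50) fitted by nonlinear
#' least squares (Hill slope fixed at 1).
#'
#' @slot emax maximal response (response units)
#' @slot ec50 half-maximal agonist concentration (molar)
#' @slot pec50 -log10(ec50)
#' @slot basal basal response (0 when not fitted)
#' @slot sePec50 standard error of pec50 (NA when unavailable)
#' @slot noResponse logical: TRUE when Emax is indistinguishable from 0
#'   (the "NR" outcome); the other slots are then NA
#' @slot rss residual sum of squares
#' @slot n number of data points
#'
#' @seealso \code{\link{fitEmax}}, \code{\link{generateDoseResponse}}
#' @export
setClass("EmaxFit",
  representation(emax = "numeric", ec50 = "numeric", pec50 = "numeric",
                 basal = "numeric", sePec50 = "numeric",
                 noResponse = "logical", rss = "numeric", n = "numeric"))

setValidity("EmaxFit", function(object) {
  if (!object@noResponse &&
      abs(object@pec50 + log10(object@ec50)) > 1e-9)
    "pec50 must equal -log10(ec50)" else TRUE
})
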