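# User-facing constructors.

#' Create a confocal detection volume
#'
#' @param omega lateral beam-waist radius at focus (micrometres)
#' @param S structure parameter (axial/lateral ratio); 5 is typical for a
#'   water-immersion confocal setup
#' @return a \code{\linkS4class{DetectionVolume}}
#' @examples
#' vol <- detectionVolume(0.2, S = 5)
#' beamArea(vol)  # pi * 0.2^2 = 0.1257 um^2
#' @export
detectionVolume <- function(omega, S = 5) {
  new("DetectionVolume", omega = as.numeric(omega), S = as.numeric(S))
}

#' Create a species specification for the forward simulator
#'
#' @param dimensionality "2D" (membrane species, confined to the focal plane)
#'   or "3D" (solution species)
#' @param D diffusion coefficient (um^2/s)
#' @param density particles/um^2 (2D) or particles/um^3 (3D)
#' @param epsilon molecular brightness at focus (counts molecule^-1 s^-1)
#' @param Tdark stationary dark-state occupancy in [0, 1); 0 disables the
#'   dark-state process
#' @param tauDark dark-state relaxation time (s)
#' @return a \code{\linkS4class{SpeciesSpec}}
#' @examples
#' # a membrane receptor species
#' speciesSpec("2D", D = 0.13, density = 36.7, epsilon = 18111)
#' @export
speciesSpec <- function(dimensionality, D, density, epsilon,
                        Tdark = 0, tauDark = 5e-6) {
  new("SpeciesSpec", dimensionality = dimensionality, D = as.numeric(D),
      density = as.numeric(density), epsilon = as.numeric(epsilon),
      Tdark = as.numeric(Tdark), tauDark = as.numeric(tauDark))
}

#' Create a simulation configuration
#'
#' Defaults reflect a standard acquisition: 30 s reads, 2 us raw bins
#' (rebinnable downstream), 1 us propagation step resolving ~5 us dark-state
#' kinetics, zero background and a periodic box of half-width 8 omega.
#'
#' @param volume a \code{\linkS4class{DetectionVolume}}
#' @param species a \code{\linkS4class{SpeciesSpec}} or list of them
#' @param duration acquisition time (s)
#' @param binTime photon-counting bin width (s)
#' @param background uncorrelated background rate (counts/s)
#' @param boxScale box half-width in units of omega (>= 5)
#' @param dt propagation time step (s)
#' @param seed integer RNG seed; the same configuration always yields the
#'   identical trace
#' @return a \code{\linkS4class{SimulationConfig}}
#' @export
simulationConfig <- function(volume, species, duration = 30, binTime = 2e-6,
                             background = 0, boxScale = 8, dt = 1e-6,
                             seed = 1L) {
  if (is(species, "SpeciesSpec")) species <- list(species)
  new("SimulationConfig", volume = volume, species = species,
      duration = as.numeric(duration), binTime = as.numeric(binTime),
      background = as.numeric(background), boxScale = as.numeric(boxScale),
      dt = as.numeric(dt), seed = as.integer(seed))
}

#' Create a photon trace from raw counts
#'
#' Mostly used internally and by the CSV reader; simulated traces come from
#' \code{\link{simulateTrace}}.
#'
#' @param counts non-negative integer counts per bin
#' @param binTime bin width (s)
#' @param metadata optional provenance list
#' @return a \code{\linkS4class{PhotonTrace}}
#' @export
photonTrace <- function(counts, binTime, metadata = list()) {
  new("PhotonTrace", counts = as.numeric(counts),
      binTime = as.numeric(binTime),
      duration = length(counts) * as.numeric(binTime), metadata = metadata)
}

#' Convert a nanomolar concentration to particles per cubic micrometre
#'
#' Convenience for stating solution-species densities: 1 nM corresponds to
#' about 0.602 molecules/um^3.
#'
#' @param nM concentration in nanomolar
#' @return particles per um^3
#' @examples
#' nanomolarToPerCubicMicron(20)  # ~12 molecules/um^3
#' @export
nanomolarToPerCubicMicron <- function(nM) {
  nM * 1e-9 * 6.02214076e23 * 1e-15
}
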