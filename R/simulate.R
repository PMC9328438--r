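# Forward simulation of photon-count traces.

# Run a function with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, fun) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

# Axial half-width of the periodic box, in units of the axial waist S*omega.
# exp(-2 * 2.5^2) ~ 4e-6, so emission from the wrapped axial boundary is
# negligible while the box stays small enough to keep particle counts
# tractable.
AXIAL_BOX_HALF_WIDTH_WAISTS <- 2.5

#' Simulate a binned photon-count trace
#'
#' Brownian-dynamics forward model of a confocal fluctuation measurement.
#' Particles of each species are placed uniformly in a periodic box (lateral
#' half-width \code{boxScale * omega}; 2D species confined to the focal plane
#' z = 0), propagated with Gaussian displacements of standard deviation
#' \code{sqrt(2 D dt)} per axis, and switched between bright and dark states
#' by a two-state telegraph process with stationary dark occupancy
#' \code{Tdark} and relaxation time \code{tauDark}.  Each bin's photon count
#' is a Poisson draw with mean
#' \deqn{background \cdot binTime + \sum_{steps} dt \sum_{bright}
#'   \epsilon \, e^{-2(x^2+y^2)/\omega^2 - 2 z^2/(S\omega)^2}.}
#' The per-species particle number is Poisson-distributed with mean
#' density x box measure, so occupation statistics of the detection region
#' are grand-canonical.  A fixed seed gives a bit-identical trace.
#'
#' The propagation step is snapped to an integer divisor of \code{binTime}
#' (\code{dt_eff = binTime / round(binTime/dt)}).
#'
#' @param config a \code{\linkS4class{SimulationConfig}}
#' @param returnRates when TRUE, store the per-bin expected counts (the
#'   Poisson means) in \code{traceMetadata(trace)$rates}; used for oracle
#'   checks of the photon statistics
#' @return a \code{\linkS4class{PhotonTrace}}
#' @examples
#' vol <- detectionVolume(0.2, 5)
#' sp <- speciesSpec("2D", D = 0.13, density = 36.7, epsilon = 18111)
#' cfg <- simulationConfig(vol, sp, duration = 0.5, binTime = 1e-4,
#'                         dt = 1e-4, seed = 7)
#' tr <- simulateTrace(cfg)
#' meanRate(tr)
#' @export
simulateTrace <- function(config, returnRates = FALSE) {
  validObject(config)
  if (length(config@species) == 0 && config@background == 0)
    stop("degenerate request: no species and zero background ",
         "(an all-zero trace must be asked for explicitly via epsilon = 0)")
  for (s in config@species) {
    if (s@Tdark > 0 && config@dt > s@tauDark / 5)
      stop("dt must be <= tauDark/5 to resolve dark-state kinetics ",
           sprintf("(dt = %g, tauDark = %g)", config@dt, s@tauDark))
  }
  omega <- config@volume@omega
  S <- config@volume@S
  Lxy <- config@boxScale * omega
  Lz <- AXIAL_BOX_HALF_WIDTH_WAISTS * S * omega
  n_bins <- round(config@duration / config@binTime)
  steps_per_bin <- max(1L, as.integer(round(config@binTime / config@dt)))
  dt_eff <- config@binTime / steps_per_bin

  dim_ <- vapply(config@species,
                 function(s) if (s@dimensionality == "3D") 3L else 2L,
                 integer(1))
  D <- vapply(config@species, function(s) s@D, numeric(1))
  eps <- vapply(config@species, function(s) s@epsilon, numeric(1))
  Td <- vapply(config@species, function(s) s@Tdark, numeric(1))
  taud <- vapply(config@species, function(s) s@tauDark, numeric(1))
  measure <- ifelse(dim_ == 3L, (2 * Lxy)^2 * (2 * Lz), (2 * Lxy)^2)
  dens <- vapply(config@species, function(s) s@density, numeric(1))

  res <- withLocalSeed(config@seed, function() {
    np <- as.integer(rpois(length(dens), dens * measure))
    sim_trace_cpp(n_bins, steps_per_bin, dt_eff, dim_, D, np, eps, Td, taud,
                  omega, S, Lxy, Lz, config@background, returnRates)
  })
  meta <- list(config = config, dt_effective = dt_eff)
  if (returnRates) meta$rates <- res$rates
  new("PhotonTrace", counts = res$counts, binTime = config@binTime,
      duration = n_bins * config@binTime, metadata = meta)
}

#' Simulate a calibration trace for a dye diffusion standard
#'
#' Convenience wrapper over \code{\link{simulateTrace}} for an aqueous
#' solution of a reference dye (for example Rhodamine 6G at 280 um^2/s for
#' the 488 nm line, or Cy5 at 316 um^2/s for the 633 nm line): a single 3D
#' species with triplet kinetics.  The reference diffusion coefficient is
#' recorded in the trace metadata.
#'
#' @param Dref reference diffusion coefficient (um^2/s, > 0)
#' @param volume a \code{\linkS4class{DetectionVolume}} (ground truth)
#' @param concentration dye concentration in particles/um^3 (> 0); see
#'   \code{\link{nanomolarToPerCubicMicron}}
#' @param epsilon molecular brightness (counts molecule^-1 s^-1)
#' @param duration acquisition time (s)
#' @param seed integer RNG seed
#' @param Tdark,tauDark triplet occupancy and relaxation time
#' @param binTime,dt,boxScale acquisition/propagation settings; the defaults
#'   resolve the ~30 us dwell time of a fast dye and its ~5 us triplet
#' @return a \code{\linkS4class{PhotonTrace}} with \code{Dref} in its metadata
#' @export
simulateCalibrationTrace <- function(Dref, volume, concentration,
                                     epsilon = 5e4, duration = 1, seed = 1L,
                                     Tdark = 0.15, tauDark = 5e-6,
                                     binTime = 2e-6, dt = 1e-6,
                                     boxScale = 5) {
  if (Dref <= 0) stop("Dref must be > 0")
  if (concentration <= 0) stop("concentration must be > 0")
  sp <- speciesSpec("3D", D = Dref, density = concentration,
                    epsilon = epsilon, Tdark = Tdark, tauDark = tauDark)
  cfg <- simulationConfig(volume, sp, duration = duration, binTime = binTime,
                          background = 0, boxScale = boxScale, dt = dt,
                          seed = seed)
  tr <- simulateTrace(cfg)
  tr@metadata$Dref <- Dref
  tr
}

#' Simulate free-space Brownian displacements
#'
#' Propagates particles with the same Gaussian-step rule as the trace
#' simulator but without periodic wrapping, and returns the squared
#' displacement of each particle after \code{nSteps} steps.  The mean obeys
#' the diffusion law 4 D t (2D) or 6 D t (3D).
#'
#' @param nParticles number of independent particles
#' @param nSteps number of propagation steps
#' @param dt step duration (s)
#' @param D diffusion coefficient (um^2/s)
#' @param dimensionality "2D" or "3D"
#' @param seed integer RNG seed
#' @return numeric vector of squared displacements (um^2)
#' @export
simulateDisplacements <- function(nParticles, nSteps, dt, D,
                                  dimensionality = "2D", seed = 1L) {
  dim_ <- if (dimensionality == "3D") 3L else 2L
  withLocalSeed(seed, function()
    sim_displacement2_cpp(nParticles, nSteps, dt, D, dim_))
}

#' Simulate the dark-state telegraph process in isolation
#'
#' @param duration trajectory length (s)
#' @param dt step duration (s)
#' @param Tdark stationary dark occupancy
#' @param tauDark relaxation time (s)
#' @param seed integer RNG seed
#' @return realized fraction of time spent dark
#' @export
simulateDarkFraction <- function(duration, dt, Tdark, tauDark, seed = 1L) {
  if (dt > tauDark / 5)
    stop("dt must be <= tauDark/5 to resolve dark-state kinetics")
  withLocalSeed(seed, function()
    sim_dark_fraction_cpp(as.integer(round(duration / dt)), dt, Tdark,
                          tauDark))
}
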