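# Shared fixtures, generated once per test run and cached.
#
# Recovery studies run at the published membrane ground truths with a compact
# simulation box (half-width 5 omega) and single 30 s reads at 100 us bins;
# the box keeps particle counts tractable while leaving re-entry artifacts
# negligible on the 1 s fit window.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

studyVolume <- function() detectionVolume(0.2, 5)

# Published membrane ground truths used across tests.
GT_VEHICLE <- list(D = 0.13, density = 36.7, epsilon = 18111)
GT_NECA <- list(D = 0.09, density = 64.1, epsilon = 24027)
GT_BIFC_VEHICLE <- list(D = 0.24, density = 7.9,
                        epsilon = c(4383, 34006))

simulateMembraneTrace <- function(species, seed, duration = 30) {
  cfg <- simulationConfig(studyVolume(), species, duration = duration,
                          binTime = 1e-4, dt = 1e-4, boxScale = 5,
                          seed = seed)
  simulateTrace(cfg)
}

# 20 seeded vehicle-condition traces (shared by the D / density / brightness
# recovery tests).
vehicleTraces <- function() fixture("vehicleTraces", function() {
  sp <- speciesSpec("2D", GT_VEHICLE$D, GT_VEHICLE$density,
                    GT_VEHICLE$epsilon)
  lapply(1:20, function(s) simulateMembraneTrace(sp, seed = 1000 + s))
})

vehicleFits <- function() fixture("vehicleFits", function() {
  lapply(vehicleTraces(), function(tr)
    fitMembraneACF(autocorrelate(tr), studyVolume()))
})

# Rhodamine 6G calibration trace at the 488 nm channel protocol (20 nM,
# triplet kinetics, 2 us raw bins).  Shared by the beam-waist closure and the
# frozen first-order-correction chain.
r6gTrace <- function() fixture("r6gTrace", function()
  simulateCalibrationTrace(280, studyVolume(),
                           nanomolarToPerCubicMicron(20), epsilon = 5e4,
                           duration = 2, seed = 501))

r6gPchCorrection <- function() fixture("r6gPchCorrection", function()
  calibratePCHCorrection(computePCH(r6gTrace(), 2e-5)))

# A noiseless synthetic curve from the model itself, on a multi-tau-like grid.
noiselessCurve <- function(Ntotal, components, Tdark = 0, tauTr = 1e-5,
                           S = 5, lagRange = c(2e-6, 1), n = 160) {
  lag <- exp(seq(log(lagRange[1]), log(lagRange[2]), length.out = n))
  G <- acfModel(lag, Ntotal, components, Tdark = Tdark, tauTr = tauTr, S = S)
  new("CorrelationCurve", lags = lag, G = G, npts = rep(1e6, n),
      meanRate = 1e5, binTime = lagRange[1])
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
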