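# Forward simulator: photon statistics, diffusion law, dark-state kinetics,
# determinism and input validation.

test_that("zero-brightness species with zero background gives an all-zero trace", {
  cfg <- simulationConfig(studyVolume(),
                          speciesSpec("2D", 0.1, 10, epsilon = 0),
                          duration = 0.01, binTime = 1e-4, dt = 1e-4,
                          seed = 1)
  tr <- simulateTrace(cfg)
  expect_true(all(counts(tr) == 0))
  expect_length(counts(tr), 100L)
})

test_that("mean count rate matches the brute-force rate oracle and the analytic MDF integral", {
  vol <- studyVolume()
  # 2D species: rate = eps * density * (pi/2) * omega^2
  sp <- speciesSpec("2D", D = 0.13, density = 36.7, epsilon = 18111)
  cfg <- simulationConfig(vol, sp, duration = 10, binTime = 1e-4,
                          dt = 1e-4, boxScale = 5, seed = 3)
  tr <- simulateTrace(cfg, returnRates = TRUE)
  rates <- traceMetadata(tr)$rates
  # Poisson sampling agrees with the realized per-bin rates (3 sigma)
  expect_lt(abs(sum(counts(tr)) - sum(rates)), 3 * sqrt(sum(rates)))
  # realized trajectory average agrees with the analytic expectation within
  # the particle-number fluctuation of a single box draw (~3/sqrt(n_p))
  analytic2d <- 18111 * 36.7 * (pi / 2) * 0.2^2
  nP <- 36.7 * (2 * 5 * 0.2)^2
  expect_lt(abs(mean(rates) / 1e-4 - analytic2d) / analytic2d,
            3.5 / sqrt(nP))
  # 3D species: rate = eps * density * (pi/2)^{3/2} * omega^3 * S
  sp3 <- speciesSpec("3D", D = 280, density = 12, epsilon = 5e4)
  cfg3 <- simulationConfig(vol, sp3, duration = 0.2, binTime = 2e-6,
                           dt = 2e-6, boxScale = 5, seed = 4)
  tr3 <- simulateTrace(cfg3, returnRates = TRUE)
  analytic3d <- 5e4 * 12 * (pi / 2)^1.5 * 0.2^3 * 5
  nP3 <- 12 * (2 * 5 * 0.2)^2 * (2 * 2.5 * 5 * 0.2)
  expect_lt(abs(mean(traceMetadata(tr3)$rates) / 2e-6 - analytic3d) /
              analytic3d, 3.5 / sqrt(nP3))
})

test_that("identical configuration gives a bit-identical trace and leaves the caller RNG intact", {
  cfg <- simulationConfig(studyVolume(),
                          speciesSpec("2D", 0.13, 36.7, 18111),
                          duration = 0.2, binTime = 1e-4, dt = 1e-4,
                          boxScale = 5, seed = 11)
  set.seed(99)
  tr1 <- simulateTrace(cfg)
  after1 <- runif(1)
  set.seed(99)
  tr2 <- simulateTrace(cfg)
  after2 <- runif(1)
  expect_identical(counts(tr1), counts(tr2))
  expect_identical(after1, after2)  # local seeding restores RNG state
})

test_that("mean squared displacement follows the diffusion law", {
  d2 <- simulateDisplacements(2000, 100, 1e-6, 0.13, "2D", seed = 5)
  expect_rel_equal(mean(d2), 4 * 0.13 * 1e-4, 0.05)
  d3 <- simulateDisplacements(2000, 100, 1e-6, 280, "3D", seed = 6)
  expect_rel_equal(mean(d3), 6 * 280 * 1e-4, 0.05)
})

test_that("dark-state occupancy converges to the stationary fraction", {
  f <- simulateDarkFraction(1, 1e-6, Tdark = 0.2, tauDark = 5e-6, seed = 7)
  expect_rel_equal(f, 0.2, 0.02)
})

test_that("degenerate and unresolved configurations are rejected", {
  vol <- studyVolume()
  cfg <- simulationConfig(vol, list(), duration = 0.01, binTime = 1e-4,
                          dt = 1e-4, seed = 1)
  expect_error(simulateTrace(cfg), "degenerate")
  # dt too coarse for the dark-state kinetics
  sp <- speciesSpec("2D", 0.1, 10, 1e4, Tdark = 0.2, tauDark = 5e-6)
  cfg2 <- simulationConfig(vol, sp, duration = 0.01, binTime = 1e-4,
                           dt = 1e-4, seed = 1)
  expect_error(simulateTrace(cfg2), "tauDark/5")
  expect_error(simulationConfig(vol, sp, duration = 0.01, binTime = 1e-4,
                                dt = 1e-4, boxScale = 3, seed = 1),
               "boxScale")
  expect_error(simulateCalibrationTrace(280, vol, concentration = 0),
               "concentration")
  expect_error(simulateCalibrationTrace(-1, vol, concentration = 1),
               "Dref")
})

test_that("calibration wrapper records the reference diffusion coefficient", {
  tr <- simulateCalibrationTrace(280, studyVolume(), 2, epsilon = 2e4,
                                 duration = 0.01, seed = 2, Tdark = 0)
  expect_equal(traceMetadata(tr)$Dref, 280)
  expect_equal(binTime(tr), 2e-6)
})
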