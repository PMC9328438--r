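# Correlator: hand-computable cases, oracle equivalence, shot-noise and
# physical-limit properties.

test_that("direct correlator reproduces hand-computed values", {
  # two-bin trace [0, 2], global mean 1: G(1) = (0-1)(2-1)/1^2 = -1
  tr <- photonTrace(c(0, 2), binTime = 1e-3)
  expect_equal(corrValues(autocorrelateDirect(tr, 1))[1], -1)
  # periodic [1,0,1,0,...]: perfectly anticorrelated at lag 1, +1 at lag 2
  tr2 <- photonTrace(rep(c(1, 0), 50), binTime = 1e-3)
  G <- corrValues(autocorrelateDirect(tr2, 2))
  expect_equal(G[2], 1)
  expect_equal(G[1], -1, tolerance = 0.05)
  # constant trace: no fluctuations
  tr3 <- photonTrace(rep(5, 200), binTime = 1e-3)
  expect_true(all(abs(corrValues(autocorrelateDirect(tr3, 50))) < 1e-14))
  expect_true(all(abs(corrValues(autocorrelate(tr3))) < 1e-14))
})

test_that("multi-tau equals the brute-force oracle on shared lags", {
  set.seed(42)
  for (rep in 1:5) {
    y <- rpois(1000, rgamma(1000, shape = 2, rate = 0.5))
    tr <- photonTrace(y, binTime = 1e-5)
    for (norm in c("symmetric", "global")) {
      mt <- autocorrelate(tr, m = 16, normalization = norm)
      dr <- autocorrelateDirect(tr, 999, normalization = norm)
      # base-resolution block: identical estimator, 1e-12 agreement
      base <- lagTimes(mt) <= 32 * 1e-5 + 1e-12
      idx <- match(round(lagTimes(mt)[base] / 1e-5),
                   round(lagTimes(dr) / 1e-5))
      expect_lt(max(abs(corrValues(mt)[base] - corrValues(dr)[idx])),
                1e-12)
      # every rebinned octave: identical to the direct estimator applied to
      # the identically rebinned series
      for (lev in 1:3) {
        fac <- 2L^lev
        yr <- fflux:::rebinCounts(y, fac)
        trr <- photonTrace(yr, binTime = 1e-5 * fac)
        drr <- autocorrelateDirect(trr, length(yr) - 1,
                                   normalization = norm)
        oct <- lagTimes(mt) > 16 * fac * 1e-5 &
               lagTimes(mt) <= 32 * fac * 1e-5 + 1e-12
        if (!any(oct)) next
        idx2 <- match(round(lagTimes(mt)[oct] / (1e-5 * fac)),
                      round(lagTimes(drr) / (1e-5 * fac)))
        expect_lt(max(abs(corrValues(mt)[oct] -
                          corrValues(drr)[idx2])), 1e-12)
      }
    }
  }
})

test_that("i.i.d. Poisson counts are delta-correlated (shot noise only)", {
  set.seed(7)
  tr <- photonTrace(rpois(1e6, 3), binTime = 1e-6)
  cu <- autocorrelate(tr)
  expect_true(all(abs(corrValues(cu)) < 5 / sqrt(nPoints(cu))))
})

test_that("fitted amplitude reads 1/N for a single 3D species", {
  # quick dye-like species; amplitude checked at three particle numbers
  vol <- detectionVolume(0.2, 3)
  Veff <- pi^1.5 * 0.2^2 * (3 * 0.2)
  for (N in c(1, 5, 20)) {
    conc <- N / Veff
    tr <- simulateCalibrationTrace(280, vol, conc, epsilon = 8e4,
                                   duration = 0.35, seed = 40 + N,
                                   Tdark = 0, binTime = 4e-6, dt = 4e-6,
                                   boxScale = 5)
    cal <- fitCalibration(autocorrelate(tr), 280)
    expect_rel_equal(nTotal(cal@fit), N, 0.10)
  }
})

test_that("fitted dwell time scales as omega^2/(4D) across beam waists", {
  # D = 1 um^2/s; fit window matched to the ~10-20 ms decay
  for (omega in c(0.2, 0.3)) {
    vol <- detectionVolume(omega, 5)
    sp <- speciesSpec("2D", D = 1, density = 5 / (pi * omega^2),
                      epsilon = 3e4)
    taus <- vapply(1:5, function(s) {
      cfg <- simulationConfig(vol, sp, duration = 20, binTime = 2e-4,
                              dt = 2e-4, boxScale = 5, seed = 60 + s)
      fit <- fitMembraneACF(autocorrelate(simulateTrace(cfg)), vol,
                            window = c(2e-4, 0.25))
      dominantComponent(fit)$tauD
    }, numeric(1))
    expect_rel_equal(median(taus), omega^2 / 4, 0.10)
  }
})

test_that("invalid correlator inputs are rejected", {
  tr <- photonTrace(rep(0, 200), binTime = 1e-4)
  expect_error(autocorrelate(tr), "all-zero")
  expect_error(autocorrelateDirect(tr, 10), "all-zero")
  short <- photonTrace(rep(1, 20), binTime = 1e-4)
  expect_error(autocorrelate(short), "4\\*m")
  expect_error(autocorrelate(photonTrace(1:100, 1e-4), m = 15), "even")
  expect_error(autocorrelateDirect(photonTrace(1:10, 1e-4), 10),
               "maxLagBins")
})

test_that("curve averaging pools reads with npts weighting", {
  set.seed(3)
  tr1 <- photonTrace(rpois(4000, 5), binTime = 1e-5)
  tr2 <- photonTrace(rpois(4000, 5), binTime = 1e-5)
  c1 <- autocorrelate(tr1); c2 <- autocorrelate(tr2)
  av <- averageCurves(list(c1, c2))
  expect_equal(lagTimes(av), lagTimes(c1))
  expect_equal(nPoints(av), nPoints(c1) + nPoints(c2))
  w <- nPoints(c1) / (nPoints(c1) + nPoints(c2))
  expect_equal(corrValues(av),
               w * corrValues(c1) + (1 - w) * corrValues(c2))
})
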