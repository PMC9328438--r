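# ACF model evaluation, noiseless roundtrips, derived quantities.

test_that("model evaluation matches hand-computed values", {
  cmp1 <- data.frame(kind = "2D", tauD = 1e-3, fraction = 1)
  expect_equal(acfModel(1e-3, 1, cmp1), 0.5)                 # half-decay
  # two 2D components f = (0.5, 0.5), tauD = (1, 10) ms at 1 ms:
  cmp2 <- data.frame(kind = c("2D", "2D"), tauD = c(1e-3, 1e-2),
                     fraction = c(0.5, 0.5))
  expect_equal(acfModel(1e-3, 1, cmp2), 0.5 * (0.5 + 1 / 1.1),
               tolerance = 1e-12)
  # 3D at S -> infinity reduces to 2D at all lags
  lags <- 10^seq(-6, 0, 0.25)
  cmp3 <- data.frame(kind = "3D", tauD = 1e-3, fraction = 1)
  expect_lt(max(abs(acfModel(lags, 2, cmp3, S = 1e6) -
                    acfModel(lags, 2, cmp1))), 1e-6)
  # zero-lag amplitude with dark-state term
  expect_equal(acfModel(0, 4, cmp1, Tdark = 0.2, tauTr = 1e-5),
               (1 / 4) * (1 + 0.2 / 0.8))
  bad <- data.frame(kind = "2D", tauD = 1e-3, fraction = 0.7)
  expect_error(acfModel(1e-3, 1, bad), "sum to 1")
})

test_that("dwell-time and density conversions are exact arithmetic", {
  vol <- detectionVolume(0.2, 5)
  expect_equal(deriveDiffusion(50e-6, vol), 200)
  expect_equal(deriveDiffusion(76.9e-3, vol), 0.2^2 / (4 * 76.9e-3))
  # inverse identity
  D <- 0.13
  expect_equal(deriveDiffusion(0.2^2 / (4 * D), vol), D)
  # density: N = 10, f = 0.5, omega = 0.25 -> 5 / (pi 0.25^2) = 25.46
  fit <- new("ACFFit", model = "membrane", Ntotal = 10,
             components = data.frame(kind = c("2D", "2D"),
                                     tauD = c(1e-2, 1e-1),
                                     fraction = c(0.5, 0.5),
                                     fixed = FALSE),
             Tdark = 0, tauTr = 1e-5, S = 5, offset = 0, chisq = 0,
             converged = TRUE, degenerate = FALSE)
  vol25 <- detectionVolume(0.25, 5)
  expect_equal(deriveDensity(fit, vol25, "dominant"), 5 / (pi * 0.25^2),
               tolerance = 1e-9)
  expect_equal(deriveDensity(fit, vol25, "sum2D"), 10 / (pi * 0.25^2))
  # f = 0 on the 2D part -> zero density
  fit0 <- new("ACFFit", model = "ligand", Ntotal = 10,
              components = data.frame(kind = c("3D", "2D"),
                                      tauD = c(3e-5, 1e-1),
                                      fraction = c(1, 0), fixed = FALSE),
              Tdark = 0, tauTr = 1e-5, S = 5, offset = 0, chisq = 0,
              converged = TRUE, degenerate = FALSE)
  expect_equal(deriveDensity(fit0, vol), 0)
})

test_that("calibration fit roundtrips a noiseless curve and derives the beam geometry", {
  cmp <- data.frame(kind = "3D", tauD = 36e-6, fraction = 1)
  cu <- noiselessCurve(5, cmp, Tdark = 0.15, tauTr = 4e-6, S = 5,
                       lagRange = c(1e-6, 0.1))
  cal <- fitCalibration(cu, Dref = 280)
  expect_rel_equal(dwellTime(cal), 36e-6, 1e-6)
  expect_rel_equal(nTotal(cal@fit), 5, 1e-6)
  expect_rel_equal(structureParameter(cal), 5, 1e-4)
  expect_rel_equal(cal@fit@Tdark, 0.15, 1e-5)
  # hand arithmetic at tauD = 35.7 us: omega = 0.19996 um, A = 0.1256 um^2
  cmp2 <- data.frame(kind = "3D", tauD = 35.7e-6, fraction = 1)
  cal2 <- fitCalibration(noiselessCurve(5, cmp2, Tdark = 0.15,
                                        tauTr = 4e-6, S = 5,
                                        lagRange = c(1e-6, 0.1)), 280)
  expect_equal(beamWaist(cal2), 0.19996, tolerance = 1e-4)
  expect_equal(beamArea(cal2), 0.12561, tolerance = 1e-4)
})

test_that("membrane fit roundtrips a noiseless two-component curve exactly", {
  vol <- detectionVolume(0.2, 5)
  cmp <- data.frame(kind = c("2D", "2D"), tauD = c(0.01, 0.12),
                    fraction = c(0.35, 0.65))
  cu <- noiselessCurve(4.6, cmp, Tdark = 0.1, tauTr = 2e-5)
  fit <- fitMembraneACF(cu, vol)
  expect_false(fit@degenerate)
  got <- components(fit)
  expect_rel_equal(nTotal(fit), 4.6, 1e-6)
  expect_rel_equal(got$tauD[1], 0.01, 1e-5)
  expect_rel_equal(got$tauD[2], 0.12, 1e-5)
  expect_rel_equal(got$fraction[1], 0.35, 1e-4)
  expect_lt(abs(fit@offset), 1e-6)
  # components always ordered by increasing dwell time
  expect_true(!is.unsorted(got$tauD))
})

test_that("ligand fit roundtrips noiselessly with the 3D dwell time fixed", {
  vol <- detectionVolume(0.2, 5)
  cmp <- data.frame(kind = c("3D", "2D", "2D"),
                    tauD = c(32e-6, 8e-3, 67e-3),
                    fraction = c(0.45, 0.15, 0.40))
  cu <- noiselessCurve(3, cmp, Tdark = 0.12, tauTr = 4e-6,
                       lagRange = c(2e-6, 1))
  fit <- fitLigandACF(cu, vol, tauD1Fixed = 32e-6)
  got <- components(fit)
  expect_rel_equal(nTotal(fit), 3, 1e-6)
  expect_equal(got$kind, c("3D", "2D", "2D"))
  expect_true(got$fixed[1])
  expect_rel_equal(got$tauD[2], 8e-3, 1e-4)
  expect_rel_equal(got$tauD[3], 67e-3, 1e-4)
  expect_rel_equal(got$fraction[3], 0.40, 1e-3)
  expect_error(fitLigandACF(cu, vol, tauD1Fixed = -1), "tauD1Fixed")
})

test_that("collapsed dwell times trigger the degenerate single-component refit", {
  vol <- detectionVolume(0.2, 5)
  cmp <- data.frame(kind = "2D", tauD = 0.0769, fraction = 1)
  cu <- noiselessCurve(4.6, cmp)
  fit <- fitMembraneACF(cu, vol)
  got <- components(fit)
  # either the ratio collapsed (-> flagged + refit with one component) or
  # one component carries essentially the whole amplitude
  if (fit@degenerate) {
    expect_equal(nrow(got), 1L)
    expect_rel_equal(got$tauD[1], 0.0769, 1e-5)
  } else {
    expect_gt(max(got$fraction), 0.999)
    expect_rel_equal(got$tauD[which.max(got$fraction)], 0.0769, 1e-4)
  }
  expect_rel_equal(deriveDensity(fit, vol), 4.6 / (pi * 0.04), 1e-4)
})

test_that("best-of-starts fitting is invariant under start permutation", {
  vol <- detectionVolume(0.2, 5)
  cmp <- data.frame(kind = c("2D", "2D"), tauD = c(0.01, 0.12),
                    fraction = c(0.35, 0.65))
  cu <- noiselessCurve(4.6, cmp, Tdark = 0.1, tauTr = 2e-5)
  fd <- fflux:::curveFitData(cu, c(4e-6, 1))
  sg <- fflux:::acfStartGuess(fd)
  G0g <- sg$G0
  lower <- c(log(1e-4), 0, log(1e-5), log(1), 0, log(1e-7), -0.3)
  upper <- c(log(1e7), 1, log(5), log(1e5), 0.8, log(50e-6), 0.3)
  rf <- function(p, fd)
    (fflux:::.acfEval(fd$lag, exp(p[1]), c(exp(p[3]), exp(p[3] + p[4])),
                      c(p[2], 1 - p[2]), c(FALSE, FALSE), p[5], exp(p[6]),
                      5) + p[7] * G0g - fd$G) * fd$w
  starts <- lapply(fflux:::ACF_START_JITTER, function(j)
    c(log(sg$N0 * j["N"]), 0.5, log(sg$tau0 * 0.5 * j["tau"]), log(10),
      0.05, log(4e-6), 0))
  b1 <- fflux:::acfFitEngine(fd, rf, starts, lower, upper)
  b2 <- fflux:::acfFitEngine(fd, rf, rev(starts), lower, upper)
  expect_equal(b1$par, b2$par, tolerance = 1e-10)
  expect_equal(b1$rss, b2$rss, tolerance = 1e-12)
})

test_that("pure free ligand yields negligible bound fractions", {
  vol <- detectionVolume(0.2, 5)
  sp <- speciesSpec("3D", D = 316, density = 3, epsilon = 6e4)
  cfg <- simulationConfig(vol, sp, duration = 0.6, binTime = 4e-6,
                          dt = 4e-6, boxScale = 5, seed = 71)
  cu <- autocorrelate(simulateTrace(cfg))
  tauD1 <- 0.2^2 / (4 * 316)
  fit <- fitLigandACF(cu, vol, tauD1Fixed = tauD1)
  got <- components(fit)
  expect_lt(sum(got$fraction[got$kind == "2D"]), 0.05)
})
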