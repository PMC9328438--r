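# Photon counting histograms: tallying, the model and its Monte-Carlo
# oracle, fits, the first-order correction and model selection.

# Static snapshot Monte-Carlo oracle: Poisson(Nbar-equivalent) particles
# placed uniformly per bin, Poisson photon counts from the summed MDF.
mcHistogram3d <- function(Nbar, lambda, nBins, seed, omega = 0.2, S = 5) {
  set.seed(seed)
  Vref <- pi^1.5 * omega^2 * (S * omega)
  Lxy <- 5 * omega; Lz <- 2.5 * S * omega
  Vbox <- (2 * Lxy)^2 * (2 * Lz)
  out <- integer(0)
  for (start in seq(1, nBins, by = 10000)) {
    nb <- min(10000, nBins - start + 1)
    npart <- rpois(nb, Nbar / Vref * Vbox)
    tot <- sum(npart)
    x <- runif(tot, -Lxy, Lxy); y <- runif(tot, -Lxy, Lxy)
    z <- runif(tot, -Lz, Lz)
    u <- exp(-2 * (x^2 + y^2) / omega^2 - 2 * z^2 / (S * omega)^2)
    lam <- numeric(nb)
    agg <- rowsum(u, rep(seq_len(nb), npart))
    lam[as.integer(rownames(agg))] <- agg
    out <- c(out, rpois(nb, lam * lambda))
  }
  out
}

test_that("histogram computation tallies and conserves counts", {
  # constant one-count bins, rebinned x2 -> all mass at k = 2
  tr <- photonTrace(rep(1, 1000), binTime = 1e-5)
  h <- computePCH(tr, 2e-5)
  expect_equal(h@frequency, c(0, 0, 500))
  # conservation + equality with a brute-force tally
  set.seed(12)
  y <- rpois(1e4, 2.3)
  tr2 <- photonTrace(y, binTime = 1e-5)
  h2 <- computePCH(tr2, 5e-5)
  yr <- colSums(matrix(y, nrow = 5))
  expect_equal(sum(h2@frequency), 2000)
  tally <- table(factor(yr, levels = 0:max(yr)))
  expect_equal(h2@frequency, as.numeric(tally))
  expect_error(computePCH(tr2, 2.5e-5), "integer multiple")
})

test_that("PCH model is a normalized distribution with the exact moments", {
  grid <- expand.grid(eps = c(5e3, 18111, 5e4), Nbar = c(0.5, 4.6, 20))
  for (i in seq_len(nrow(grid))) {
    cmp <- data.frame(epsilon = grid$eps[i], Nbar = grid$Nbar[i])
    for (geom in c("3d", "2d")) {
      g1 <- if (geom == "3d") 2^(-3 / 2) else 0.5
      kM <- 30 + ceiling(12 * g1 * grid$eps[i] * 1e-4 * grid$Nbar[i])
      p <- pchModel(cmp, 0, 1e-4, kM, geometry = geom)
      expect_lt(abs(sum(p) - 1), 1e-9)
      expect_true(all(p >= 0))
      expect_rel_equal(sum(seq_len(kM) * p[-1]),
                       g1 * grid$eps[i] * grid$Nbar[i] * 1e-4, 1e-6)
    }
  }
  # dark molecules: all mass at zero
  expect_equal(pchModel(data.frame(epsilon = 0, Nbar = 3), 0, 1e-4, 10)[1],
               1)
  # shot-noise limit: variance/mean -> 1 as eps * binTime -> 0
  pp <- pchModel(data.frame(epsilon = 10, Nbar = 5), 0, 1e-7, 30)
  m <- sum(0:30 * pp); v <- sum((0:30 - m)^2 * pp)
  expect_lt(abs(v / m - 1), 1e-6)
  expect_error(pchModel(data.frame(epsilon = 5e4, Nbar = 10), 0, 1e-4, 5),
               "kMax")
})

test_that("model matches the Monte-Carlo snapshot oracle across a brightness/occupancy grid", {
  for (lam in c(0.5, 1.8, 4)) {
    for (Nbar in c(0.6, 4.6, 15)) {
      y <- mcHistogram3d(Nbar, lam, 1.2e5, seed = round(100 * lam) + Nbar)
      tab <- tabulate(y + 1, nbins = max(y) + 1)
      pm <- pchModel(data.frame(epsilon = lam / 1e-4, Nbar = Nbar), 0,
                     1e-4, max(y) + 15)
      E <- 1.2e5 * pm[seq_along(tab)]
      keep <- E > 5
      chisq <- sum((tab[keep] - E[keep])^2 / E[keep])
      p <- pchisq(chisq, sum(keep) - 1, lower.tail = FALSE)
      expect_gt(p, 0.01)
    }
  }
})

test_that("fits roundtrip noiseless expected frequencies", {
  cmp <- data.frame(epsilon = 18111, Nbar = 4.6)
  p <- pchModel(cmp, F = 0.3, pchBinTime = 1e-4, kMax = 50)
  h <- new("PCHistogram", k = 0:50, frequency = 3e5 * p / sum(p),
           binTime = 1e-4, nBins = 3e5)
  fit <- fitPCH(h, 1, Ffixed = 0.3)
  expect_rel_equal(brightnessValues(fit), 18111, 1e-4)
  expect_rel_equal(components(fit)$Nbar, 4.6, 1e-4)
  # two components, sorted by brightness
  cmp2 <- data.frame(epsilon = c(4383, 34006), Nbar = c(0.5, 0.5))
  p2 <- pchModel(cmp2, 0, 1e-4, 60, geometry = "2d")
  h2 <- new("PCHistogram", k = 0:60, frequency = 6e5 * p2 / sum(p2),
            binTime = 1e-4, nBins = 6e5)
  fit2 <- fitPCH(h2, 2, Ffixed = 0, geometry = "2d")
  expect_rel_equal(brightnessValues(fit2)[1], 4383, 1e-3)
  expect_rel_equal(brightnessValues(fit2)[2], 34006, 1e-3)
  expect_true(!is.unsorted(brightnessValues(fit2)))
  expect_false(fit2@collapsed)
})

test_that("first-order correction is recovered and vanishes for the ideal volume", {
  # F = 0.5 roundtrip through sampled histograms
  ps <- pchModel(data.frame(epsilon = 5e4, Nbar = 2.7), F = 0.5,
                 pchBinTime = 2e-5, kMax = 30)
  hs <- fflux:::sampleHistogram(ps, 5e5, 2e-5, seed = 9)
  fc <- calibratePCHCorrection(hs)
  expect_rel_equal(correctionF(fc), 0.5, 0.15)
  # quasi-static simulated trace through the ideal Gaussian volume: F ~ 0
  vol <- detectionVolume(0.2, 5)
  sp <- speciesSpec("3D", D = 1, density = 13.5, epsilon = 4e4)
  cfg <- simulationConfig(vol, sp, duration = 25, binTime = 1e-4,
                          dt = 1e-4, boxScale = 5, seed = 81)
  h <- computePCH(simulateTrace(cfg), 1e-4)
  fit <- calibratePCHCorrection(h)
  expect_lt(abs(correctionF(fit)), 0.1)
})

test_that("model selection distinguishes one from two brightness populations", {
  # generative truth: one species -> selects 1
  p1 <- pchModel(data.frame(epsilon = 18111, Nbar = 4.6), 0, 1e-4, 50)
  h1 <- fflux:::sampleHistogram(p1, 3e5, 1e-4, seed = 13)
  sel1 <- selectPCHModel(h1, Ffixed = 0)
  expect_equal(sel1$nComponents, 1L)
  # two species, 10x brightness ratio -> selects 2
  p2 <- pchModel(data.frame(epsilon = c(3400, 34000), Nbar = c(0.6, 0.6)),
                 0, 1e-4, 60)
  h2 <- fflux:::sampleHistogram(p2, 3e5, 1e-4, seed = 14)
  sel2 <- selectPCHModel(h2, Ffixed = 0)
  expect_equal(sel2$nComponents, 2L)
  # indistinguishable components -> parsimony picks 1
  p3 <- pchModel(data.frame(epsilon = c(18111, 18111),
                            Nbar = c(2.3, 2.3)), 0, 1e-4, 50)
  h3 <- fflux:::sampleHistogram(p3, 3e5, 1e-4, seed = 15)
  sel3 <- selectPCHModel(h3, Ffixed = 0)
  expect_equal(sel3$nComponents, 1L)
})

test_that("two-component brightness regime is recovered from sampled histograms", {
  cmp2 <- data.frame(epsilon = c(4383, 34006), Nbar = c(0.5, 0.5))
  p2 <- pchModel(cmp2, F = 0, pchBinTime = 1e-4, kMax = 60,
                 geometry = "2d")
  eps <- sapply(11:15, function(s) {
    h <- fflux:::sampleHistogram(p2, 6e5, 1e-4, seed = s)
    brightnessValues(fitPCH(h, 2, Ffixed = 0, geometry = "2d"))
  })
  expect_rel_equal(median(eps[1, ]), 4383, 0.30)
  expect_rel_equal(median(eps[2, ]), 34006, 0.30)
})
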