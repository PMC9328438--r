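# Photon counting histograms and the PCH model.
#
# Conventions: the reference volume is the 1/e^2 effective volume
# V_ref = pi^{3/2} omega^2 (S omega) for the 3D-Gaussian MDF (gamma factor
# gamma_1 = 2^{-3/2}), and the beam area A_ref = pi omega^2 for the 2D
# in-plane MDF (gamma_1 = 1/2).  With these choices the PCH particle number
# N_bar shares the scale of the FCS amplitude-derived N, and the modeled
# mean counts per bin equal gamma_1 * sum_i (epsilon_i N_bar_i) * binTime.

PCH_GAMMA <- c("3d" = 2^(-3/2), "2d" = 0.5)

#' Compute a photon counting histogram
#'
#' Rebins the trace to the requested counting bin time (by summation; the
#' requested bin time must be an integer multiple of the native bin width)
#' and tallies the per-bin counts from 0 up to the largest observed count.
#'
#' @param trace a \code{\linkS4class{PhotonTrace}}
#' @param pchBinTime counting bin time (s); typical choices are 20 us for
#'   solution dye calibration and 100 us for membrane receptors
#' @return a \code{\linkS4class{PCHistogram}}
#' @export
computePCH <- function(trace, pchBinTime = binTime(trace)) {
  r <- pchBinTime / binTime(trace)
  if (abs(r - round(r)) > 1e-9)
    stop("pchBinTime must be an integer multiple of the trace bin time")
  y <- rebinCounts(counts(trace), as.integer(round(r)))
  kmax <- max(y)
  freq <- tabulate(y + 1L, nbins = kmax + 1L)
  new("PCHistogram", k = seq.int(0L, kmax), frequency = as.numeric(freq),
      binTime = pchBinTime, nBins = length(y))
}

# Gauss-Legendre nodes/weights on [0, b] (Golub-Welsch, no extra deps).
# The unit rule is computed once per node count and cached; [0, b] is a
# linear rescaling.
.glCache <- new.env(parent = emptyenv())

gaussLegendre01 <- function(n, b) {
  key <- as.character(n)
  unit <- .glCache[[key]]
  if (is.null(unit)) {
    i <- seq_len(n - 1)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- beta
    J[cbind(i + 1, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    unit <- list(x01 = (e$values + 1) / 2, w01 = e$vectors[1, ]^2)
    .glCache[[key]] <- unit
  }
  list(nodes = unit$x01 * b, weights = unit$w01 * b)
}

# Single-particle photon-count probabilities p1(k), k = 1..kmax, for one
# particle in the reference volume with peak counts-per-bin lambda.
# 3D-Gaussian MDF:  p1(k) = sqrt(2/pi) Int_0^inf t^2 Poi(k; lambda e^{-t^2}) dt
# 2D in-plane MDF:  p1(k) = (1/2)     Int_0^inf     Poi(k; lambda e^{-s})   ds
# (change of variables from the amplitude distribution of the MDF).
pchP1 <- function(kmax, lambda, geometry = c("3d", "2d"), nodes = 260L) {
  geometry <- match.arg(geometry)
  if (lambda <= 0) return(rep(0, kmax))
  k <- seq_len(kmax)
  if (geometry == "3d") {
    tmax <- sqrt(max(log(lambda) + 41, 1))
    gl <- gaussLegendre01(nodes, tmax)
    lam <- lambda * exp(-gl$nodes^2)
    M <- outer(lam, k, function(l, kk) dpois(kk, l))    # nodes x k
    as.numeric(sqrt(2 / pi) * colSums(M * (gl$weights * gl$nodes^2)))
  } else {
    smax <- max(log(lambda) + 41, 1)
    gl <- gaussLegendre01(nodes, smax)
    lam <- lambda * exp(-gl$nodes)
    M <- outer(lam, k, function(l, kk) dpois(kk, l))
    as.numeric(0.5 * colSums(M * gl$weights))
  }
}

#' Evaluate the photon counting histogram model
#'
#' Probability of observing k photons in a bin for a mixture of species with
#' molecular brightness \eqn{\epsilon_i} and mean particle number
#' \eqn{\bar N_i} in the reference volume of the chosen molecular detection
#' function.  The single-particle probabilities are obtained by numerical
#' integration of the Poisson distribution over the MDF amplitude
#' distribution; the particle-number average (Poisson-weighted
#' self-convolution across particles and species) is evaluated exactly with
#' the compound-Poisson (Panjer) recursion.
#'
#' The first-order out-of-focus correction F adds the contribution of weak,
#' spatially extended out-of-focus emission: to first order in the local
#' rate, light from the out-of-focus volume only ever contributes single
#' photons, adding \eqn{F \gamma_1 \epsilon_i \bar N_i T} to the k = 1 jump
#' intensity of each species (T = bin time).  F = 0 is the ideal Gaussian
#' volume.
#'
#' @param components data.frame with columns \code{epsilon} (counts
#'   molecule^-1 s^-1) and \code{Nbar}
#' @param F first-order out-of-focus correction (>= 0)
#' @param pchBinTime counting bin time (s)
#' @param kMax largest count value evaluated
#' @param geometry "3d" (3D-Gaussian MDF, the default, mirroring the uniform
#'   instrument protocol) or "2d" (in-plane Gaussian MDF for membrane
#'   species)
#' @return numeric vector p(0..kMax); sums to 1 up to truncation (an error is
#'   raised if the truncated tail mass exceeds 1e-6)
#' @examples
#' p <- pchModel(data.frame(epsilon = 18111, Nbar = 4.6), F = 0,
#'               pchBinTime = 1e-4, kMax = 60)
#' sum(p)
#' @export
pchModel <- function(components, F = 0, pchBinTime, kMax,
                     geometry = c("3d", "2d")) {
  geometry <- match.arg(geometry)
  if (F < 0) stop("F must be >= 0")
  nu <- rep(0, kMax)  # jump intensity: expected number of j-photon emitters
  g1 <- PCH_GAMMA[[geometry]]
  for (i in seq_len(nrow(components))) {
    lam <- components$epsilon[i] * pchBinTime
    if (lam <= 0) next
    nu <- nu + components$Nbar[i] * pchP1(kMax, lam, geometry)
    if (F > 0)
      nu[1] <- nu[1] + F * g1 * lam * components$Nbar[i]
  }
  # Panjer recursion for the compound-Poisson count distribution
  p <- numeric(kMax + 1)
  p[1] <- exp(-sum(nu))
  jnu <- seq_len(kMax) * nu
  for (k in seq_len(kMax))
    p[k + 1] <- sum(jnu[seq_len(k)] * p[k:1]) / k
  tail_mass <- 1 - sum(p)
  if (tail_mass > 1e-6)
    stop("kMax too small: truncated tail mass ", format(tail_mass))
  p
}

# Draw a histogram directly from a model pmf (used for parametric
# bootstrap-style generation in tests and calibration roundtrips).
sampleHistogram <- function(p, nBins, pchBinTime, seed = 1L) {
  freq <- withLocalSeed(seed, function()
    as.numeric(stats::rmultinom(1, nBins, p)))
  kmax <- max(which(freq > 0)) - 1L
  new("PCHistogram", k = seq.int(0L, kmax),
      frequency = freq[seq_len(kmax + 1L)],
      binTime = pchBinTime, nBins = nBins)
}
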