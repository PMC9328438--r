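# Autocorrelation of photon traces.

#' Multi-tau autocorrelation of a photon trace
#'
#' Computes the normalized fluctuation autocorrelation
#' \deqn{G(\tau) = \langle \delta I(t)\,\delta I(t+\tau)\rangle /
#'   \langle I \rangle^2}
#' on a quasi-logarithmic lag grid: \code{m} linear lags per octave with the
#' counts rebinned by a factor 2 per octave (the classic hardware-correlator
#' scheme).  G is defined without the +1 baseline, so G(infinity) = 0 and for
#' an ideal single species the zero-lag amplitude reads 1/N.
#'
#' With the default symmetric normalization the means of the leading and
#' lagging segments are computed separately at each lag, which removes the
#' normalization bias at long lags; "global" uses the single whole-trace mean
#' (the textbook definition evaluated by
#' \code{\link{autocorrelateDirect}}).  Lags from rebinned octaves estimate a
#' triangularly lag-averaged covariance; at base resolution (the first two
#' octaves) the estimate is identical to the brute-force definition.
#'
#' @param trace a \code{\linkS4class{PhotonTrace}} (length >= 4 m bins, not
#'   all zero)
#' @param m points per octave (even; default 16)
#' @param rebinFactor rebin the counts by this integer factor before
#'   correlating (1 = native resolution)
#' @param normalization "symmetric" (default) or "global"
#' @return a \code{\linkS4class{CorrelationCurve}}
#' @seealso \code{\link{autocorrelateDirect}}, \code{\link{averageCurves}}
#' @export
autocorrelate <- function(trace, m = 16L, rebinFactor = 1L,
                          normalization = c("symmetric", "global")) {
  normalization <- match.arg(normalization)
  m <- as.integer(m)
  if (m < 2L || m %% 2L != 0L) stop("m must be an even integer >= 2")
  y <- counts(trace)
  bt <- binTime(trace)
  if (rebinFactor > 1L) {
    y <- rebinCounts(y, as.integer(rebinFactor))
    bt <- bt * as.integer(rebinFactor)
  }
  if (length(y) < 4L * m)
    stop("trace must contain at least 4*m bins after rebinning")
  if (sum(y) == 0)
    stop("all-zero trace: mean intensity is zero, correlation undefined")
  res <- multitau_cpp(as.numeric(y), m,
                      if (normalization == "symmetric") 0L else 1L)
  new("CorrelationCurve", lags = res$lag_bins * bt, G = res$G,
      npts = res$npts, meanRate = sum(y) / (length(y) * bt), binTime = bt)
}

#' Brute-force autocorrelation (test oracle)
#'
#' Literal evaluation of the normalized covariance definition at every
#' integer lag up to \code{maxLagBins}, with no rebinning.  O(N * maxLag);
#' intended as the independent reference for \code{\link{autocorrelate}} and
#' for short traces.
#'
#' @param trace a \code{\linkS4class{PhotonTrace}}
#' @param maxLagBins largest lag, in bins (< trace length)
#' @param normalization "global" (default; single whole-trace mean, the
#'   textbook definition) or "symmetric"
#' @return a \code{\linkS4class{CorrelationCurve}}
#' @examples
#' tr <- photonTrace(rep(c(1, 0), 50), binTime = 1e-3)
#' G <- corrValues(autocorrelateDirect(tr, 4))
#' G[2]  # +1 at lag 2: the trace is periodic
#' @export
autocorrelateDirect <- function(trace, maxLagBins,
                                normalization = c("global", "symmetric")) {
  normalization <- match.arg(normalization)
  y <- counts(trace)
  maxLagBins <- as.integer(maxLagBins)
  if (maxLagBins >= length(y)) stop("maxLagBins must be < trace length")
  if (maxLagBins < 1L) stop("maxLagBins must be >= 1")
  if (sum(y) == 0)
    stop("all-zero trace: mean intensity is zero, correlation undefined")
  res <- direct_acf_cpp(as.numeric(y), maxLagBins,
                        if (normalization == "symmetric") 0L else 1L)
  new("CorrelationCurve", lags = res$lag_bins * binTime(trace), G = res$G,
      npts = res$npts, meanRate = meanRate(trace), binTime = binTime(trace))
}

#' Average correlation curves across repeated reads
#'
#' Element-wise average of curves on identical lag grids, weighted by the
#' per-lag averaging counts.  Used to combine the repeated reads taken on one
#' cell: each read is correlated separately and the curves averaged.
#'
#' @param curves list of \code{\linkS4class{CorrelationCurve}} objects with
#'   identical lag grids
#' @return a \code{\linkS4class{CorrelationCurve}}
#' @export
averageCurves <- function(curves) {
  if (length(curves) == 0) stop("no curves to average")
  if (length(curves) == 1L) return(curves[[1]])
  lag0 <- lagTimes(curves[[1]])
  for (cu in curves[-1])
    if (!isTRUE(all.equal(lagTimes(cu), lag0)))
      stop("curves must share an identical lag grid")
  W <- vapply(curves, nPoints, numeric(length(lag0)))
  Gm <- vapply(curves, corrValues, numeric(length(lag0)))
  wsum <- rowSums(W)
  new("CorrelationCurve", lags = lag0,
      G = rowSums(Gm * W) / wsum, npts = wsum,
      meanRate = mean(vapply(curves, meanRate, numeric(1))),
      binTime = binTime(curves[[1]]))
}

# Sum consecutive groups of `factor` bins; trailing remainder dropped.
rebinCounts <- function(y, factor) {
  if (factor == 1L) return(y)
  n <- (length(y) %/% factor) * factor
  colSums(matrix(y[seq_len(n)], nrow = factor))
}
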