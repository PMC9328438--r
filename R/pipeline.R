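# Experiment orchestration: calibration -> per-cell trace fitting ->
# condition-level summary tables.

#' Summary statistics for a set of per-cell records
#'
#' @param x numeric vector (per-cell values; NAs dropped)
#' @return list with \code{mean}, \code{sem} (sd/sqrt(n); NA for a single
#'   record) and \code{n}
#' @examples
#' summarizeRecords(c(2, 4, 6))  # mean 4, sem 1.1547
#' @export
summarizeRecords <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) stop("no records to summarize")
  list(mean = mean(x), sem = if (n > 1) sd(x) / sqrt(n) else NA_real_,
       n = n)
}

combineHistograms <- function(hists) {
  if (length(hists) == 1L) return(hists[[1]])
  kmax <- max(vapply(hists, function(h) max(h@k), integer(1)))
  freq <- rep(0, kmax + 1)
  for (h in hists) freq[seq_along(h@frequency)] <-
    freq[seq_along(h@frequency)] + h@frequency
  new("PCHistogram", k = seq.int(0L, kmax), frequency = freq,
      binTime = hists[[1]]@binTime,
      nBins = sum(vapply(hists, function(h) h@nBins, numeric(1))))
}

speciesFromList <- function(s) {
  if (is(s, "SpeciesSpec")) return(s)
  speciesSpec(s$dimensionality, s$D, s$density, s$epsilon,
              Tdark = if (is.null(s$Tdark)) 0 else s$Tdark,
              tauDark = if (is.null(s$tauDark)) 5e-6 else s$tauDark)
}

#' Read an experiment configuration from YAML
#'
#' The YAML document mirrors the list accepted by
#' \code{\link{runExperiment}}: \code{volume} (omega, S), \code{calibration}
#' (Dref, concentration_nM, epsilon, duration, ...), \code{conditions}
#' (named, each with \code{model} and a list of \code{species}),
#' \code{nCells}, \code{reads}, \code{duration}, \code{binTime}, \code{dt},
#' \code{seed} and \code{analysis} options.
#'
#' @param path YAML file path
#' @return experiment configuration list
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$volume) && !is(cfg$volume, "DetectionVolume"))
    cfg$volume <- detectionVolume(cfg$volume$omega,
                                  if (is.null(cfg$volume$S)) 5 else
                                    cfg$volume$S)
  cfg
}

#' Run a full synthetic fluctuation experiment
#'
#' Executes the complete protocol on synthetic data: (1) calibration of the
#' detection volume from a simulated dye-standard trace (autocorrelation fit
#' of a single 3D component with triplet term) and of the PCH first-order
#' correction (one-component fit at the calibration bin time, F free); then
#' (2) for every cell of every condition, simulates the configured reads,
#' correlates each read and averages the curves, fits the condition's
#' autocorrelation model with S fixed to the calibration value, computes the
#' PCH at the analysis bin time with the frozen correction, and derives the
#' diffusion coefficient of the dominant membrane component, the particle
#' density (N/um^2) and the molecular brightness(es); finally (3) aggregates
#' mean +/- SEM across cells per condition.  Everything is reproducible from
#' the base seed; individual fit failures are logged and excluded from the
#' summaries, a calibration failure aborts.
#'
#' @param config configuration list; see \code{\link{readExperimentConfig}}
#'   and the package vignette.  Minimal fields: \code{volume}
#'   (ground-truth \code{\linkS4class{DetectionVolume}}), \code{calibration}
#'   (list with \code{Dref}, \code{concentration_nM}; optional
#'   \code{epsilon}, \code{duration}, \code{binTime}, \code{dt},
#'   \code{boxScale}, \code{pchBinTime}), \code{conditions} (named list,
#'   each with \code{model} = "membrane" or "ligand", \code{species},
#'   optional \code{pchComponents} (1, 2 or "auto") and, for ligand
#'   conditions, \code{ligandDfree}), \code{nCells}, \code{reads},
#'   \code{duration}, \code{binTime}, \code{dt}, \code{boxScale},
#'   \code{seed}, and optional \code{analysis} list (\code{pchBinTime},
#'   \code{pchGeometry}, \code{window})
#' @return list with \code{calibration} (a
#'   \code{\linkS4class{CalibrationResult}}), \code{correctionFit} (a
#'   \code{\linkS4class{PCHFit}}), \code{records} (per-cell data.frame),
#'   \code{summary} (per-condition mean/SEM/n data.frame) and
#'   \code{failures}
#' @export
runExperiment <- function(config) {
  if (is.null(config$conditions) || length(config$conditions) == 0)
    stop("config must name at least one condition")
  if (is.null(config$calibration))
    stop("config must contain a calibration block")
  vol <- config$volume
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  nCells <- if (is.null(config$nCells)) 1L else as.integer(config$nCells)
  reads <- if (is.null(config$reads)) 2L else as.integer(config$reads)
  an <- config$analysis
  pchBinTime <- if (is.null(an$pchBinTime)) 1e-4 else an$pchBinTime
  pchGeometry <- if (is.null(an$pchGeometry)) "3d" else an$pchGeometry
  window <- if (is.null(an$window)) ACF_FIT_WINDOW else an$window

  # ---- calibration (failure here aborts)
  cal <- config$calibration
  calTrace <- simulateCalibrationTrace(
    Dref = cal$Dref, volume = vol,
    concentration = nanomolarToPerCubicMicron(cal$concentration_nM),
    epsilon = if (is.null(cal$epsilon)) 5e4 else cal$epsilon,
    duration = if (is.null(cal$duration)) 1 else cal$duration,
    seed = seed,
    binTime = if (is.null(cal$binTime)) 2e-6 else cal$binTime,
    dt = if (is.null(cal$dt)) 1e-6 else cal$dt,
    boxScale = if (is.null(cal$boxScale)) 5 else cal$boxScale)
  calib <- fitCalibration(autocorrelate(calTrace), cal$Dref)
  calPch <- computePCH(calTrace, if (is.null(cal$pchBinTime)) 2e-5 else
                                   cal$pchBinTime)
  corrFit <- calibratePCHCorrection(calPch, geometry = "3d")
  Fhat <- correctionF(corrFit)

  records <- list()
  failures <- list()
  condNames <- names(config$conditions)
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[[ci]]
    model <- if (is.null(cond$model)) "membrane" else cond$model
    species <- lapply(cond$species, speciesFromList)
    for (cell in seq_len(nCells)) {
      res <- tryCatch({
        curves <- list()
        hists <- list()
        for (rd in seq_len(reads)) {
          scfg <- simulationConfig(
            vol, species,
            duration = if (is.null(cond$duration)) config$duration else
                         cond$duration,
            binTime = if (is.null(cond$binTime)) config$binTime else
                        cond$binTime,
            boxScale = if (is.null(config$boxScale)) 8 else config$boxScale,
            dt = if (is.null(config$dt)) config$binTime else config$dt,
            seed = seed + 100000L * ci + 100L * cell + rd)
          tr <- simulateTrace(scfg)
          curves[[rd]] <- autocorrelate(tr)
          hists[[rd]] <- computePCH(tr, pchBinTime)
        }
        curve <- averageCurves(curves)
        fit <- if (model == "ligand") {
          tauD1 <- beamWaist(calib)^2 / (4 * cond$ligandDfree)
          fitLigandACF(curve, calib, tauD1, window = window)
        } else {
          fitMembraneACF(curve, calib, window = window)
        }
        dom <- dominantComponent(fit)
        hist <- combineHistograms(hists)
        nPch <- if (is.null(cond$pchComponents)) 1L else cond$pchComponents
        pchFit <- if (identical(nPch, "auto")) {
          sel <- selectPCHModel(hist, Ffixed = Fhat,
                                geometry = pchGeometry)
          if (sel$nComponents == 2L) sel$fit2 else sel$fit1
        } else {
          fitPCH(hist, as.integer(nPch), Ffixed = Fhat,
                 geometry = pchGeometry)
        }
        eps <- brightnessValues(pchFit)
        data.frame(
          condition = condNames[ci], cell = cell,
          N_total = nTotal(fit),
          tauD_dominant_s = dom$tauD,
          D_um2_s = deriveDiffusion(dom$tauD, calib),
          density_per_um2 = deriveDensity(fit, calib),
          epsilon1_cps = eps[1],
          epsilon2_cps = if (length(eps) > 1) eps[2] else NA_real_,
          acf_chisq = chiSquared(fit), pch_chisq = chiSquared(pchFit),
          degenerate = fit@degenerate)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(condition = condNames[ci], cell = cell,
                     reason = conditionMessage(res))
      } else {
        records[[length(records) + 1]] <- res
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(condition = character(), cell = integer(),
               reason = character())

  summary <- NULL
  if (!is.null(records)) {
    qty <- c("density_per_um2", "D_um2_s", "N_total", "epsilon1_cps",
             "epsilon2_cps")
    rows <- list()
    for (cn in unique(records$condition)) {
      sub <- records[records$condition == cn, , drop = FALSE]
      for (q in qty) {
        v <- sub[[q]]
        if (all(is.na(v))) next
        s <- summarizeRecords(v)
        rows[[length(rows) + 1]] <-
          data.frame(condition = cn, quantity = q, mean = s$mean,
                     sem = s$sem, n = s$n)
      }
    }
    summary <- do.call(rbind, rows)
  }
  list(calibration = calib, correctionFit = corrFit, records = records,
       summary = summary, failures = failures)
}
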