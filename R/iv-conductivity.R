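#' Fit an ohmic (linear) model to an I/V sweep
#'
#' Ordinary least squares of current on voltage. Cable-bacterium filaments
#' show linear I/V curves over the -1..1 V scan, so the slope is the
#' filament conductance in A/V.
#'
#' @param x an \linkS4class{IVSweep}, or a numeric vector of voltages (V).
#' @param currents numeric vector of currents (A); only when \code{x} is the
#'   voltage vector.
#' @param ... unused.
#' @return an \linkS4class{OhmicFit}.
#' @examples
#' fitIV(c(-1, 0, 1), c(-2e-9, 0, 2e-9))
#' @export
setGeneric("fitIV", function(x, ...) standardGeneric("fitIV"))

#' @rdname fitIV
#' @export
setMethod("fitIV", "IVSweep", function(x, ...) {
  fitIV(x@voltages, x@currents)
})

#' @rdname fitIV
#' @export
setMethod("fitIV", "numeric", function(x, currents, ...) {
  stopIf(length(x) != length(currents),
         "voltages and currents must have the same length")
  stopIf(length(x) < 2L, "need at least 2 (V, I) points to fit a line")
  stopIf(stats::var(x) == 0,
         "degenerate sweep: all voltages equal, no line can be fitted")
  fit <- stats::lm(currents ~ x)
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((currents - mean(currents))^2)
  r2 <- if (ssTot == 0) {
    if (ssRes <= .Machine$double.eps) 1 else 0
  } else max(0, min(1, 1 - ssRes / ssTot))
  new("OhmicFit",
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = r2)
})

#' Is a fitted sweep below the detection limit?
#'
#' A measurement is censored when the magnitude of its fitted conductance is
#' strictly below the instrument's limit of detection (default 1 pA/V). A
#' slope exactly equal to the limit counts as detectable.
#'
#' @param fit an \linkS4class{OhmicFit}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return logical scalar.
#' @export
isBelowLOD <- function(fit, config = AnalysisConfig()) {
  abs(fit@slope) < config@lodConductance
}

#' PCF count from filament diameter
#'
#' For strains without a direct electron-microscopy PCF count, the number of
#' periplasmic conductive fibers is estimated from the filament diameter
#' assuming a linear relation: count = c * pi * diameter, with diameter in
#' micrometers and density constant c (default 5). The result is rounded to
#' the nearest integer, halves away from zero.
#'
#' @param diameter filament diameter in micrometers (>= 0).
#' @param geometry a \linkS4class{StrainGeometry} supplying the density
#'   constant.
#' @return integer PCF count.
#' @examples
#' pcfCountFromDiameter(1.0, StrainGeometry("Hou", 850))  # 5*pi -> 16
#' @export
pcfCountFromDiameter <- function(diameter,
                                 geometry = StrainGeometry("", 850)) {
  stopIf(!is.finite(diameter) || diameter < 0,
         "filament diameter must be a non-negative number (micrometers)")
  as.integer(roundHalfAway(geometry@pcfDensityConstant * pi * diameter))
}

#' Total PCF cross-sectional area of a filament
#'
#' The conductive cross-section A of the conductivity formula: the PCF count
#' times the assumed single-fiber area (850 nm^2 for GS-type strains, 1100
#' nm^2 for RB).
#'
#' @param pcfCount integer number of PCFs (>= 1).
#' @param geometry a \linkS4class{StrainGeometry}.
#' @return total area in nm^2.
#' @examples
#' totalPCFArea(34, StrainGeometry("GS", 850, 34))   # 28900
#' totalPCFArea(15, StrainGeometry("RB", 1100, 15))  # 16500
#' @export
totalPCFArea <- function(pcfCount, geometry) {
  stopIf(pcfCount < 1, "pcfCount must be >= 1: no conductive path otherwise")
  pcfCount * geometry@perFiberArea
}

#' Resolve the PCF count for a filament
#'
#' An explicit fixed count on the geometry (the measured value for
#' single-strain enrichments) wins; the diameter formula is used only when
#' no fixed count is given.
#'
#' @param geometry a \linkS4class{StrainGeometry}.
#' @param diameter filament diameter in micrometers; required when the
#'   geometry has no fixed count.
#' @return integer PCF count.
#' @export
resolvePcfCount <- function(geometry, diameter = NULL) {
  if (!is.null(geometry@fixedPcfCount)) return(geometry@fixedPcfCount)
  stopIf(is.null(diameter),
         "geometry '%s' has no fixed PCF count; supply a filament diameter",
         geometry@strainLabel)
  pcfCountFromDiameter(diameter, geometry)
}

#' Single-PCF conductivity from a fitted sweep
#'
#' Applies sigma = (I * l) / (V * A) with I the fitted current at the
#' evaluation voltage (slope times V, i.e. the intercept is excluded), l the
#' electrode gap, and A the total PCF cross-sectional area. Internally the
#' calculation is in SI units; the result is reported in S/cm. Sweeps whose
#' conductance is below the limit of detection are censored: \code{belowLod}
#' is set and sigma is NA.
#'
#' @param fit an \linkS4class{OhmicFit}.
#' @param sweep the \linkS4class{IVSweep} the fit came from (supplies the
#'   gap length and sample id).
#' @param area total PCF cross-sectional area in nm^2 (> 0).
#' @param config an \linkS4class{AnalysisConfig}.
#' @return one-row data.frame with columns \code{sampleId}, \code{strain},
#'   \code{conductance} (A/V), \code{currentAtEval} (A), \code{sigmaSPerCm},
#'   \code{belowLod}.
#' @examples
#' sw <- IVSweep("f1", "GS", seq(-1, 1, 0.1), 1e-8 * seq(-1, 1, 0.1), 300)
#' conductivity(fitIV(sw), sw, area = 28900)  # 1.038 S/cm
#' @export
conductivity <- function(fit, sweep, area, config = AnalysisConfig()) {
  stopIf(!is.finite(area) || area <= 0, "area must be > 0 (nm^2)")
  stopIf(sweep@gapLength <= 0, "gap length must be > 0 (micrometers)")
  censored <- isBelowLOD(fit, config)
  iEval <- fit@slope * config@evalVoltage
  sigma <- if (censored) NA_real_ else
    (iEval * sweep@gapLength) / (config@evalVoltage * area) *
      .SIGMA_SCM_PER_SLOPE_UM_NM2
  data.frame(
    sampleId = sweep@sampleId,
    strain = sweep@strainLabel,
    conductance = fit@slope,
    currentAtEval = iEval,
    sigmaSPerCm = sigma,
    belowLod = censored,
    stringsAsFactors = FALSE
  )
}

#' Fit, censor and convert one sweep in a single call
#'
#' @param sweep an \linkS4class{IVSweep}.
#' @param geometry a \linkS4class{StrainGeometry}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param diameter filament diameter in micrometers, needed only when the
#'   geometry has no fixed PCF count.
#' @return one-row data.frame as in \code{\link{conductivity}}.
#' @export
analyzeSweep <- function(sweep, geometry, config = AnalysisConfig(),
                         diameter = NULL) {
  n <- resolvePcfCount(geometry, diameter)
  conductivity(fitIV(sweep), sweep, totalPCFArea(n, geometry), config)
}

#' Cohort summary of conductivity results
#'
#' Mean and sample standard deviation (n-1) over the non-censored
#' conductivities only — measurements below the limit of detection are
#' counted but never enter the statistics — plus Tukey box statistics
#' (quartiles, whiskers at the most extreme values within 1.5 IQR of the
#' box, outliers beyond).
#'
#' @param results data.frame with columns \code{sigmaSPerCm} and
#'   \code{belowLod}, e.g. row-bound outputs of \code{\link{conductivity}}.
#' @return a list with \code{nTotal}, \code{nBelowLod}, \code{mean},
#'   \code{sd}, \code{median}, \code{q1}, \code{q3}, \code{whiskerLow},
#'   \code{whiskerHigh}, \code{outliers}. For an all-censored cohort only
#'   the counts are populated; the statistics are NA.
#' @examples
#' res <- data.frame(sigmaSPerCm = c(1, 2, 3), belowLod = FALSE)
#' summarizeCohort(res)$mean  # 2
#' @export
summarizeCohort <- function(results) {
  stopIf(nrow(results) == 0L, "empty cohort")
  cens <- results$belowLod
  x <- results$sigmaSPerCm[!cens]
  out <- list(nTotal = nrow(results), nBelowLod = sum(cens))
  if (length(x) == 0L) {
    out <- c(out, list(mean = NA_real_, sd = NA_real_, median = NA_real_,
                       q1 = NA_real_, q3 = NA_real_, whiskerLow = NA_real_,
                       whiskerHigh = NA_real_, outliers = numeric()))
    return(out)
  }
  tk <- tukeyStats(x)
  c(out,
    list(mean = mean(x),
         sd = if (length(x) >= 2L) stats::sd(x) else NA_real_),
    tk)
}

#' Built-in strain geometry presets
#'
#' The conductivity-model geometries of the study strains: one PCF assumed
#' to be 850 nm^2 for GS-type strains (GS, Rat, Hou, Hou1) and 1100 nm^2 for
#' RB; fixed cross-section PCF counts of 34 (GS) and 15 (RB); Hou and Hou1
#' were mixed enrichments, so their counts come from the filament-diameter
#' formula.
#'
#' @param strain one of \code{"GS"}, \code{"RB"}, \code{"Rat"},
#'   \code{"Hou"}, \code{"Hou1"}.
#' @return a \linkS4class{StrainGeometry}.
#' @export
geometryPreset <- function(strain = c("GS", "RB", "Rat", "Hou", "Hou1")) {
  strain <- match.arg(strain)
  switch(strain,
    GS = StrainGeometry("GS", 850, fixedPcfCount = 34L),
    RB = StrainGeometry("RB", 1100, fixedPcfCount = 15L),
    Rat = StrainGeometry("Rat", 850),
    Hou = StrainGeometry("Hou", 850),
    Hou1 = StrainGeometry("Hou1", 850)
  )
}
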