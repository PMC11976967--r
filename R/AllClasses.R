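#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' IVSweep: one filament's two-probe current-voltage scan
#'
#' Container for a single voltage sweep measured on one cable-bacterium
#' filament bridged between two carbon-paste electrodes. Voltages are in
#' volts, currents in amperes, and the electrode gap (the length of the
#' conductive channel) in micrometers.
#'
#' @slot sampleId character scalar identifying the filament.
#' @slot strainLabel character scalar, e.g. \code{"GS"} or \code{"RB"}.
#' @slot voltages numeric vector of applied voltages (V).
#' @slot currents numeric vector of measured currents (A), parallel to
#'   \code{voltages}.
#' @slot gapLength numeric scalar, electrode gap in micrometers (> 0).
#' @slot atmosphere character scalar, one of \code{"vacuum"}, \code{"N2"},
#'   \code{"air"}.
#'
#' @examples
#' sw <- IVSweep("f1", "GS", c(-1, 0, 1), c(-2e-9, 0, 2e-9), gapLength = 300)
#' fitIV(sw)
#' @export
setClass("IVSweep",
  representation(
    sampleId = "character",
    strainLabel = "character",
    voltages = "numeric",
    currents = "numeric",
    gapLength = "numeric",
    atmosphere = "character"
  )
)

setValidity("IVSweep", function(object) {
  msg <- character()
  if (length(object@voltages) != length(object@currents))
    msg <- c(msg, "voltages and currents must have the same length")
  if (length(object@voltages) < 3L)
    msg <- c(msg, "a sweep needs at least 3 points")
  if (length(object@gapLength) != 1L || !is.finite(object@gapLength) ||
      object@gapLength <= 0)
    msg <- c(msg, "gapLength must be a single positive number (micrometers)")
  if (!object@atmosphere %in% c("vacuum", "N2", "air"))
    msg <- c(msg, "atmosphere must be one of 'vacuum', 'N2', 'air'")
  if (length(msg)) msg else TRUE
})

#' @rdname IVSweep-class
#' @param sampleId,strainLabel,voltages,currents,gapLength,atmosphere see slots.
#' @export
IVSweep <- function(sampleId, strainLabel, voltages, currents, gapLength,
                    atmosphere = "vacuum") {
  obj <- new("IVSweep",
    sampleId = as.character(sampleId),
    strainLabel = as.character(strainLabel),
    voltages = as.numeric(voltages),
    currents = as.numeric(currents),
    gapLength = as.numeric(gapLength),
    atmosphere = atmosphere
  )
  if (min(obj@voltages) >= 0 || max(obj@voltages) <= 0)
    warning("voltages do not span both signs; expected a full -V..+V scan",
            call. = FALSE)
  obj
}

setMethod("show", "IVSweep", function(object) {
  cat(sprintf(
    "IVSweep '%s' (strain %s): %d points, V in [%g, %g] V, gap %g um, %s\n",
    object@sampleId, object@strainLabel, length(object@voltages),
    min(object@voltages), max(object@voltages), object@gapLength,
    object@atmosphere
  ))
})

#' OhmicFit: an ordinary least-squares line through an I/V sweep
#'
#' @slot slope conductance in amperes per volt.
#' @slot intercept current offset in amperes.
#' @slot rSquared coefficient of determination in [0, 1]. For a perfectly
#'   fitted constant-current sweep (zero total variance, zero residual) the
#'   0/0 case is defined as 1.
#' @export
setClass("OhmicFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric")
)

setValidity("OhmicFit", function(object) {
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    "rSquared must lie in [0, 1]" else TRUE
})

setMethod("show", "OhmicFit", function(object) {
  cat(sprintf("OhmicFit: slope %.4g A/V, intercept %.4g A, r^2 = %.6f\n",
              object@slope, object@intercept, object@rSquared))
})

#' StrainGeometry: per-strain PCF cross-section model
#'
#' Captures how conductance is converted to conductivity for a given strain:
#' the assumed cross-sectional area of one periplasmic conductive fiber
#' (PCF), and either a fixed PCF count measured by electron microscopy or the
#' linear diameter scaling \eqn{n = c \pi d} (count per filament, diameter
#' \eqn{d} in micrometers, density constant \eqn{c} = 5 by default) used for
#' strains without a direct count.
#'
#' @slot strainLabel character scalar.
#' @slot perFiberArea assumed single-PCF cross-sectional area, nm^2.
#' @slot fixedPcfCount integer PCF count per filament, or NULL to use the
#'   diameter formula.
#' @slot pcfDensityConstant unitless density constant of the diameter
#'   formula (default 5 per micrometer of filament diameter).
#' @export
setClass("StrainGeometry",
  representation(
    strainLabel = "character",
    perFiberArea = "numeric",
    fixedPcfCount = "integerOrNULL",
    pcfDensityConstant = "numeric"
  )
)

setValidity("StrainGeometry", function(object) {
  msg <- character()
  if (length(object@perFiberArea) != 1L || !is.finite(object@perFiberArea) ||
      object@perFiberArea <= 0)
    msg <- c(msg, "perFiberArea must be a single positive number (nm^2)")
  if (!is.null(object@fixedPcfCount) &&
      (length(object@fixedPcfCount) != 1L || object@fixedPcfCount <= 0L))
    msg <- c(msg, "fixedPcfCount must be a positive integer when present")
  if (object@pcfDensityConstant <= 0)
    msg <- c(msg, "pcfDensityConstant must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname StrainGeometry-class
#' @param strainLabel,perFiberArea,fixedPcfCount,pcfDensityConstant see slots.
#' @export
StrainGeometry <- function(strainLabel, perFiberArea, fixedPcfCount = NULL,
                           pcfDensityConstant = 5) {
  new("StrainGeometry",
    strainLabel = as.character(strainLabel),
    perFiberArea = as.numeric(perFiberArea),
    fixedPcfCount = if (is.null(fixedPcfCount)) NULL else
      as.integer(fixedPcfCount),
    pcfDensityConstant = as.numeric(pcfDensityConstant)
  )
}

setMethod("show", "StrainGeometry", function(object) {
  cnt <- if (is.null(object@fixedPcfCount))
    sprintf("count = %g*pi*diameter", object@pcfDensityConstant)
  else sprintf("fixed count = %d", object@fixedPcfCount)
  cat(sprintf("StrainGeometry '%s': %g nm^2 per PCF, %s\n",
              object@strainLabel, object@perFiberArea, cnt))
})

#' AnalysisConfig: constants of the conductivity calculation
#'
#' @slot evalVoltage voltage at which the fitted current is taken (V,
#'   default 0.1, i.e. 100 mV).
#' @slot lodConductance detection limit of the probe setup in A/V
#'   (default 1e-12, i.e. 1 pA/V); sweeps with |slope| strictly below it are
#'   censored.
#' @export
setClass("AnalysisConfig",
  representation(evalVoltage = "numeric", lodConductance = "numeric")
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@evalVoltage <= 0) msg <- c(msg, "evalVoltage must be > 0")
  if (object@lodConductance <= 0) msg <- c(msg, "lodConductance must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname AnalysisConfig-class
#' @param evalVoltage,lodConductance see slots.
#' @export
AnalysisConfig <- function(evalVoltage = 0.1, lodConductance = 1e-12) {
  new("AnalysisConfig", evalVoltage = as.numeric(evalVoltage),
      lodConductance = as.numeric(lodConductance))
}

#' PCFShape: cross-sectional shape model of one periplasmic conductive fiber
#'
#' GS-type fibers have a rounded cross-section described by a diameter;
#' RB-type fibers are more rectangular and described by height and width.
#' Dimensions are in nanometers.
#'
#' @slot strainLabel character scalar.
#' @slot shapeKind \code{"circular"} or \code{"rectangular"}.
#' @slot dims named numeric: \code{diameter} for circular shapes,
#'   \code{height} and \code{width} for rectangular ones.
#' @examples
#' pcfArea(PCFShape("GS", "circular", diameter = 30.89))
#' pcfArea(PCFShape("RB", "rectangular", height = 25.95, width = 43.01))
#' @export
setClass("PCFShape",
  representation(strainLabel = "character", shapeKind = "character",
                 dims = "numeric")
)

setValidity("PCFShape", function(object) {
  kind <- object@shapeKind
  want <- switch(kind, circular = "diameter",
                 rectangular = c("height", "width"), NULL)
  if (is.null(want))
    return("shapeKind must be 'circular' or 'rectangular'")
  if (!setequal(names(object@dims), want))
    return(sprintf("a %s shape needs exactly the dimension(s): %s",
                   kind, paste(want, collapse = ", ")))
  if (any(!is.finite(object@dims)) || any(object@dims <= 0))
    return("all dimensions must be positive and finite (nm)")
  TRUE
})

#' @rdname PCFShape-class
#' @param strainLabel,shapeKind see slots.
#' @param diameter,height,width dimensions in nm; supply \code{diameter} for
#'   circular shapes, \code{height} and \code{width} for rectangular ones.
#' @export
PCFShape <- function(strainLabel, shapeKind = c("circular", "rectangular"),
                     diameter = NULL, height = NULL, width = NULL) {
  shapeKind <- match.arg(shapeKind)
  dims <- if (shapeKind == "circular") c(diameter = diameter)
  else c(height = height, width = width)
  new("PCFShape", strainLabel = as.character(strainLabel),
      shapeKind = shapeKind, dims = unlist(dims))
}

setMethod("show", "PCFShape", function(object) {
  cat(sprintf("PCFShape '%s' (%s): %s => area %.1f nm^2\n",
              object@strainLabel, object@shapeKind,
              paste(sprintf("%s=%g nm", names(object@dims), object@dims),
                    collapse = ", "),
              pcfArea(object)))
})

#' IsotopeReference: natural-abundance pattern of an element
#'
#' The listed isotopes need not sum to 100\% — only the listed subset is
#' ever used for normalisation (e.g. the three most abundant nickel
#' isotopes cover 97.94\%).
#'
#' @slot element character scalar, e.g. \code{"Ni"}.
#' @slot abundances named numeric, natural abundance percent per isotope
#'   label (e.g. \code{c("58Ni" = 68.08, ...)}).
#' @export
setClass("IsotopeReference",
  representation(element = "character", abundances = "numeric")
)

setValidity("IsotopeReference", function(object) {
  if (is.null(names(object@abundances)) || any(names(object@abundances) == ""))
    return("abundances must be a fully named numeric vector")
  if (any(object@abundances <= 0)) return("abundances must be > 0")
  TRUE
})

#' @rdname IsotopeReference-class
#' @param element,abundances see slots.
#' @export
IsotopeReference <- function(element, abundances) {
  new("IsotopeReference", element = as.character(element),
      abundances = abundances)
}

#' @describeIn IsotopeReference-class the nickel reference used for ToF-SIMS
#'   verification: the three most abundant isotopes at their natural
#'   abundances (58Ni 68.08\%, 60Ni 26.22\%, 62Ni 3.64\%).
#' @export
nickelReference <- function() {
  IsotopeReference("Ni",
    c("58Ni" = 68.08, "60Ni" = 26.22, "62Ni" = 3.64))
}

setMethod("show", "IsotopeReference", function(object) {
  cat(sprintf("IsotopeReference for %s: %s\n", object@element,
              paste(sprintf("%s %.2f%%", names(object@abundances),
                            object@abundances), collapse = ", ")))
})

#' ScoringScheme: protein local-alignment scoring parameters
#'
#' Affine-gap Smith-Waterman scoring. A gap of length L costs
#' \code{gapOpen + L * gapExtend}. In lenient mode (the default) the
#' ambiguity letter X scores 0 against every residue; in strict mode
#' sequences containing X are rejected.
#'
#' @slot matrixName substitution matrix name (\code{"BLOSUM62"},
#'   \code{"BLOSUM45"}, \code{"BLOSUM50"}, \code{"BLOSUM80"},
#'   \code{"BLOSUM100"}, \code{"PAM30"}, \code{"PAM40"}, \code{"PAM70"},
#'   \code{"PAM120"}, \code{"PAM250"}).
#' @slot gapOpen positive gap-opening penalty.
#' @slot gapExtend positive per-residue gap-extension penalty.
#' @slot lenient logical; see above.
#' @export
setClass("ScoringScheme",
  representation(matrixName = "character", gapOpen = "numeric",
                 gapExtend = "numeric", lenient = "logical")
)

setValidity("ScoringScheme", function(object) {
  if (object@gapOpen <= 0 || object@gapExtend <= 0)
    "gap penalties must be positive" else TRUE
})

#' @rdname ScoringScheme-class
#' @param matrixName,gapOpen,gapExtend,lenient see slots.
#' @export
ScoringScheme <- function(matrixName = "BLOSUM62", gapOpen = 11,
                          gapExtend = 1, lenient = TRUE) {
  new("ScoringScheme", matrixName = matrixName, gapOpen = as.numeric(gapOpen),
      gapExtend = as.numeric(gapExtend), lenient = lenient)
}

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme: %s, gap %g/%g, %s X handling\n",
              object@matrixName, object@gapOpen, object@gapExtend,
              if (object@lenient) "lenient" else "strict"))
})
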