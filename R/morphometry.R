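#' Cross-sectional area of one PCF
#'
#' Circular shapes (GS-type rounded fibers) give pi * (D/2)^2; rectangular
#' shapes (RB-type) give height * width. Dimensions in nm, area in nm^2.
#'
#' @param shape a \linkS4class{PCFShape}.
#' @return area in nm^2.
#' @examples
#' pcfArea(PCFShape("GS", "circular", diameter = 30.89))               # 749.4
#' pcfArea(PCFShape("RB", "rectangular", height = 25.95, width = 43.01))
#' @export
pcfArea <- function(shape) {
  switch(shape@shapeKind,
    circular = pi * (shape@dims[["diameter"]] / 2)^2,
    rectangular = shape@dims[["height"]] * shape@dims[["width"]]
  )
}

#' Percent difference between two single-PCF areas
#'
#' 100 * (area_b - area_a) / area_a, i.e. how much larger (positive) or
#' smaller (negative) shape \code{b} is relative to shape \code{a}. The
#' rounded value (nearest \code{step} percent, default 10, halves away from
#' zero) accompanies the unrounded one so "around 50\% bigger"-style
#' statements can be reproduced without losing the exact number. Note
#' percent difference is not antisymmetric: swapping a and b does not just
#' flip the sign.
#'
#' @param a,b \linkS4class{PCFShape}s (a is the reference).
#' @param step rounding step in percent.
#' @return list with \code{percent} (unrounded) and \code{rounded}.
#' @export
compareSinglePCFArea <- function(a, b, step = 10) {
  areaA <- pcfArea(a)
  areaB <- pcfArea(b)
  stopIf(areaA == 0, "zero reference area")
  p <- 100 * (areaB - areaA) / areaA
  list(percent = p, rounded = roundHalfAway(p / step) * step)
}

#' Percent difference between two total PCF cross-sections
#'
#' Total area = PCF count x per-fiber area for each filament; the
#' comparison is 100 * (total_b - total_a) / total_a, with the same
#' rounding convention as \code{\link{compareSinglePCFArea}}.
#'
#' @param countA,countB PCF counts (>= 1).
#' @param areaA,areaB per-fiber areas in nm^2.
#' @param step rounding step in percent.
#' @return list with \code{totalA}, \code{totalB}, \code{percent},
#'   \code{rounded}.
#' @examples
#' compareTotalPCFArea(34, 850, 15, 1100)$rounded  # -40
#' @export
compareTotalPCFArea <- function(countA, areaA, countB, areaB, step = 10) {
  stopIf(countA < 1 || countB < 1, "PCF counts must be >= 1")
  totalA <- countA * areaA
  totalB <- countB * areaB
  p <- 100 * (totalB - totalA) / totalA
  list(totalA = totalA, totalB = totalB,
       percent = p, rounded = roundHalfAway(p / step) * step)
}

#' Measured PCF shape presets from cross-sectional electron microscopy
#'
#' GS: circular, mean diameter 30.89 nm. RB: rectangular, mean height
#' 25.95 nm, mean width 43.01 nm. These are the "measured" per-fiber areas;
#' the conductivity model uses the distinct "model" presets 850 / 1100 nm^2
#' (see \code{\link{geometryPreset}}). Every comparison should state which
#' preset it used.
#'
#' @param strain \code{"GS"} or \code{"RB"}.
#' @return a \linkS4class{PCFShape}.
#' @export
shapePreset <- function(strain = c("GS", "RB")) {
  strain <- match.arg(strain)
  switch(strain,
    GS = PCFShape("GS", "circular", diameter = 30.89),
    RB = PCFShape("RB", "rectangular", height = 25.95, width = 43.01)
  )
}

#' Per-fiber area presets
#'
#' \code{"model"}: the areas assumed by the conductivity calculation
#' (GS-type 850 nm^2, RB 1100 nm^2). \code{"measured"}: areas computed from
#' the electron-microscopy shape presets (GS 749.4 nm^2, RB 1116.1 nm^2).
#'
#' @param strain \code{"GS"} or \code{"RB"}.
#' @param kind \code{"model"} or \code{"measured"}.
#' @return area in nm^2.
#' @export
pcfAreaPreset <- function(strain = c("GS", "RB"),
                          kind = c("model", "measured")) {
  strain <- match.arg(strain)
  kind <- match.arg(kind)
  if (kind == "model") {
    c(GS = 850, RB = 1100)[[strain]]
  } else {
    pcfArea(shapePreset(strain))
  }
}

#' Summary of vesicle observations
#'
#' Fraction of inner membrane-attached vesicles (IMAVs) among all vesicles,
#' and per-class diameter mean and sample standard deviation (n-1). A class
#' with a single observation reports an NA standard deviation.
#'
#' @param vesicles data.frame with numeric \code{diameter} (nm, > 0) and
#'   \code{attachment} in \code{c("IMAV", "CV")}.
#' @return list with \code{nTotal}, \code{nIMAV}, \code{nCV},
#'   \code{imavFraction}, and \code{byClass}, a data.frame of per-class n,
#'   mean and sd.
#' @examples
#' v <- data.frame(diameter = c(60, 70, 65),
#'                 attachment = c("IMAV", "IMAV", "CV"))
#' summarizeVesicles(v)$imavFraction  # 2/3
#' @export
summarizeVesicles <- function(vesicles) {
  stopIf(!is.data.frame(vesicles) || nrow(vesicles) == 0L,
         "empty vesicle table")
  stopIf(!all(c("diameter", "attachment") %in% names(vesicles)),
         "vesicle table needs 'diameter' and 'attachment' columns")
  stopIf(any(vesicles$diameter <= 0), "vesicle diameters must be > 0")
  att <- as.character(vesicles$attachment)
  bad <- setdiff(unique(att), c("IMAV", "CV"))
  stopIf(length(bad) > 0, "unknown attachment class(es): %s",
         paste(bad, collapse = ", "))
  byClass <- do.call(rbind, lapply(c("IMAV", "CV"), function(cl) {
    d <- vesicles$diameter[att == cl]
    data.frame(class = cl, n = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) >= 2L) stats::sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(nTotal = nrow(vesicles),
       nIMAV = sum(att == "IMAV"),
       nCV = sum(att == "CV"),
       imavFraction = sum(att == "IMAV") / nrow(vesicles),
       byClass = byClass)
}
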