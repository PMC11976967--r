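#' Relative atomic percentages from integrated K-alpha counts
#'
#' Cliff-Lorimer-style relative quantification: each element's integrated
#' K-alpha counts are weighted by a per-element sensitivity factor and
#' normalised to 100. Only ratios of factors matter; a global rescaling of
#' the factors leaves the result unchanged. Factors are acquisition
#' dependent (beam current, dwell, detector geometry), so they are supplied
#' per region or per batch, never defaulted globally.
#'
#' @param counts named non-negative numeric vector of integrated K-alpha
#'   counts, one entry per element (>= 2 elements, not all zero).
#' @param factors named positive numeric vector of sensitivity factors
#'   covering every element in \code{counts}.
#' @return named numeric vector of relative atomic percentages summing
#'   to 100.
#' @examples
#' relativeAtomicPercent(c(S = 100, Fe = 100, Ni = 100),
#'                       c(S = 1, Fe = 1, Ni = 1))
#' @export
relativeAtomicPercent <- function(counts, factors) {
  stopIf(is.null(names(counts)) || any(names(counts) == ""),
         "counts must be a fully named vector (element -> counts)")
  stopIf(any(counts < 0), "counts must be non-negative")
  stopIf(all(counts == 0), "all-zero counts: nothing to quantify")
  missing <- setdiff(names(counts), names(factors))
  stopIf(length(missing) > 0,
         "no sensitivity factor for element(s): %s",
         paste(missing, collapse = ", "))
  f <- factors[names(counts)]
  stopIf(any(f <= 0), "sensitivity factors must be positive")
  w <- counts * f
  100 * w / sum(w)
}

#' Fit sensitivity factors from a region with known composition
#'
#' The inverse of \code{\link{relativeAtomicPercent}}: given one region's
#' raw counts and its known relative atomic percentages, returns the
#' sensitivity factors (normalised so the first element's factor is 1) that
#' reproduce the known composition exactly. This lets a published
#' quantification row calibrate the count-to-percent step for its
#' acquisition batch.
#'
#' @param counts named positive numeric vector of integrated counts.
#' @param known named numeric vector of relative atomic percentages for the
#'   same elements.
#' @return named numeric vector of factors, first element = 1.
#' @examples
#' f <- fitSensitivityFactors(c(S = 1651, Fe = 5302, Ni = 40),
#'                            c(S = 13.0, Fe = 86.3, Ni = 0.7))
#' relativeAtomicPercent(c(S = 1651, Fe = 5302, Ni = 40), f)
#' @export
fitSensitivityFactors <- function(counts, known) {
  stopIf(is.null(names(counts)) || is.null(names(known)),
         "counts and known must be named vectors")
  stopIf(!setequal(names(counts), names(known)),
         "counts and known must cover the same elements")
  known <- known[names(counts)]
  stopIf(any(counts == 0 & known > 0),
         "zero counts with nonzero percent: factors are unsolvable")
  f <- ifelse(known == 0, 0, known / counts)
  stopIf(f[1L] == 0, "first element must have a nonzero percent")
  f / f[1L]
}

#' Elemental ratios from a composition
#'
#' @param percents named numeric vector of relative atomic percentages.
#' @param pairs character vector of ratios to form, each \code{"A:B"}
#'   meaning percent_A / percent_B. Default: the study's S:Fe, S:Ni, Fe:Ni
#'   panel.
#' @return named numeric vector; a zero denominator yields NA (undefined),
#'   not an error.
#' @examples
#' elementalRatios(c(S = 31.4, Fe = 64.9, Ni = 3.8))["S:Fe"]  # 0.48
#' @export
elementalRatios <- function(percents,
                            pairs = c("S:Fe", "S:Ni", "Fe:Ni")) {
  parts <- strsplit(pairs, ":", fixed = TRUE)
  bad <- pairs[vapply(parts, length, 1L) != 2L]
  stopIf(length(bad) > 0, "malformed pair(s): %s", paste(bad, collapse = ", "))
  vapply(parts, function(p) {
    stopIf(!all(p %in% names(percents)),
           "pair %s refers to element(s) absent from the composition",
           paste(p, collapse = ":"))
    den <- percents[[p[2L]]]
    if (den == 0) NA_real_ else percents[[p[1L]]] / den
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(pairs)
}

#' Outlier-excluded cohort summary of EDX compositions
#'
#' Per-element means and sample standard deviations (n-1) of the relative
#' atomic percentages over the non-excluded regions, plus ratio statistics.
#' Ratio averaging follows the published-table convention by default
#' (\code{"from_row_ratios"}): the mean of the per-region ratios. The
#' alternative \code{"from_percents"} forms each ratio from the mean
#' percentages instead. Outliers are excluded by explicit flag only; no
#' numeric criterion is applied.
#'
#' @param percents data.frame with a \code{section_id} column, one numeric
#'   column per element, and optionally a logical/0-1 \code{outlier} column.
#' @param ratios optional data.frame of per-region ratio columns (named
#'   \code{"A:B"}, check.names = FALSE), aligned row-by-row with
#'   \code{percents}. When absent and ratio statistics are requested, ratios
#'   are recomputed from the percent columns.
#' @param pairs character vector of \code{"A:B"} ratio names to summarise.
#' @param ratioMode \code{"from_row_ratios"} (default) or
#'   \code{"from_percents"}.
#' @return a list with \code{elementMean}, \code{elementSd},
#'   \code{ratioMean}, \code{ratioSd}, \code{includedIds},
#'   \code{excludedIds}, \code{n}.
#' @examples
#' gs <- data.frame(section_id = 1:3, S = c(13.0, 31.4, 30.3),
#'                  Fe = c(86.3, 64.9, 66.8), Ni = c(0.7, 3.8, 2.9))
#' summarizeCompositions(gs)$elementMean["S"]  # 24.9
#' @export
summarizeCompositions <- function(percents, ratios = NULL,
                                  pairs = c("S:Fe", "S:Ni", "Fe:Ni"),
                                  ratioMode = c("from_row_ratios",
                                                "from_percents")) {
  ratioMode <- match.arg(ratioMode)
  stopIf(!is.data.frame(percents) || nrow(percents) == 0L,
         "percents must be a non-empty data.frame")
  excl <- if ("outlier" %in% names(percents))
    as.logical(percents$outlier) else rep(FALSE, nrow(percents))
  ids <- if ("section_id" %in% names(percents))
    as.character(percents$section_id) else as.character(seq_len(nrow(percents)))
  stopIf(all(excl), "all regions flagged as outliers: nothing to average")
  elements <- setdiff(names(percents), c("section_id", "strain", "outlier"))
  stopIf(length(elements) == 0L, "no element columns found")
  kept <- percents[!excl, elements, drop = FALSE]
  stopIf(nrow(kept) < 2L,
         "need >= 2 non-excluded regions for a standard deviation")

  if (is.null(ratios)) {
    ratios <- as.data.frame(
      t(apply(percents[, elements, drop = FALSE], 1L, function(row)
        elementalRatios(stats::setNames(as.numeric(row), elements), pairs))),
      check.names = FALSE)
  } else {
    stopIf(nrow(ratios) != nrow(percents),
           "ratios must align row-by-row with percents")
    stopIf(!all(pairs %in% names(ratios)),
           "ratios table lacks column(s): %s",
           paste(setdiff(pairs, names(ratios)), collapse = ", "))
  }
  keptRatios <- ratios[!excl, pairs, drop = FALSE]

  ratioMean <- if (ratioMode == "from_row_ratios")
    vapply(keptRatios, mean, numeric(1))
  else
    elementalRatios(vapply(kept, mean, numeric(1)), pairs)
  list(
    elementMean = vapply(kept, mean, numeric(1)),
    elementSd = vapply(kept, stats::sd, numeric(1)),
    ratioMean = ratioMean,
    ratioSd = vapply(keptRatios, stats::sd, numeric(1)),
    includedIds = ids[!excl],
    excludedIds = ids[excl],
    n = nrow(kept)
  )
}
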