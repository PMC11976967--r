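#' Relative isotope counts over a named subset
#'
#' The relative count of an isotope is its absolute count divided by the
#' summed counts of the named subset (for nickel: the three most abundant
#' isotopes 58Ni, 60Ni, 62Ni). The subset is explicit and ordered because
#' ToF-SIMS spectra contain interfering peaks; "all isotopes present" is
#' never assumed.
#'
#' @param counts named non-negative numeric vector of isotope counts.
#' @param isotopes character vector naming the subset to normalise over
#'   (default: all names of \code{counts}, in order).
#' @return named numeric fractions over \code{isotopes}, summing to 1.
#' @examples
#' relativeIsotopeCounts(c("58Ni" = 580, "60Ni" = 260, "62Ni" = 160))
#' @export
relativeIsotopeCounts <- function(counts, isotopes = names(counts)) {
  stopIf(is.null(names(counts)) || any(names(counts) == ""),
         "counts must be a fully named vector (isotope -> count)")
  missing <- setdiff(isotopes, names(counts))
  stopIf(length(missing) > 0, "isotope(s) absent from counts: %s",
         paste(missing, collapse = ", "))
  x <- counts[isotopes]
  stopIf(any(x < 0), "counts must be non-negative")
  stopIf(sum(x) == 0, "summed count over the subset is zero")
  x / sum(x)
}

#' Expected isotope fractions from natural abundances
#'
#' @param ref an \linkS4class{IsotopeReference}.
#' @param isotopes character vector naming the (non-empty) subset; default
#'   all isotopes of the reference, in order.
#' @return named numeric fractions summing to 1.
#' @examples
#' expectedFractions(nickelReference())["58Ni"]  # 68.08 / 97.94 = 0.6951
#' @export
expectedFractions <- function(ref, isotopes = names(ref@abundances)) {
  stopIf(length(isotopes) == 0L, "isotope subset must be non-empty")
  unknown <- setdiff(isotopes, names(ref@abundances))
  stopIf(length(unknown) > 0, "unknown isotope(s) for %s: %s",
         ref@element, paste(unknown, collapse = ", "))
  a <- ref@abundances[isotopes]
  a / sum(a)
}

#' Chi-square goodness of fit of an isotope pattern
#'
#' Pearson chi-square of the observed counts against the expected counts
#' (total times the expected fractions from natural abundances), with
#' k - 1 degrees of freedom. This formalises the visual observed-vs-expected
#' bar comparison; no p-value threshold is applied — the headline output of
#' the isotope stage is the fraction table, the statistic is auxiliary.
#'
#' @param counts named non-negative numeric vector of observed counts.
#' @param ref an \linkS4class{IsotopeReference}.
#' @param isotopes character vector naming the subset to test.
#' @return a list with \code{chiSquare}, \code{dof}, \code{pValue},
#'   \code{observed}, \code{expected} (both count vectors), and a
#'   \code{note} warning when any expected cell is below 5 (asymptotic
#'   statistic unreliable).
#' @export
isotopeGof <- function(counts, ref = nickelReference(),
                       isotopes = names(ref@abundances)) {
  obs <- counts[isotopes]
  stopIf(any(is.na(obs)), "isotope(s) absent from counts: %s",
         paste(isotopes[is.na(obs)], collapse = ", "))
  total <- sum(obs)
  stopIf(total == 0, "zero total count")
  expd <- total * expectedFractions(ref, isotopes)
  note <- ""
  if (any(expd < 5)) {
    note <- "expected count < 5 in some cell; asymptotic chi-square unreliable"
    warning(note, call. = FALSE)
  }
  chi2 <- sum((obs - expd)^2 / expd)
  dof <- length(isotopes) - 1L
  list(chiSquare = chi2, dof = dof,
       pValue = stats::pchisq(chi2, dof, lower.tail = FALSE),
       observed = obs, expected = expd, note = note)
}

#' Observed-versus-expected isotope fraction table
#'
#' @param counts named numeric vector of observed counts.
#' @param ref an \linkS4class{IsotopeReference}.
#' @param isotopes subset to normalise over.
#' @return data.frame with columns \code{isotope}, \code{count},
#'   \code{observedFraction}, \code{expectedFraction}.
#' @export
isotopeFractionTable <- function(counts, ref = nickelReference(),
                                 isotopes = names(ref@abundances)) {
  obs <- relativeIsotopeCounts(counts, isotopes)
  expd <- expectedFractions(ref, isotopes)
  data.frame(isotope = isotopes,
             count = as.numeric(counts[isotopes]),
             observedFraction = as.numeric(obs),
             expectedFraction = as.numeric(expd),
             stringsAsFactors = FALSE)
}
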