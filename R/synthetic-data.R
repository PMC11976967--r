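# Seeded generators emulating the statistical structure of each pipeline
# stage's inputs. All are pure functions of their arguments: the RNG is
# seeded locally (Mersenne-Twister via set.seed) and global RNG state is
# restored on exit, so the same call is byte-identical every time.

#' Simulate two-probe I/V sweeps
#'
#' Generates 21-point voltage scans over -1..1 V whose underlying
#' conductance realises \code{trueSigma} given the strain geometry and a
#' gap length drawn uniformly from 100-800 micrometers, with Gaussian
#' relative current noise per point. A \code{lodFraction} of the sweeps is
#' generated below the detection limit, at one tenth of the LOD conductance
#' (not at zero, so the censoring boundary is exercised).
#'
#' @param n number of sweeps.
#' @param trueSigma true conductivity in S/cm (>= 0).
#' @param noiseFraction relative (fractional) standard deviation of the
#'   per-point current noise, in [0, 1].
#' @param lodFraction fraction of sweeps generated below the detection
#'   limit, in [0, 1].
#' @param geometry a \linkS4class{StrainGeometry}; its fixed PCF count (or
#'   the diameter formula with \code{diameter}) sets the cross-section.
#' @param config an \linkS4class{AnalysisConfig} (supplies the LOD).
#' @param seed integer seed.
#' @param diameter filament diameter in micrometers when the geometry has
#'   no fixed count.
#' @param nPoints points per sweep.
#' @return list of \linkS4class{IVSweep}s with a \code{"truth"} attribute:
#'   data.frame of \code{sampleId}, \code{trueSigma}, \code{gap_um},
#'   \code{censored}.
#' @examples
#' sweeps <- simIVSweeps(5, trueSigma = 4, noiseFraction = 0, seed = 1)
#' analyzeSweep(sweeps[[1]], geometryPreset("GS"))$sigmaSPerCm  # 4
#' @export
simIVSweeps <- function(n, trueSigma = 4.0, noiseFraction = 0.05,
                        lodFraction = 0, geometry = geometryPreset("GS"),
                        config = AnalysisConfig(), seed = 1,
                        diameter = NULL, nPoints = 21L) {
  stopIf(trueSigma < 0, "trueSigma must be >= 0")
  stopIf(noiseFraction < 0 || noiseFraction > 1,
         "noiseFraction must be in [0, 1]")
  stopIf(lodFraction < 0 || lodFraction > 1,
         "lodFraction must be in [0, 1]")
  area <- totalPCFArea(resolvePcfCount(geometry, diameter), geometry)
  withLocalSeed(seed, {
    gaps <- stats::runif(n, 100, 800)
    nCens <- roundHalfAway(lodFraction * n)
    censored <- seq_len(n) %in% sample.int(n, nCens)
    volts <- seq(-1, 1, length.out = nPoints)
    sweeps <- vector("list", n)
    for (i in seq_len(n)) {
      g <- if (censored[i]) 0.1 * config@lodConductance
      else trueSigma * area / (gaps[i] * .SIGMA_SCM_PER_SLOPE_UM_NM2)
      ideal <- g * volts
      curr <- ideal * (1 + stats::rnorm(nPoints, 0, noiseFraction))
      sweeps[[i]] <- IVSweep(sprintf("sim%03d", i), geometry@strainLabel,
                             volts, curr, gaps[i])
    }
    attr(sweeps, "truth") <- data.frame(
      sampleId = sprintf("sim%03d", seq_len(n)),
      trueSigma = ifelse(censored, NA_real_, trueSigma),
      gap_um = gaps, censored = censored, stringsAsFactors = FALSE)
    sweeps
  })
}

#' Simulate STEM-EDX region count tables
#'
#' Per-region integrated K-alpha counts drawn as
#' counts_i ~ Poisson(totalCounts * w_i) with weights w_i proportional to
#' percent_i / f_i (the inverse of the sensitivity-factor quantification),
#' so \code{\link{relativeAtomicPercent}} with the same factors recovers
#' the planted composition in expectation. \code{mode = "expected"} skips
#' the Poisson draw and returns the expected counts, for exact round-trip
#' checks.
#'
#' @param nRegions number of regions.
#' @param composition named vector of true relative atomic percentages
#'   (must sum to 100 within 1e-6).
#' @param totalCounts expected total counts per region.
#' @param factors named positive sensitivity factors.
#' @param mode \code{"poisson"} or \code{"expected"}.
#' @param seed integer seed.
#' @return data.frame with \code{section_id} and one count column per
#'   element, plus attributes \code{"truth"} (the composition) and
#'   \code{"factors"}.
#' @export
simEDXCounts <- function(nRegions, composition = c(S = 24.9, Fe = 72.7,
                                                   Ni = 2.4),
                         totalCounts = 1e4,
                         factors = c(S = 1, Fe = 1, Ni = 1),
                         mode = c("poisson", "expected"), seed = 1) {
  mode <- match.arg(mode)
  stopIf(any(composition < 0), "composition must be non-negative")
  stopIf(abs(sum(composition) - 100) > 1e-6,
         "composition must sum to 100 (relative atomic percent)")
  stopIf(!setequal(names(composition), names(factors)),
         "composition and factors must cover the same elements")
  f <- factors[names(composition)]
  stopIf(any(f <= 0), "factors must be positive")
  w <- (composition / f) / sum(composition / f)
  lam <- totalCounts * w
  draw <- function() {
    if (mode == "expected") lam else
      stats::setNames(stats::rpois(length(lam), lam), names(lam))
  }
  counts <- withLocalSeed(seed, t(replicate(nRegions, draw())))
  out <- data.frame(section_id = sprintf("region%03d", seq_len(nRegions)),
                    counts, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "truth") <- composition
  attr(out, "factors") <- f
  out
}

#' Simulate a ToF-SIMS isotope count pattern
#'
#' A multinomial draw of \code{totalCounts} over the reference subset at
#' its natural-abundance fractions, or the exact expected counts with
#' \code{mode = "expected"}.
#'
#' @param totalCounts total counts over the subset (> 0).
#' @param ref an \linkS4class{IsotopeReference}.
#' @param isotopes subset to draw over (default all reference isotopes).
#' @param mode \code{"multinomial"} or \code{"expected"}.
#' @param seed integer seed.
#' @return named numeric count vector.
#' @examples
#' simIsotopeCounts(97940, mode = "expected")  # 68080 26220 3640
#' @export
simIsotopeCounts <- function(totalCounts, ref = nickelReference(),
                             isotopes = names(ref@abundances),
                             mode = c("multinomial", "expected"), seed = 1) {
  mode <- match.arg(mode)
  stopIf(totalCounts <= 0, "totalCounts must be > 0")
  p <- expectedFractions(ref, isotopes)
  if (mode == "expected") return(totalCounts * p)
  withLocalSeed(seed,
    stats::setNames(as.numeric(stats::rmultinom(1, totalCounts, p)),
                    isotopes))
}

.AA19_NOC <- setdiff(.AA20, "C")

# random sequence without cysteine: planted CXXCH motifs stay the only ones
.randSeqNoC <- function(len) paste(sample(.AA19_NOC, len, TRUE),
                                   collapse = "")

.plantMotifs <- function(len, k, nInternal = 2L) {
  motifLen <- nInternal + 3L
  stopIf(len < k * (motifLen + 2L),
         "sequence of length %d cannot hold %d motifs", len, k)
  seq <- strsplit(.randSeqNoC(len), "")[[1]]
  starts <- integer(0)
  if (k > 0L) {
    # one motif per equal-width block, at a random in-block offset
    block <- len %/% k
    starts <- vapply(seq_len(k) - 1L, function(b) {
      b * block + sample.int(block - motifLen + 1L, 1L)
    }, integer(1))
    for (s in starts) {
      seq[s] <- "C"
      seq[s + seq_len(nInternal)] <- sample(.AA19_NOC, nInternal, TRUE)
      seq[s + nInternal + 1L] <- "C"
      seq[s + nInternal + 2L] <- "H"
    }
  }
  masked <- unlist(lapply(starts, function(s) s + 0:(motifLen - 1L)))
  list(seq = seq, masked = masked)
}

.mutateSeq <- function(seqChars, rate, masked) {
  hit <- which(stats::runif(length(seqChars)) < rate)
  hit <- setdiff(hit, masked)
  for (i in hit) {
    seqChars[i] <- sample(setdiff(.AA19_NOC, seqChars[i]), 1L)
  }
  seqChars
}

#' Simulate a pair of proteomes with planted conserved cytochromes
#'
#' Proteome A holds \code{nHomologs} planted proteins (a declared subset
#' carrying exact CXXCH motif counts per \code{hemeCounts}) plus
#' \code{nDecoys} unrelated random proteins; proteome B holds point-mutated
#' copies of the planted proteins (motif positions are masked from
#' mutation, so planted motifs are never destroyed) plus its own
#' independent decoys. Planted-protein backgrounds are cysteine-free
#' outside the motifs, so the planted heme counts are exact by
#' construction; decoys use the full alphabet. The truth table lists each
#' planted pair with its heme count, length and cytochrome class.
#'
#' @param nHomologs number of planted homolog pairs.
#' @param nDecoys number of unrelated decoys per proteome.
#' @param mutationRate per-residue point-mutation probability for the B
#'   copies, in [0, 0.3].
#' @param hemeCounts integer vector (length \code{nHomologs}) of planted
#'   CXXCH counts; the default panel covers pentaheme sPHC and lPHC cases,
#'   mono-, di-, tri- and tetraheme cytochromes and two motif-free
#'   homologs.
#' @param lengths integer vector of planted protein lengths.
#' @param decoyLengthRange decoy length range (uniform integer draw).
#' @param sphcMaxLength length threshold for the sPHC/lPHC split recorded
#'   in the truth table.
#' @param seed integer seed.
#' @return list with \code{proteomeA}, \code{proteomeB} (named character
#'   vectors) and \code{truth} (data.frame \code{id_a}, \code{id_b},
#'   \code{heme_count}, \code{length}, \code{class}).
#' @examples
#' pp <- simProteomePair(seed = 42)
#' names(pp$proteomeA)[1:3]
#' @export
simProteomePair <- function(nHomologs = 8L, nDecoys = 12L,
                            mutationRate = 0.10,
                            hemeCounts = c(5L, 5L, 1L, 2L, 4L, 3L, 0L, 0L),
                            lengths = c(180L, 600L, 150L, 300L, 350L,
                                        400L, 250L, 320L),
                            decoyLengthRange = c(150L, 400L),
                            sphcMaxLength = 250L, seed = 42) {
  stopIf(mutationRate < 0 || mutationRate > 0.3,
         "mutationRate must be in [0, 0.3]")
  stopIf(length(hemeCounts) != nHomologs || length(lengths) != nHomologs,
         "hemeCounts and lengths must each have one entry per homolog")
  withLocalSeed(seed, {
    protA <- character(0)
    protB <- character(0)
    truth <- vector("list", nHomologs)
    for (i in seq_len(nHomologs)) {
      pl <- .plantMotifs(lengths[i], hemeCounts[i])
      idA <- sprintf("A_hom%02d", i)
      idB <- sprintf("B_hom%02d", i)
      protA[idA] <- paste(pl$seq, collapse = "")
      protB[idB] <- paste(.mutateSeq(pl$seq, mutationRate, pl$masked),
                          collapse = "")
      truth[[i]] <- data.frame(
        id_a = idA, id_b = idB, heme_count = hemeCounts[i],
        length = lengths[i],
        class = classifyCytochrome(hemeCounts[i], lengths[i],
                                   sphcMaxLength),
        stringsAsFactors = FALSE)
    }
    decoy <- function(prefix) {
      lens <- sample(decoyLengthRange[1]:decoyLengthRange[2], nDecoys,
                     replace = TRUE)
      stats::setNames(
        vapply(lens, function(L) paste(sample(.AA20, L, TRUE),
                                       collapse = ""), character(1)),
        sprintf("%s_dec%02d", prefix, seq_len(nDecoys)))
    }
    protA <- c(protA, decoy("A"))
    protB <- c(protB, decoy("B"))
    list(proteomeA = protA, proteomeB = protB,
         truth = do.call(rbind, truth))
  })
}

#' Simulate vesicle observations
#'
#' Attachment class is Bernoulli(\code{imavFraction}) (IMAV vs CV);
#' diameters are Normal(\code{meanDiameter}, \code{sdDiameter}) truncated
#' at zero by resampling. Defaults emulate the GS observations: mean
#' diameter 65.5 +/- 4.6 nm with IMAVs making up the large majority
#' (more than 85 percent) of vesicles.
#'
#' @param n number of vesicles.
#' @param imavFraction probability a vesicle is an IMAV, in [0, 1].
#' @param meanDiameter,sdDiameter Normal parameters in nm.
#' @param seed integer seed.
#' @return data.frame with \code{diameter}, \code{attachment}.
#' @export
simVesicles <- function(n, imavFraction = 0.9, meanDiameter = 65.5,
                        sdDiameter = 4.6, seed = 1) {
  stopIf(imavFraction < 0 || imavFraction > 1,
         "imavFraction must be in [0, 1]")
  stopIf(sdDiameter < 0 || meanDiameter <= 0, "invalid diameter parameters")
  withLocalSeed(seed, {
    att <- ifelse(stats::runif(n) < imavFraction, "IMAV", "CV")
    d <- stats::rnorm(n, meanDiameter, sdDiameter)
    while (any(d <= 0))
      d[d <= 0] <- stats::rnorm(sum(d <= 0), meanDiameter, sdDiameter)
    data.frame(diameter = d, attachment = att, stringsAsFactors = FALSE)
  })
}
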