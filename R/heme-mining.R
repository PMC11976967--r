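.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# validate and uppercase a protein sequence; X tolerated (ambiguity), never
# matching the C/H positions of the heme motif
.checkProteinSeq <- function(seq, id = "<sequence>") {
  stopIf(length(seq) != 1L || is.na(seq) || nchar(seq) == 0L,
         "empty protein sequence for '%s'", id)
  seq <- toupper(seq)
  letters <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(letters, c(.AA20, "X"))
  stopIf(length(bad) > 0,
         "sequence '%s' contains non-amino-acid letter(s): %s",
         id, paste(bad, collapse = ", "))
  seq
}

#' Scan a protein for CXXCH heme c-binding motifs
#'
#' Left-to-right scan for the canonical heme c covalent attachment motif:
#' cysteine, \code{nInternal} arbitrary residues, cysteine, histidine
#' (default \code{nInternal = 2}, i.e. C-x-x-C-H). Under the default
#' \code{"non_overlapping"} policy, scanning resumes after the last residue
#' of each match; \code{"all"} reports every matching window. The ambiguity
#' letter X never matches the C or H positions (it may occupy a wildcard
#' position).
#'
#' @param sequence protein sequence (single character string, 20 standard
#'   letters plus X; lowercase accepted).
#' @param proteinId identifier carried into the annotation.
#' @param nInternal number of wildcard residues between the cysteines
#'   (>= 1; variants like CX3CH are available for sensitivity analysis but
#'   the default is the canonical motif).
#' @param overlap \code{"non_overlapping"} (default) or \code{"all"}.
#' @return list with \code{proteinId}, \code{motifStarts} (0-based),
#'   \code{hemeCount}, \code{length}.
#' @examples
#' scanHemeMotifs("CAACH")$hemeCount                      # 1
#' scanHemeMotifs("CAACHACH", overlap = "all")$motifStarts  # 0 3
#' @export
scanHemeMotifs <- function(sequence, proteinId = "protein", nInternal = 2L,
                           overlap = c("non_overlapping", "all")) {
  overlap <- match.arg(overlap)
  stopIf(nInternal < 1L, "nInternal must be >= 1")
  sequence <- .checkProteinSeq(sequence, proteinId)
  core <- sprintf("C.{%d}CH", as.integer(nInternal))
  pattern <- if (overlap == "all") sprintf("(?=%s)", core) else core
  m <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
  starts <- if (m[1L] == -1L) integer() else as.integer(m) - 1L
  list(proteinId = proteinId, motifStarts = starts,
       hemeCount = length(starts), length = nchar(sequence))
}

#' Classify a cytochrome from its heme count and length
#'
#' 0 hemes: \code{"none"}; 1: \code{"monoheme"}; exactly 5: pentaheme,
#' split into the small (\code{"pentaheme_sPHC"}, length <= threshold) and
#' large (\code{"pentaheme_lPHC"}) variants of the cable-bacteria pentaheme
#' cytochrome family; any other count >= 2: \code{"multiheme"}. The sPHC
#' threshold defaults to 250 residues; the small/large split in the source
#' material is by predicted domain size without a printed cutoff, so the
#' default is a documented, configurable choice.
#'
#' @param hemeCount number of CXXCH motifs.
#' @param seqLength protein length in residues.
#' @param sphcMaxLength largest length still classified sPHC.
#' @return character class label.
#' @export
classifyCytochrome <- function(hemeCount, seqLength, sphcMaxLength = 250L) {
  stopIf(sphcMaxLength < 0, "sphcMaxLength must be non-negative")
  stopIf(hemeCount < 0, "hemeCount must be non-negative")
  if (hemeCount == 0L) return("none")
  if (hemeCount == 1L) return("monoheme")
  if (hemeCount == 5L) {
    return(if (seqLength <= sphcMaxLength) "pentaheme_sPHC"
           else "pentaheme_lPHC")
  }
  "multiheme"
}

#' Annotate every protein of a proteome with heme motifs
#'
#' @param proteome named character vector of sequences, or a
#'   \code{Biostrings::AAStringSet}.
#' @param nInternal,overlap see \code{\link{scanHemeMotifs}}.
#' @param sphcMaxLength see \code{\link{classifyCytochrome}}.
#' @return data.frame with \code{protein_id}, \code{length},
#'   \code{n_hemes}, \code{motif_starts} (comma-joined, 0-based),
#'   \code{class}.
#' @export
annotateProteome <- function(proteome, nInternal = 2L,
                             overlap = c("non_overlapping", "all"),
                             sphcMaxLength = 250L) {
  overlap <- match.arg(overlap)
  seqs <- .asNamedSeqs(proteome)
  rows <- lapply(names(seqs), function(id) {
    ann <- scanHemeMotifs(seqs[[id]], id, nInternal, overlap)
    data.frame(protein_id = id, length = ann$length,
               n_hemes = ann$hemeCount,
               motif_starts = paste(ann$motifStarts, collapse = ","),
               class = classifyCytochrome(ann$hemeCount, ann$length,
                                          sphcMaxLength),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(protein_id = character(), length = integer(),
                      n_hemes = integer(), motif_starts = character(),
                      class = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# coerce AAStringSet / character to a named character vector with unique ids
.asNamedSeqs <- function(proteome) {
  if (methods::is(proteome, "XStringSet"))
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  stopIf(length(proteome) > 0 &&
           (is.null(names(proteome)) || any(names(proteome) == "")),
         "proteome sequences must be named with protein ids")
  dup <- names(proteome)[duplicated(names(proteome))]
  stopIf(length(dup) > 0, "duplicate protein id(s): %s",
         paste(unique(dup), collapse = ", "))
  vapply(seq_along(proteome),
         function(i) .checkProteinSeq(proteome[[i]], names(proteome)[i]),
         character(1)) |> stats::setNames(names(proteome))
}

# substitution matrix for a scheme; lenient mode scores X as 0 vs everything
.schemeMatrix <- function(scheme) {
  env <- new.env()
  utils::data(list = scheme@matrixName, package = "Biostrings", envir = env)
  mat <- get(scheme@matrixName, envir = env)
  if (scheme@lenient && "X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two protein sequences under an affine
#' gap model (a gap of length L costs \code{gapOpen + L * gapExtend}),
#' computed with \code{Biostrings::pairwiseAlignment}. Scores are floored
#' at 0 (the empty local alignment). Symmetric in its arguments for the
#' symmetric substitution matrices used here.
#'
#' @param a,b protein sequences (character strings).
#' @param scheme a \linkS4class{ScoringScheme}; in strict mode sequences
#'   containing X are rejected, in lenient mode (default) X scores 0
#'   against everything.
#' @return numeric score >= 0.
#' @examples
#' localAlign("HEAGAWGHEE", "HEAGAWGHEE")
#' @export
localAlign <- function(a, b, scheme = ScoringScheme()) {
  a <- .checkProteinSeq(a, "a")
  b <- .checkProteinSeq(b, "b")
  if (!scheme@lenient)
    stopIf(grepl("X", a, fixed = TRUE) || grepl("X", b, fixed = TRUE),
           "sequences contain X and the scoring scheme is strict")
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = .schemeMatrix(scheme),
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend,
    scoreOnly = TRUE)
  max(0, s)
}

# full local-alignment score matrix (rows = proteome A, cols = proteome B)
.scoreMatrix <- function(seqsA, seqsB, scheme) {
  mat <- .schemeMatrix(scheme)
  setA <- Biostrings::AAStringSet(seqsA)
  out <- matrix(0, nrow = length(seqsA), ncol = length(seqsB),
                dimnames = list(names(seqsA), names(seqsB)))
  for (j in seq_along(seqsB)) {
    s <- Biostrings::pairwiseAlignment(
      setA, Biostrings::AAString(seqsB[[j]]), type = "local",
      substitutionMatrix = mat, gapOpening = scheme@gapOpen,
      gapExtension = scheme@gapExtend, scoreOnly = TRUE)
    out[, j] <- pmax(0, s)
  }
  out
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (x in A, y in B) is a reciprocal best hit when y is x's unique
#' top-scoring match in B, x is y's unique top-scoring match in A, and both
#' scores reach \code{minScore}. Ties for the top score are broken by
#' lexicographic protein id and flagged rather than silently dropped. The
#' default threshold (raw Smith-Waterman score 50 under BLOSUM62, gap 11/1)
#' is set so unrelated random sequences of typical protein length
#' essentially never pass.
#'
#' @param proteomeA,proteomeB named character vectors of sequences or
#'   \code{Biostrings::AAStringSet}s with unique ids.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param minScore minimum alignment score for a hit to count.
#' @return data.frame with one row per best-hit pair considered:
#'   \code{id_a}, \code{id_b}, \code{score_ab}, \code{score_ba},
#'   \code{tie_a}, \code{tie_b}, \code{reciprocal}. Rows with
#'   \code{reciprocal == TRUE} are the conservation calls.
#' @export
reciprocalBestHits <- function(proteomeA, proteomeB,
                               scheme = ScoringScheme(), minScore = 50) {
  seqsA <- .asNamedSeqs(proteomeA)
  seqsB <- .asNamedSeqs(proteomeB)
  empty <- data.frame(id_a = character(), id_b = character(),
                      score_ab = numeric(), score_ba = numeric(),
                      tie_a = logical(), tie_b = logical(),
                      reciprocal = logical(), stringsAsFactors = FALSE)
  if (length(seqsA) == 0L || length(seqsB) == 0L) return(empty)
  sc <- .scoreMatrix(seqsA, seqsB, scheme)

  bestOf <- function(scores) { # -> list(id, tie) over a named score vector
    top <- max(scores)
    cand <- sort(names(scores)[scores == top])
    list(id = cand[1L], tie = length(cand) > 1L)
  }
  rowOf <- function(ida) stats::setNames(sc[ida, ], colnames(sc))
  colOf <- function(idb) stats::setNames(sc[, idb], rownames(sc))
  bestB <- lapply(rownames(sc), function(ida) bestOf(rowOf(ida)))
  names(bestB) <- rownames(sc)
  bestA <- lapply(colnames(sc), function(idb) bestOf(colOf(idb)))
  names(bestA) <- colnames(sc)

  rows <- lapply(rownames(sc), function(ida) {
    idb <- bestB[[ida]]$id
    back <- bestA[[idb]]
    sAB <- sc[ida, idb]
    recip <- identical(back$id, ida) && !bestB[[ida]]$tie && !back$tie &&
      sAB >= minScore
    data.frame(id_a = ida, id_b = idb, score_ab = sAB, score_ba = sAB,
               tie_a = bestB[[ida]]$tie, tie_b = back$tie,
               reciprocal = recip, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Census of conserved c-type cytochromes between two proteomes
#'
#' Combines the reciprocal-best-hit conservation calls with the heme-motif
#' annotation: the census lists reciprocal pairs in which both members
#' carry at least one CXXCH motif, with per-member heme counts and
#' cytochrome classes, and tallies conserved multiheme (both >= 2 hemes)
#' and pentaheme (both exactly 5) families. Pairs with a motif on one side
#' only are reported separately as discordant. An optional localization
#' table restricts the census to proteins whose label is in
#' \code{keepLabels} on both sides (localization prediction itself is out
#' of scope; labels come from external tools).
#'
#' @param proteomeA,proteomeB named character vectors or
#'   \code{Biostrings::AAStringSet}s.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param minScore reciprocal-best-hit score threshold.
#' @param nInternal,overlap motif parameters, see
#'   \code{\link{scanHemeMotifs}}.
#' @param sphcMaxLength see \code{\link{classifyCytochrome}}.
#' @param localization optional data.frame with \code{protein_id} and
#'   \code{label} covering proteins of either proteome.
#' @param keepLabels labels retained when \code{localization} is given.
#' @return list with \code{census} (data.frame: \code{id_a}, \code{id_b},
#'   \code{score_ab}, \code{hemes_a}, \code{hemes_b}, \code{class_a},
#'   \code{class_b}), \code{discordant} (same shape), \code{pairs} (all
#'   reciprocal pairs), \code{annotationA}, \code{annotationB}, and
#'   \code{counts} (list: \code{nConserved}, \code{nMultiheme},
#'   \code{nPentaheme}).
#' @export
conservedCytochromeCensus <- function(proteomeA, proteomeB,
                                      scheme = ScoringScheme(),
                                      minScore = 50, nInternal = 2L,
                                      overlap = "non_overlapping",
                                      sphcMaxLength = 250L,
                                      localization = NULL,
                                      keepLabels = NULL) {
  annA <- annotateProteome(proteomeA, nInternal, overlap, sphcMaxLength)
  annB <- annotateProteome(proteomeB, nInternal, overlap, sphcMaxLength)
  rbh <- reciprocalBestHits(proteomeA, proteomeB, scheme, minScore)
  recip <- rbh[rbh$reciprocal, , drop = FALSE]

  hemesA <- stats::setNames(annA$n_hemes, annA$protein_id)
  hemesB <- stats::setNames(annB$n_hemes, annB$protein_id)
  classA <- stats::setNames(annA$class, annA$protein_id)
  classB <- stats::setNames(annB$class, annB$protein_id)

  tab <- data.frame(
    id_a = recip$id_a, id_b = recip$id_b, score_ab = recip$score_ab,
    hemes_a = as.integer(hemesA[recip$id_a]),
    hemes_b = as.integer(hemesB[recip$id_b]),
    class_a = as.character(classA[recip$id_a]),
    class_b = as.character(classB[recip$id_b]),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  census <- tab[tab$hemes_a >= 1L & tab$hemes_b >= 1L, , drop = FALSE]
  discordant <- tab[xor(tab$hemes_a >= 1L, tab$hemes_b >= 1L), ,
                    drop = FALSE]

  if (!is.null(localization)) {
    stopIf(is.null(keepLabels),
           "keepLabels must be given alongside a localization table")
    lab <- stats::setNames(as.character(localization$label),
                           as.character(localization$protein_id))
    keep <- lab[census$id_a] %in% keepLabels &
      lab[census$id_b] %in% keepLabels
    keep[is.na(keep)] <- FALSE
    census <- census[keep, , drop = FALSE]
  }

  list(census = census, discordant = discordant, pairs = rbh,
       annotationA = annA, annotationB = annB,
       counts = list(
         nConserved = nrow(census),
         nMultiheme = sum(census$hemes_a >= 2L & census$hemes_b >= 2L),
         nPentaheme = sum(census$hemes_a == 5L & census$hemes_b == 5L)))
}
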