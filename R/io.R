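# Delimited-text readers/writers for the pipeline's table dialects, plus
# FASTA via Biostrings. All tables are UTF-8, period decimal separator;
# "17,681"-style thousands separators are parsed leniently on input and
# never emitted.

# autodetect comma vs tab from the header line
.readDelimited <- function(path) {
  stopIf(!file.exists(path), "file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

.requireColumns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  stopIf(length(missing) > 0, "%s: missing required column(s): %s",
         path, paste(missing, collapse = ", "))
}

# lenient numeric parse: strips thousands separators, errors with row number
.parseNumeric <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  bad <- which(is.na(out) & !is.na(x) & x != "" & toupper(x) != "NA")
  stopIf(length(bad) > 0, "%s: unparseable number '%s' in column '%s', row %d",
         path, x[bad[1L]], column, bad[1L])
  out
}

#' Read I/V sweeps from a long-format delimited file
#'
#' Expected columns: \code{sample_id}, \code{strain}, \code{gap_um},
#' \code{voltage_V}, \code{current_A}; comma or tab delimited
#' (autodetected). One \linkS4class{IVSweep} is built per
#' \code{sample_id}. A header-only file yields an empty list.
#'
#' @param path file path.
#' @return list of \linkS4class{IVSweep}s.
#' @export
readIVSweeps <- function(path) {
  df <- .readDelimited(path)
  .requireColumns(df, c("sample_id", "strain", "gap_um", "voltage_V",
                        "current_A"), path)
  if (nrow(df) == 0L) return(list())
  df$gap_um <- .parseNumeric(df$gap_um, "gap_um", path)
  df$voltage_V <- .parseNumeric(df$voltage_V, "voltage_V", path)
  df$current_A <- .parseNumeric(df$current_A, "current_A", path)
  ids <- unique(df$sample_id)
  lapply(ids, function(id) {
    rows <- df[df$sample_id == id, , drop = FALSE]
    IVSweep(id, rows$strain[1L], rows$voltage_V, rows$current_A,
            rows$gap_um[1L])
  })
}

#' Write I/V sweeps to a long-format CSV
#'
#' @param sweeps list of \linkS4class{IVSweep}s.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeIVSweeps <- function(sweeps, path) {
  rows <- lapply(sweeps, function(sw) {
    data.frame(sample_id = sw@sampleId, strain = sw@strainLabel,
               gap_um = sw@gapLength, voltage_V = sw@voltages,
               current_A = sw@currents, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), strain = character(),
               gap_um = numeric(), voltage_V = numeric(),
               current_A = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format EDX table
#'
#' Expected columns: \code{section_id}, \code{strain}, \code{element},
#' \code{ka_counts}; optional \code{percent} and \code{outlier} (0/1).
#'
#' @param path file path.
#' @return data.frame in long form with parsed numeric columns.
#' @export
readEDXTable <- function(path) {
  df <- .readDelimited(path)
  .requireColumns(df, c("section_id", "strain", "element", "ka_counts"),
                  path)
  if (nrow(df) > 0L) {
    df$ka_counts <- .parseNumeric(df$ka_counts, "ka_counts", path)
    if ("percent" %in% names(df))
      df$percent <- .parseNumeric(df$percent, "percent", path)
    if ("outlier" %in% names(df))
      df$outlier <- .parseNumeric(df$outlier, "outlier", path) != 0
  }
  df
}

#' Pivot a long EDX table to one wide row per region
#'
#' @param long data.frame as returned by \code{\link{readEDXTable}}.
#' @param value \code{"percent"} or \code{"ka_counts"}.
#' @return data.frame with \code{section_id}, \code{strain}, one column
#'   per element, and \code{outlier}.
#' @export
edxWide <- function(long, value = c("percent", "ka_counts")) {
  value <- match.arg(value)
  stopIf(!value %in% names(long), "column '%s' absent from the table", value)
  elements <- unique(long$element)
  ids <- unique(long$section_id)
  rows <- lapply(ids, function(id) {
    sub <- long[long$section_id == id, , drop = FALSE]
    vals <- stats::setNames(sub[[value]][match(elements, sub$element)],
                            elements)
    cbind(data.frame(section_id = id, strain = sub$strain[1L],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE),
          data.frame(outlier = if ("outlier" %in% names(sub))
            any(sub$outlier) else FALSE))
  })
  do.call(rbind, rows)
}

#' Read isotope counts
#'
#' Expected columns: \code{sample_id}, \code{isotope}, \code{count}.
#'
#' @param path file path.
#' @return named list (per sample) of named count vectors.
#' @export
readIsotopeCounts <- function(path) {
  df <- .readDelimited(path)
  .requireColumns(df, c("sample_id", "isotope", "count"), path)
  if (nrow(df) == 0L) return(list())
  df$count <- .parseNumeric(df$count, "count", path)
  lapply(split(df, df$sample_id), function(sub)
    stats::setNames(sub$count, sub$isotope))
}

#' Read vesicle observations
#'
#' Expected columns: \code{diameter_nm}, \code{attachment} (IMAV or CV).
#'
#' @param path file path.
#' @return data.frame with \code{diameter}, \code{attachment}.
#' @export
readVesicles <- function(path) {
  df <- .readDelimited(path)
  .requireColumns(df, c("diameter_nm", "attachment"), path)
  if (nrow(df) == 0L)
    return(data.frame(diameter = numeric(), attachment = character()))
  data.frame(diameter = .parseNumeric(df$diameter_nm, "diameter_nm", path),
             attachment = df$attachment, stringsAsFactors = FALSE)
}

#' Read a protein FASTA into a named sequence vector
#'
#' Ids are the first whitespace-delimited token of each description line;
#' sequences are uppercased; duplicate ids and empty records are rejected.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  stopIf(!file.exists(path), "file not found: %s", path)
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  stopIf(length(dup) > 0, "%s: duplicate protein id(s): %s", path,
         paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  empty <- ids[nchar(seqs) == 0L]
  stopIf(length(empty) > 0, "%s: empty record(s): %s", path,
         paste(empty, collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write a named sequence vector as protein FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProteinFasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
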