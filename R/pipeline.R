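#' Default run configuration
#'
#' Every constant of the analysis with its default baked in: per-strain
#' geometries (per-fiber areas 850/1100 nm^2, fixed PCF counts 34/15 where
#' measured, shape kinds), the conductivity constants (evaluation voltage
#' 0.1 V, detection limit 1e-12 A/V), the EDX element panel and ratio
#' pairs, the nickel isotope reference abundances, the motif and scoring
#' parameters, and the sPHC length threshold.
#'
#' @return nested list; see \code{\link{readRunConfig}} for overriding
#'   parts of it from a YAML file.
#' @export
defaultRunConfig <- function() {
  list(
    strains = list(
      GS = list(per_fiber_area = 850, fixed_pcf_count = 34,
                shape_kind = "circular"),
      RB = list(per_fiber_area = 1100, fixed_pcf_count = 15,
                shape_kind = "rectangular"),
      Rat = list(per_fiber_area = 850),
      Hou = list(per_fiber_area = 850),
      Hou1 = list(per_fiber_area = 850)
    ),
    analysis = list(eval_voltage = 0.1, lod_conductance = 1e-12),
    edx = list(panel = c("S", "Fe", "Ni"),
               pairs = c("S:Fe", "S:Ni", "Fe:Ni")),
    isotope = list(element = "Ni",
                   abundances = list("58Ni" = 68.08, "60Ni" = 26.22,
                                     "62Ni" = 3.64)),
    motif = list(n_internal = 2, overlap = "non_overlapping",
                 sphc_max_length = 250),
    scoring = list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                   min_score = 50),
    simulate = list(n_sweeps = 50, true_sigma = 4.0, noise_fraction = 0.05,
                    lod_fraction = 0.1, strain = "GS",
                    n_edx_regions = 10, edx_total_counts = 1e4,
                    isotope_total_counts = 1e5,
                    n_vesicles = 200, imav_fraction = 0.9,
                    vesicle_mean = 65.5, vesicle_sd = 4.6)
  )
}

# recursive override of defaults by user values
.mergeConfig <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], override[[nm]])
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

#' Read a YAML run configuration over the defaults
#'
#' Any key present in the file overrides the corresponding default; all
#' other defaults are kept. The overridden keys are recorded in the
#' \code{"overrides"} attribute so run summaries can echo them for
#' provenance.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  stopIf(!file.exists(path), "config file not found: %s", path)
  override <- yaml::read_yaml(path)
  cfg <- .mergeConfig(cfg, override)
  attr(cfg, "overrides") <- override
  cfg
}

.geometryFromConfig <- function(config, strain) {
  sc <- config$strains[[strain]]
  stopIf(is.null(sc), "strain '%s' is not defined in the configuration",
         strain)
  StrainGeometry(strain, sc$per_fiber_area,
                 fixedPcfCount = sc$fixed_pcf_count)
}

.writeSummaryJson <- function(outDir, stage, seed, summary, config) {
  path <- file.path(outDir, sprintf("%s_summary.json", stage))
  payload <- list(stage = stage, seed = seed,
                  package = "pcfQuant",
                  version = as.character(utils::packageVersion("pcfQuant")),
                  rng = "Mersenne-Twister (set.seed)",
                  overrides = attr(config, "overrides"),
                  summary = summary)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

#' Run one pipeline stage end to end
#'
#' Thin orchestration over the package's functions: reads the stage's
#' inputs, runs the computation, writes result tables to \code{outDir} and
#' a machine-readable JSON run summary (inputs, seed, headline statistics,
#' echoed configuration overrides). Stages: \code{"simulate"} (write
#' seeded fixtures for every stage), \code{"conduct"} (I/V conductivity
#' cohort), \code{"edx"} (composition summary), \code{"isotope"}
#' (observed-vs-expected fractions), \code{"morpho"} (area comparisons and
#' vesicle summary), \code{"heme"} (proteome annotation), \code{"census"}
#' (conserved-cytochrome census).
#'
#' @param stage stage name, see above.
#' @param inputs named list of input file paths; which keys are needed
#'   depends on the stage (\code{sweeps}, \code{edx}, \code{isotope},
#'   \code{vesicles}, \code{fasta}, \code{fastaA}, \code{fastaB}).
#' @param outDir output directory (created if absent).
#' @param config configuration list from \code{\link{readRunConfig}}.
#' @param seed integer seed for stages that draw random numbers.
#' @return the stage summary list, invisibly; result files land in
#'   \code{outDir}.
#' @export
runPipeline <- function(stage, inputs = list(), outDir = tempfile("run"),
                        config = readRunConfig(), seed = 1) {
  known <- c("simulate", "conduct", "edx", "isotope", "morpho", "heme",
             "census")
  stopIf(!is.character(stage) || length(stage) != 1L || !stage %in% known,
         "unknown stage '%s'; expected one of: %s",
         paste(stage, collapse = ","), paste(known, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  summary <- switch(stage,
    simulate = .stageSimulate(outDir, config, seed),
    conduct = .stageConduct(inputs, outDir, config),
    edx = .stageEdx(inputs, outDir, config),
    isotope = .stageIsotope(inputs, outDir, config),
    morpho = .stageMorpho(inputs, outDir, config),
    heme = .stageHeme(inputs, outDir, config),
    census = .stageCensus(inputs, outDir, config))
  .writeSummaryJson(outDir, stage, seed, summary, config)
  invisible(summary)
}

.stageSimulate <- function(outDir, config, seed) {
  sim <- config$simulate
  geometry <- .geometryFromConfig(config, sim$strain)
  sweeps <- simIVSweeps(sim$n_sweeps, sim$true_sigma, sim$noise_fraction,
                        sim$lod_fraction, geometry, seed = seed)
  writeIVSweeps(sweeps, file.path(outDir, "iv_sweeps.csv"))
  utils::write.csv(attr(sweeps, "truth"),
                   file.path(outDir, "iv_truth.csv"), row.names = FALSE)

  edx <- simEDXCounts(sim$n_edx_regions, totalCounts = sim$edx_total_counts,
                      seed = seed + 1L)
  elements <- setdiff(names(edx), "section_id")
  long <- do.call(rbind, lapply(seq_len(nrow(edx)), function(i)
    data.frame(section_id = edx$section_id[i], strain = sim$strain,
               element = elements,
               ka_counts = as.numeric(edx[i, elements]),
               stringsAsFactors = FALSE)))
  utils::write.csv(long, file.path(outDir, "edx_counts.csv"),
                   row.names = FALSE)

  ref <- IsotopeReference(config$isotope$element,
                          unlist(config$isotope$abundances))
  iso <- simIsotopeCounts(sim$isotope_total_counts, ref, seed = seed + 2L)
  utils::write.csv(data.frame(sample_id = "sim", isotope = names(iso),
                              count = as.numeric(iso)),
                   file.path(outDir, "isotope_counts.csv"),
                   row.names = FALSE)

  ves <- simVesicles(sim$n_vesicles, sim$imav_fraction, sim$vesicle_mean,
                     sim$vesicle_sd, seed = seed + 3L)
  utils::write.csv(data.frame(diameter_nm = ves$diameter,
                              attachment = ves$attachment),
                   file.path(outDir, "vesicles.csv"), row.names = FALSE)

  pp <- simProteomePair(seed = seed + 4L)
  writeProteinFasta(pp$proteomeA, file.path(outDir, "proteome_a.fasta"))
  writeProteinFasta(pp$proteomeB, file.path(outDir, "proteome_b.fasta"))
  utils::write.csv(pp$truth, file.path(outDir, "proteome_truth.csv"),
                   row.names = FALSE)
  list(nSweeps = sim$n_sweeps, trueSigma = sim$true_sigma,
       nEdxRegions = sim$n_edx_regions, nVesicles = sim$n_vesicles,
       nProteinsPerProteome = length(pp$proteomeA))
}

.stageConduct <- function(inputs, outDir, config) {
  stopIf(is.null(inputs$sweeps), "stage 'conduct' needs inputs$sweeps")
  sweeps <- readIVSweeps(inputs$sweeps)
  cfg <- AnalysisConfig(config$analysis$eval_voltage,
                        config$analysis$lod_conductance)
  rows <- do.call(rbind, lapply(sweeps, function(sw) {
    analyzeSweep(sw, .geometryFromConfig(config, sw@strainLabel), cfg)
  }))
  utils::write.csv(rows, file.path(outDir, "conductivity_results.csv"),
                   row.names = FALSE)
  cohorts <- lapply(split(rows, rows$strain), summarizeCohort)
  coTab <- do.call(rbind, lapply(names(cohorts), function(s) {
    co <- cohorts[[s]]
    data.frame(strain = s, n_total = co$nTotal, n_below_lod = co$nBelowLod,
               mean_s_per_cm = co$mean, sd_s_per_cm = co$sd,
               median = co$median, q1 = co$q1, q3 = co$q3,
               whisker_low = co$whiskerLow, whisker_high = co$whiskerHigh,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(coTab, file.path(outDir, "cohort_summary.csv"),
                   row.names = FALSE)
  list(nSweeps = length(sweeps),
       cohorts = lapply(cohorts, function(co)
         co[c("nTotal", "nBelowLod", "mean", "sd", "median")]))
}

.stageEdx <- function(inputs, outDir, config) {
  stopIf(is.null(inputs$edx), "stage 'edx' needs inputs$edx")
  long <- readEDXTable(inputs$edx)
  stopIf(!"percent" %in% names(long),
         "edx input needs a 'percent' column (factors are per acquisition)")
  wide <- edxWide(long, "percent")
  out <- lapply(split(wide, wide$strain), function(sub) {
    s <- summarizeCompositions(sub[, setdiff(names(sub), "strain")],
                               pairs = config$edx$pairs)
    list(elementMean = as.list(s$elementMean),
         elementSd = as.list(s$elementSd),
         ratioMean = as.list(s$ratioMean), ratioSd = as.list(s$ratioSd),
         n = s$n, excluded = s$excludedIds)
  })
  sumTab <- do.call(rbind, lapply(names(out), function(s) {
    data.frame(strain = s,
               stat = c("mean", "sd"),
               rbind(as.data.frame(out[[s]]$elementMean),
                     as.data.frame(out[[s]]$elementSd)),
               rbind(as.data.frame(out[[s]]$ratioMean, check.names = FALSE),
                     as.data.frame(out[[s]]$ratioSd, check.names = FALSE)),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  utils::write.csv(wide, file.path(outDir, "edx_compositions.csv"),
                   row.names = FALSE)
  utils::write.csv(sumTab, file.path(outDir, "edx_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  out
}

.stageIsotope <- function(inputs, outDir, config) {
  stopIf(is.null(inputs$isotope), "stage 'isotope' needs inputs$isotope")
  ref <- IsotopeReference(config$isotope$element,
                          unlist(config$isotope$abundances))
  samples <- readIsotopeCounts(inputs$isotope)
  tabs <- lapply(names(samples), function(id) {
    cbind(sample_id = id, isotopeFractionTable(samples[[id]], ref))
  })
  utils::write.csv(do.call(rbind, tabs),
                   file.path(outDir, "isotope_fractions.csv"),
                   row.names = FALSE)
  lapply(samples, function(x) {
    g <- isotopeGof(x, ref)
    list(chiSquare = g$chiSquare, dof = g$dof, pValue = g$pValue)
  })
}

.stageMorpho <- function(inputs, outDir, config) {
  single <- compareSinglePCFArea(shapePreset("GS"), shapePreset("RB"))
  totalModel <- compareTotalPCFArea(34, pcfAreaPreset("GS", "model"),
                                    15, pcfAreaPreset("RB", "model"))
  totalMeas <- compareTotalPCFArea(34, pcfAreaPreset("GS", "measured"),
                                   15, pcfAreaPreset("RB", "measured"))
  rep <- data.frame(
    comparison = c("single_pcf_area_rb_vs_gs",
                   "total_pcf_area_rb_vs_gs_model",
                   "total_pcf_area_rb_vs_gs_measured"),
    percent = c(single$percent, totalModel$percent, totalMeas$percent),
    rounded = c(single$rounded, totalModel$rounded, totalMeas$rounded),
    stringsAsFactors = FALSE)
  utils::write.csv(rep, file.path(outDir, "morphometry_report.csv"),
                   row.names = FALSE)
  summary <- list(singlePcfPercent = single$percent,
                  totalPcfPercentModel = totalModel$percent,
                  totalPcfPercentMeasured = totalMeas$percent)
  if (!is.null(inputs$vesicles)) {
    vs <- summarizeVesicles(readVesicles(inputs$vesicles))
    utils::write.csv(vs$byClass, file.path(outDir, "vesicle_summary.csv"),
                     row.names = FALSE)
    summary$vesicles <- vs[c("nTotal", "nIMAV", "nCV", "imavFraction")]
  }
  summary
}

.stageHeme <- function(inputs, outDir, config) {
  stopIf(is.null(inputs$fasta), "stage 'heme' needs inputs$fasta")
  ann <- annotateProteome(readProteinFasta(inputs$fasta),
                          nInternal = config$motif$n_internal,
                          overlap = config$motif$overlap,
                          sphcMaxLength = config$motif$sphc_max_length)
  utils::write.table(ann, file.path(outDir, "heme_annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(nProteins = nrow(ann),
       nCytochromes = sum(ann$n_hemes >= 1L),
       classCounts = as.list(table(ann$class)))
}

.stageCensus <- function(inputs, outDir, config) {
  stopIf(is.null(inputs$fastaA) || is.null(inputs$fastaB),
         "stage 'census' needs inputs$fastaA and inputs$fastaB")
  scheme <- ScoringScheme(config$scoring$matrix, config$scoring$gap_open,
                          config$scoring$gap_extend)
  res <- conservedCytochromeCensus(
    readProteinFasta(inputs$fastaA), readProteinFasta(inputs$fastaB),
    scheme, minScore = config$scoring$min_score,
    nInternal = config$motif$n_internal, overlap = config$motif$overlap,
    sphcMaxLength = config$motif$sphc_max_length)
  utils::write.table(res$pairs, file.path(outDir, "homolog_pairs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$census, file.path(outDir, "census.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  res$counts
}
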