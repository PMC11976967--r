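Package: pcfQuant
Title: Quantitative Analysis of Cable Bacteria Conductive Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantitative analyses
    used to characterise the conduction machinery of cable bacteria:
    single-filament electrical conductivity from two-probe current-voltage
    sweeps with a strain-specific periplasmic-conductive-fiber (PCF)
    geometry model and detection-limit censoring; STEM-EDX relative
    elemental quantification via per-region sensitivity factors with
    elemental-ratio statistics; ToF-SIMS nickel-isotope pattern
    verification against natural abundances; PCF and vesicle morphometry;
    and a CXXCH heme-motif census with reciprocal-best-hit conservation
    calls between proteomes. A seeded synthetic-data module generates
    inputs with the statistical structure each stage assumes, so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
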