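---
title: "Methods: quantifying the conduction machinery of cable bacteria"
author: "pcfQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the conduction machinery of cable bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfQuant)
```

Cable bacteria are filamentous, multicellular bacteria that conduct
electrons over centimeter distances through periplasmic conductive fibers
(PCFs) running along each filament. This package implements the
quantitative analyses used to characterise that conduction machinery in
two strains — the *Electronema aureum* GS strain and the *Electrothrix
communis* RB strain — as tested, reusable functions. This vignette is the
package's account of the underlying models, its tunable parameters, the
numerical conventions it adopts where the source material prints none, and
the limits of what its synthetic-data tests demonstrate.

## Single-fiber conductivity from two-probe I/V sweeps

A filament bridged between two carbon-paste electrodes is swept from −1 to
+1 V while the current is monitored. The sweep is ohmic, so ordinary least
squares of current on voltage (`fitIV`) yields the filament conductance
$G$ (A/V). Conductivity follows from

$$\sigma = \frac{I \, l}{V A},$$

with $I$ the current at the evaluation voltage $V$ (default 0.1 V), $l$
the electrode gap (100–800 µm in practice), and $A$ the total PCF
cross-sectional area. Internally everything is SI (A, V, m, m²); results
are presented in S/cm, and the single conversion constant is tested
against a hand-worked dimensional example (slope 10 nA/V, gap 300 µm,
area 28 900 nm² → 1.038 S/cm).

Conventions worth stating explicitly:

* **Fitted, not raw, current.** $I$ is the fitted line evaluated at the
  evaluation voltage *minus the intercept*, i.e. slope × 0.1 V. This is
  robust to per-point noise; on the linear sweeps the method assumes, the
  fitted and nearest-raw currents agree.
* **Censoring is strict.** A sweep is below the limit of detection when
  |slope| is *strictly* below `lodConductance` (default 1 pA/V); a slope
  exactly at the limit counts as detectable.
* **Geometry resolution.** The cross-section is
  `pcfCount × perFiberArea`, with one fiber assumed 850 nm² for GS-type
  strains and 1100 nm² for RB. An explicit measured PCF count (GS 34,
  RB 15) always wins; the linear diameter scaling
  `count = 5 × π × diameter` (diameter in µm) is used only for mixed
  enrichments without a direct count. Counts are rounded to the nearest
  integer, halves away from zero — base R's round-half-even is avoided
  because the convention must be predictable for users re-deriving printed
  counts by hand.
* **Cohort statistics.** Mean and sample standard deviation (n−1) are
  computed over non-censored results only; censored measurements are
  counted separately and never imputed. Box statistics follow the Tukey
  convention (type-7 quantiles, whiskers at the most extreme observations
  within 1.5 IQR of the box). The published cohorts report "19% of GS
  measurements below detection" while listing n = 17 above-LOD replicates;
  since the intended denominator is ambiguous, `summarizeCohort` reports
  both counts and leaves any percentage to the caller.
* **r² convention.** For a perfectly fitted constant-current sweep both
  the residual and total sums of squares are zero; the 0/0 case is defined
  as r² = 1 (the line explains the data exactly).

## STEM-EDX relative quantification

Scanning transmission electron microscopy with energy-dispersive X-ray
spectroscopy yields per-region integrated Kα counts for sulfur, iron and
nickel. Quantification is Cliff–Lorimer-style and strictly *relative*:

$$\mathrm{percent}_i = 100 \cdot
  \frac{c_i f_i}{\sum_j c_j f_j},$$

with one multiplicative sensitivity factor $f_i$ per element. Only factor
ratios matter (the result is invariant under global rescaling), and
factors are acquisition-dependent — beam current, dwell time and detector
geometry all move them — so they are supplied or fitted *per region or
batch*, never defaulted globally. `fitSensitivityFactors` inverts the
quantification on a region with known composition, which lets a published
quantification row calibrate its own acquisition; the round-trip
`relativeAtomicPercent ∘ fitSensitivityFactors` is the identity on any
strictly positive row and is property-tested on random rows.

Ratio summaries default to **averaging the per-row ratios** rather than
taking ratios of mean percentages, because the published summary rows
equal the former. The two modes disagree in general (a Jensen-type
effect), so both are exposed and each summary states its mode. Outlier
exclusion is by explicit flag only: the excluded GS cross-section was
flagged in the source for resembling the other strain, with no numeric
criterion, and inventing one here would be false precision.

Two presentational caveats are baked into the tests rather than papered
over: the published averages were computed from unrounded values, so
recomputing from the printed rows can differ by one unit in the last
digit (GS Ni mean 2.4 printed vs 2.5 recomputed; RB Fe 10.9 vs 11.0; RB
S:Fe 7.24 vs 7.25; GS S:Ni std 5.53 vs 5.52). And the raw-count columns
of two published rows are typographically ambiguous, so raw counts are
never used as numeric references — only percentages and ratios are.

## ToF-SIMS isotope verification

An elemental assignment is verified by comparing observed isotope
relative counts to natural abundance. The relative count of an isotope is
its count divided by the summed counts of the three most abundant nickel
isotopes — an explicit, ordered subset (⁵⁸Ni 68.08%, ⁶⁰Ni 26.22%, ⁶²Ni
3.64%, together 97.94%) rather than "all peaks present", because ToF-SIMS
spectra contain interfering peaks. The expected fraction of ⁵⁸Ni over the
subset is therefore 68.08/97.94 = 0.6951.

A Pearson chi-square against the expected counts (`isotopeGof`, k−1
degrees of freedom) is provided, but the headline output is the
observed-versus-expected fraction table: the source material makes the
comparison visually and states no quantitative agreement criterion, so the
default report renders no verdict. The statistic warns below the usual
expected-count-of-5 rule and is deliberately *not* scale invariant for
non-proportional patterns (a fixed fractional discrepancy grows with total
count) — that behaviour is documented and tested.

## Morphometry

Single-PCF cross-sections are modelled per strain from configuration, not
inferred from data: GS fibers are rounded (circular, diameter
30.89 nm → 749.4 nm²), RB fibers rectangular (25.95 × 43.01 nm →
1116.1 nm²). Comparisons report

$$100 \cdot \frac{A_b - A_a}{A_a},$$

unrounded *and* rounded to a step (default 10%) matching the
"around 50% bigger" granularity of the source claims. Percent difference
is not antisymmetric under swapping the operands; callers choose the
reference. Two per-fiber-area presets exist — `model` (850/1100 nm², the
conductivity assumption) and `measured` (Table-derived shapes) — and every
comparison states which it used. The "total area" claim (RB ≈ 40%
smaller) matches the model preset (−42.9% → −40 at step 10) better than
the measured one (−34.3%); both are reported because which one the
original used is not stated.

Vesicle summaries report the fraction of inner membrane-attached vesicles
(IMAVs) among all vesicles plus per-class diameter means and sample
standard deviations; a class with one observation reports an NA standard
deviation rather than zero.

## CXXCH mining and the conservation census

c-type cytochromes covalently bind heme through the CXXCH motif. The scan
(`scanHemeMotifs`) is strict C-x-x-C-H by default — the only pattern the
source names — with the internal gap configurable (CX3CH etc.) for
sensitivity analyses. The default overlap policy is non-overlapping
(scanning resumes after a match), with an all-windows mode that is
property-tested against brute-force window enumeration. The ambiguity
letter X never matches the C or H positions.

Classification is by motif count: none / monoheme / multiheme, with
exactly five hemes split into the small (sPHC) and large (lPHC) variants
of the cable-bacteria pentaheme cytochrome family by mature-sequence
length. The source distinguishes the two by predicted domain size without
printing a cutoff; the default threshold of 250 residues is a documented
choice (the known sPHCs are compact single-domain proteins; lPHCs carry a
larger cytochrome domain, often fused to truncated-hemoglobin domains)
and is configurable.

Conservation between the two proteomes is re-implemented as **reciprocal
best hits** under Smith–Waterman local alignment with affine gaps
(BLOSUM62, gap open 11, extend 1; a gap of length L costs open + L·ext).
The aligner is `Biostrings::pairwiseAlignment`; an independent quadratic
dynamic-programming oracle, written separately in the test helpers,
verifies it exactly on seeded random pairs. The raw-score threshold of 50
was chosen so unrelated random sequences of typical protein length
essentially never reach it (random 300-mer pairs score ≈ 33–42 under this
scheme); ties for a best hit are broken lexicographically and flagged
rather than dropped. In lenient mode (default) X scores 0 against every
residue; strict mode rejects X outright.

The census lists reciprocal pairs in which *both* members carry at least
one motif; one-sided motifs are reported as discordant. The original
study further restricted its census to predicted extracytoplasmic
proteins using external localization predictors; that filter is out of
scope here, so the census covers all conserved cytochromes and accepts an
optional user-supplied localization table instead. Reproducing the
original count of 11 conserved extracytoplasmic cytochromes therefore
requires the real genome assemblies plus external localization tools, and
is deliberately not a test target.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its arguments: seeded locally
(Mersenne–Twister via `set.seed`), restoring the global RNG state on
exit, so the same call is byte-identical every time. Defaults are the
study conditions:

| Generator | Defaults | Emulates |
|---|---|---|
| `simIVSweeps` | 21-point −1..1 V sweeps, gap ~ U(100, 800) µm, true σ 4.0 S/cm, 5% relative Gaussian current noise | the GS cohort's ohmic sweeps |
| `simEDXCounts` | Poisson counts, 10⁴ total per region, composition (24.9, 72.7, 2.4)% | count statistics of the quantification rows |
| `simIsotopeCounts` | multinomial at the ⁵⁸/⁶⁰/⁶²Ni abundances | isotope verification counts |
| `simVesicles` | IMAV fraction 0.9, diameter N(65.5, 4.6) nm truncated at 0 | the GS vesicle observations |
| `simProteomePair` | 8 planted homolog pairs, 12 decoys per side, 10% point mutation | the two-proteome conservation setting |

Censored sweeps are generated at one tenth of the LOD conductance — not
at zero — so the censoring boundary is actually exercised. Planted
proteome homologs deviate from neutral evolution in two documented ways:
motif positions are masked from mutation (a planted motif is never
destroyed), and planted-protein backgrounds are cysteine-free outside the
motifs so the planted heme counts are exact by construction. Decoys use
the full alphabet. The generators do not attempt raw spectra, images,
drift, detector artifacts, correlated noise, or realistic protein
composition biases — so passing recovery tests demonstrates correctness
of the estimators under the stated statistical model, not robustness to
every artifact of real acquisitions.

## Problem sizes and test design

The suite runs at sizes chosen to make the statistical assertions sharp
while keeping the whole run fast: 200 sweeps for the conductivity
recovery check (cohort mean within 2% of truth at 5% point noise), 100
sweeps per point of the σ ∈ {0.1, 4, 25} S/cm recovery sweep, 50 Poisson
regions at 10⁴ counts for composition recovery (within 1 percentage
point), 1000 multinomial simulations for the chi-square mean ≈ dof check,
100 seeded 30-mer pairs for the alignment oracle, and the standard
8-homolog/12-decoy fixture at seed 42 for census precision/recall = 1.
Published summary values are asserted at their printed precision.

## Known limitations

* Conductivity in air decays over time in the source observations; no
  time dependence is modelled, and atmosphere is carried as metadata only.
* EDX quantification is relative-only: no peak fitting, background
  subtraction, absorption/thickness correction, or absolute weight
  percent.
* The isotope module assumes integrated counts are already extracted from
  calibrated spectra.
* Homology here is sequence-level reciprocal best hits; the original
  study's structure-based comparisons (fold prediction and structural
  alignment) are a different, stronger criterion and out of scope.
* The sPHC/lPHC threshold and the RBH score threshold are defaults with
  rationale, not measured constants; both are configuration knobs.
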