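---
title: "Methods: direct-infusion lipidomics with lipidims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct-infusion lipidomics with lipidims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidims)
```

`lipidims` implements the data-processing and statistical stages of a
direct-infusion (shotgun) mass-spectrometry lipidomics study comparing
three body compartments — blood serum, seminal fluid and spermatozoa —
within the same men, with a secondary contrast between groups of low and
high sperm progressive motility. This vignette documents the model and
procedure, the parameters that matter and their defaults, the synthetic
cohort generator and its limits, and the numerical and design decisions
that were genuinely open.

## Data model

Direct infusion has no chromatographic dimension, so a measurement is a
*centroided peak list* per sample and ionisation channel: pairs of (m/z,
intensity). Three channels are modelled: `positive` (protonated and
ammoniated adducts, [M+H]+ and [M+NH4]+), `negative` (deprotonated
[M−H]−), and `negative_cid`, a high-collision-energy negative channel
read as a fatty-acid panel. A *variable* is one library species observed
as one adduct in one channel, e.g. `PC(34:1)[M+H]`. All matrices are one
channel each; channels never share a normalization total.

Lipid identities are sum-composition shorthand only — `CLASS(C:D)` with
total acyl/alkyl carbons and total double bonds, plus the bare token
`CHOL`. The grammar deliberately rejects sn-resolved names (slashes):
direct-infusion annotation by m/z cannot resolve chain positions, and
none of the comparisons need them. The class taxonomy (17 classes: CER,
SM, PC, PC-O, PE, PE-O, PE-P, LPC, LPE, PG, PI, PS, TG, DG, CE, CHOL,
FA) ships as a packaged CSV with each class's elemental base
composition, channels and adducts. A species mass is the class base plus
`C` methylene units minus `D` H2, using monoisotopic element masses —
which reproduces real monoisotopic masses (PC(34:1) = 759.5778 Da) and
makes natural isobar families exact by construction (PC(c:d) equals
PE(c+3:d)). PE-O and PE-P are kept as distinct classes because both
occur in the comparisons; PC ethers are a single PC-O class, since a
separate PC plasmalogen class never appears in this field's shorthand
for these panels.

## Annotation

A peak is matched to every library entry whose adduct m/z lies within
the tolerance, default **9 ppm**, where
`ppm = 1e6 * (observed − reference)/reference`. The boundary is
inclusive: only deviations strictly beyond the tolerance are excluded.
When several species match (isobars), assignment follows a per-channel
class-priority list; the defaults encode exactly the two mode-specific
rules used in practice — **PC before PE in positive mode, PC before PS
in negative mode** — with remaining ties broken by minimal absolute ppm
error, then canonical name and adduct order, making the resolution a
deterministic total order. The chosen annotation is flagged `ambiguous`
whenever alternatives existed. The phrasing of the negative-mode rule in
common use is ambiguous about its direction; `lipidims` encodes the
"PC over PS" reading and exposes the priority lists as configuration
(`isobar_priorities()`) so the opposite reading is one argument away.

Each peak receives at most one assignment; a library entry may annotate
peaks in every sample. No isotope-cluster deconvolution is attempted
(all masses monoisotopic, singly charged), and the pipeline starts at
centroided peak lists — profile-spectrum peak picking is upstream of
this package.

## Signal-quality filtering

Four rules run in a fixed order with strict boundary semantics:

| rule      | statistic                                   | removed when |
|-----------|---------------------------------------------|--------------|
| zero      | —                                           | (per cell) zero values become missing |
| snr       | mean study signal / mean blank signal       | S/N < 3      |
| presence  | fraction of study samples with signal       | < 0.5        |
| linearity | Pearson r of QC intensity vs dilution       | r ≤ 0.75     |

Decisions worth recording:

* **Zero rule is per measurement.** A variable is not discarded for a
  single zero; zeros become missing values and the presence rule then
  removes variables that are mostly absent. Treating any zero as fatal
  would contradict the 50%-presence rule's existence.
* **Noise is the blank-well mean.** S/N needs a noise definition; the
  plate design contains blank wells, so noise is the mean blank signal
  for that variable, with absent blank peaks counted as zero signal. No
  blanks, or an all-zero blank mean, gives S/N = +Inf and the variable
  passes. A variable with no study signal at all is routed to the
  presence rule (S/N undefined).
* **Presence is over study samples only** — QCs and blanks are not in
  the denominator. The 50% rule is evaluated over all study samples of
  the channel, not per compartment; a per-compartment presence analysis
  is a sensitivity check left to the user.
* **QC linearity uses product-moment r** of raw intensity against the
  dilution factor (0.25/0.5/1.0 of pooled reference), requiring at
  least three QC measurements spanning two dilution factors. Missing QC
  cells count as zero intensity — absence in a diluted QC is evidence
  about proportionality, not ignorable. Constant QC intensity leaves r
  undefined and the variable is removed.
* The 9 ppm rule is enforced at annotation (it is a match criterion,
  not a matrix filter).

Filtering reports every variable with its statistics and first failing
rule, keeps cell values untouched (only column membership changes), and
is therefore idempotent. The test suite checks the whole report against
an independently written brute-force evaluation on hundreds of random
matrices.

## Normalization and statistics

Signals are semi-quantitative, so each is expressed relative to the
total lipid signal of its sample and channel, per mille:
`1000 * x / sum(x)` over non-missing cells. Rows then sum to 1000 ‰
exactly (conservation is asserted to 1e-9 relative tolerance in the
tests).

**Outlier screen.** Variables are autoscaled (zero mean, unit variance;
zero-variance variables dropped; missing treated as zero for the screen
only) and samples whose PC1 or PC2 score lies more than 3 SD from the
component centre are excluded before any testing. PCA is the screen
named by standard practice; the 3 SD score rule is this package's
stated criterion, since no numeric criterion is standard. Group medians
and splits are recomputed after exclusions.

**Motility split.** Participants are split at the cohort median
progressive motility: low strictly below, high at or above. With the
cohorts modelled here the median is about 50% progressive motility.

**Differential tests.** Between compartments: two-sided paired t-tests
on per-participant differences, pairs with missing values dropped
variable-wise, at least two complete pairs required. Within a
compartment between motility groups: two-sided unpaired t-tests with
Welch's correction by default (`var_equal = TRUE` restores the pooled
test) — whether a pooled or
Welch test is used is genuinely open here, and Welch is the safer
default under unequal variances. Fold
changes are ratios of arithmetic means of per-mille values (numerator:
first compartment, or the high-motility group); zero denominator means
produce infinite fold changes that are routed to the volcano exclusion
list rather than plotted. Degenerate inputs are handled explicitly:
identical paired values give t = 0, p = 1; constant unequal groups give
p = 0 with an infinite t.

**Significance.** The limit is a fixed strict threshold **p < 0.001**
(`alpha` is configurable). This is the conventional strict limit used
with panels of several hundred lipid variables rather than a derived
Bonferroni bound (a literal Bonferroni correction at 0.05 over ~500
variables would give ~1e-4, a different number), so the package
implements the stated limit directly and does not guess a correction
rule. No further multiple-testing correction is layered on top.

A caveat the package's own acceptance computations make visible: on
log-normal data with per-group n around 12–26, the t-test is
conservative this far out in the tail — the realized fraction of null
tests below 0.001 comes out below 0.001 (see the
`type1_fraction_paired` / `type1_fraction_unpaired` values written by
`scripts/acceptance.R`). This is a property of the t statistic under
skewed data, not of the implementation; tests on log-transformed
abundances would be closer to nominal but would change the estimand, so
the package tests the per-mille values directly.

**Class aggregation.** Per-mille abundances are summed per class per
sample. The fatty-acid panel is reported as saturation categories —
SFA (0 double bonds), MUFA (1), PUFA (≥ 2) — plus an essential set
(default FA(18:2), FA(18:3); configurable, as the set is nowhere
enumerated). Because essential FAs are themselves polyunsaturated,
aggregation assigns each FA to exactly one category with EFA taking
precedence over PUFA; this keeps class sums at or below 1000 ‰ per
sample with equality when every variable maps to a class.
`fatty_acid_category()` itself reports saturation and essentiality as
independent fields.

## The synthetic cohort generator

No cohort of this kind is publicly deposited, so the generator is a
first-class module that emulates the study's statistical structure with
recorded ground truth. Defaults, chosen once:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 26 | participants with all three compartments |
| `sigma` | 0.3 | log-normal intensity dispersion (log-scale SD) |
| `compartment_cor` | 0.5 | within-participant correlation of log abundance across compartments |
| `measurement_sigma` | 0.1 | extra multiplicative noise when rendering peaks |
| `ppm_jitter` | 3 ppm | uniform m/z jitter |
| `missing_rate` | 0.02 | study peak drop probability |
| `n_blanks`, `blank_level` | 4, 0.002 | blank wells at 0.2% of mean study signal |
| `qc_dilutions`, `qc_replicates`, `qc_sigma` | 0.25/0.5/1.0, 2, 0.05 | pooled-reference dilution series |
| `motility_range` | 24–68% | uniform progressive-motility draw |

Log-normal multiplicative noise is the standard model for MS
intensities; the inter-compartment correlation is induced by a shared
per-participant, per-variable log-scale effect with weight
`sqrt(compartment_cor)`. Class-abundance profiles are *ordering-faithful*
transcriptions of the qualitative compartment contrasts (serum rich in
TG, PC, PC-O, CHOL, CE; sperm and seminal fluid rich in SM, CER, PE-O,
PE-P, LPE, PG; LPC, PE, PI, PS similar), with a saturation tilt inside
the FA panel (serum towards PUFAs, sperm/seminal fluid towards C20–22
long-chain FAs). The numbers are illustrative: only the
ordering of the compartment contrasts is claimed, not any measured
abundance. Spiked effects (per variable,
optionally per compartment or motility group) multiply abundance
*before* renormalization, so a nominal 2-fold spike realizes slightly
under 2-fold after closure — visible in the acceptance script's
`spike_mean_log2fc` being a few percent below 1.

The library generator draws sum compositions per class from even-carbon
grids whose carbon and double-bond ranges are chosen so that no two
default entries fall within 30 ppm at any shared-channel adduct; this
makes the ±9 ppm tolerance window unambiguous by construction, which in
turn makes recall statements exact (100% within ±9 ppm, 0% at +10 to
+20 ppm). Carbon parity and range separation keep the exact-isobar
families apart (PC/PE, PE-O/PE-P, LPC/PC-O, LPE/PE-O, DG/CE, PE/PS,
PG/SM); the deliberately planted pairs — PC(34:1)/PE(37:1), a chemically
exact isobar, and PC(34:2)/PS(31:2) with a synthetic 2 ppm mass offset —
are opt-in (`plant_isobars = TRUE`) and exist to probe the priority
rules. Cholesterol admits exactly one species, so `species_per_class`
acts as a per-class cap.

All randomness flows from the single spec seed (library: `seed`;
cohort: `seed + 1`; peak rendering: `seed + 2`) with no global RNG
side effects, so identical specs reproduce bitwise-identical run
directories.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: profile spectra and peak picking, isotope
envelopes, ionisation-efficiency differences between classes, in-source
fragmentation, plate-position and batch drift, correlated missingness
(censoring at the detection limit rather than at random), BMI/glycaemia
covariates, and any biological covariance structure beyond one shared
per-participant effect.

## Problem sizes and numerical choices

The tests and acceptance script run at these sizes, chosen to make the
statistical checks meaningful: null type-I calibration uses the full
composition grid (2064 variables) over 50 replicate cohorts (103,200
paired and unpaired tests each); spike recovery uses 24 spiked
variables across the three channels in 10 replicate cohorts at n = 26
pairs; filter-oracle equivalence uses 200 random 20 × 50 matrices;
round-trip recovery uses the default cohort with a low-noise rendering
(`measurement_sigma = 0.02`) and judges correlation per sample row of
each channel's matrix, since each channel renormalizes independently.

Other numerical conventions: per-mille conservation is asserted at 1e-9
relative tolerance; ties in isobar resolution are broken
deterministically (priority, |ppm|, name, adduct); zero-variance
variables are dropped before autoscaling; a zero row total is an error
naming the sample, never a silent NaN; all output tables are written
with `readr` defaults, which are deterministic, so reruns are
byte-identical.

## Known limitations

* Sum-composition identification only; isobars are resolved by prior
  plausibility, not by fragmentation evidence, and the `ambiguous` flag
  should be consulted before biological interpretation of any single
  species.
* S/N against blank wells is one of several defensible noise
  definitions; with no blanks the rule silently passes everything.
* The fixed p < 0.001 limit is inherited, not derived; users wanting a
  principled FDR should treat the p values in the results table as raw
  and apply their own correction.
* The t-test's far-tail conservativeness on skewed abundance data means
  the effective size at p < 0.001 is below nominal; power statements
  from the synthetic cohorts transfer to real data only to the extent
  that real per-mille abundances are approximately log-normal with
  dispersion near the defaults.
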