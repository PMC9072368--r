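---
title: "Methods: quantitative mRNA m5C mapping and comparative analysis"
author: "m5Cquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative mRNA m5C mapping and comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5Cquant)
```

## The measurement problem

RNA bisulfite sequencing reads out 5-methylcytosine (m5C) indirectly:
bisulfite converts unmethylated cytosines to uracil (sequenced as T),
while methylated cytosines resist conversion and stay C. An m5C site is
therefore a transcript position where aligned reads show C far more
often than the residual non-conversion noise can explain. Two noise
sources dominate: a small per-base non-conversion rate (typically
0.1–1%, varying by gene), and occasional reads that escape conversion
almost entirely and show C at every covered cytosine. Left unfiltered,
the second class mimics clustered methylation and is the main source of
false positives.

`m5Cquant` implements site calling against both noise sources, plus the
downstream comparative analyses a study of m5C across development and
species needs: motif-based classification of sites into the
NSUN2-dependent (Type I) and NSUN6-dependent (Type II) classes, metagene
density and GC profiles, cross-species conservation calls through an
ortholog map, base-pairing metaprofiles with a bootstrap comparison
test, a logistic model of methylation gain and loss, and quantification
of targeted amplicon bisulfite assays of substrate pools.

## The calling model

For replicate reads reduced to per-cytosine observations (position,
C/T state, base quality), `callSites()` applies, per replicate in which
a position is adequately covered:

1. **Coverage**: high-quality (Q ≥ 30) C+T coverage ≥ 20.
2. **Variant count**: ≥ 3 high-quality C observations.
3. **Level**: mismatch frequency (C/(C+T)) ≥ 0.1.
4. **C-cutoff survival**: reads carrying more than `c_cutoff` (default
   3) unconverted Cs are removed wholesale, and the three bounds above
   must still hold afterwards. The cutoff is chosen with
   `selectCCutoff()`: the Gini coefficient of candidate-site levels is
   tracked across cutoffs and the smallest cutoff at which it
   stabilizes (adjacent change < 0.02) is taken.
5. **Signal ratio**: the fraction of the site's high-quality C signal
   carried by surviving reads must be ≥ 0.9.
6. **Conversion-resistant genes**: genes whose non-conversion rate
   exceeds 5% over ≥ 50 informative observations are suppressed.
7. **Binomial test**: one-sided exact upper tail of
   Binomial(coverage, gene-specific non-conversion) at the post-filter
   counts, p < 0.001. Gene rates exclude candidate positions to avoid
   circularity; genes with < 50 informative observations inherit the
   library-wide rate, and a perfectly converted gene's rate is clamped
   to 0.5/(n+1) so the test stays defined.

With two covered replicates, the Stouffer-combined p-value
(`stoufferCombine()`) must additionally be < 0.001; a site adequately
covered in only one replicate needs at least five variant Cs there.
Every candidate position (≥ 1 high-quality C in either replicate)
appears exactly once in the filter audit, either as `emitted` or with
its first failing filter in the order above — the audit is the primary
debugging surface.

### Numerical choices

* The binomial tail is computed by `pbinom(c - 1, n, p, lower.tail =
  FALSE)` (exact, no normal approximation); Stouffer combination uses
  `qnorm(..., lower.tail = FALSE)` to keep precision at small p.
* Extreme per-replicate p-values are clamped into the open unit
  interval before combination.
* Coordinates are 0-based half-open internally and 1-based in TSV
  exports.
* Boundary semantics are inclusive where the thresholds are stated as
  inequalities: a signal ratio of exactly 0.9 passes, a read with
  exactly `c_cutoff` unconverted Cs is retained.

## Classification and motif registration

A called site is Type II iff its four downstream bases read U, C, N, A
(+1 = U, +2 = C, +4 = A; +3 free); everything else, including sites too
close to the transcript 3' end for the motif to fit, is Type I. The
literature describes the Type II context both as "5'-CUCNA-3' with the
methylated C underlined" and as a "downstream UCCA motif"; these two
readings place the motif at different registers. We implement the
downstream reading, which is the one consistent with the observation
that position +3 of the core motif tolerates non-cytosine bases, and
expose the centered alternative behind
`classifySites(registration = "cucna_centered")`. Note that with three
of four downstream positions fixed, exactly 4 of the 256 possible
downstream 4-mers classify as Type II. Flanks are clipped, never
padded, and `positionFrequencyMatrix()` counts only positions actually
present.

## Metagene profiles

Transcripts are divided into region-proportional bins: the 5'UTR is
fixed at `n_utr5` bins (10 by default) and CDS/3'UTR bin counts are
their mean lengths relative to the mean 5'UTR length, rounded half away
from zero (mean lengths 100/500/400 give the familiar 10:50:40 human
layout). A position maps through its region-local fractional coordinate
`f = offset / region_len` to `floor(f * n_region)`, clamped to the
region's last bin, so bins partition the transcript and boundary
positions stay in their own region. Per-bin density is the m5C count
over the background covered-C count; empty background bins yield `NA`
rather than 0. Background Cs are coverage-filtered by default (the
same ≥ 20 filter as calling), switchable by supplying a different
background table. Transcripts without UTR annotation are excluded, not
imputed; the unbinnable count is attached to the profile.

## Conservation calls

Orthologous cytosines are joined through a precomputed position map
(built externally or by `makeSpeciesPair()`). A pair is **conserved**
when one species is methylated (level ≥ 10%) and the other shows a
level > 5%, both covered by ≥ 10 reads; **species-specific** when
methylated in one and certifiably unmethylated (≥ 20 reads, < 5%) in
the other. The two coverage gates differ deliberately: ≥ 10 reads
admits a pair into the comparison, while the stricter ≥ 20 is required
to certify absence of methylation — both published thresholds can then
hold simultaneously. Everything else is indeterminate, and non-C bases
are excluded from the methylation comparison but kept for
substitution-rate profiles. Summaries report the conserved percentage
against both defensible denominators (determinate pairs, and all paired
Cs).

## Structure analysis and the gain/loss GLM

Dot-bracket structures are inputs; when none are provided,
`foldMinimal()` — a maximum base-pairing dynamic program over
AU/UA/GC/CG/GU/UG with a minimum hairpin loop of 3 nt, implemented in
C++ with an exhaustive-enumeration oracle in the tests — supplies them.
It is a combinatorial stand-in, not a thermodynamic model: folding
temperature is carried as metadata for an external folder and ignored
by the minimal one.

`bootstrapPairingTest()` follows the down-sampling scheme: 100
structures per group, per-position pairing frequencies, 1000
repetitions, then a per-position Student's t-test between the two
replicate samples. Down-sampling is without replacement ("down-sample"
read literally). The one-sided direction is not specified by the
procedure itself, so we set it from the sign of the full-data frequency
difference and report both one- and two-sided p-values.

The gain/loss GLM uses sites methylated in exactly one species (C at
the DNA level in both): the methylated species' context is a positive
example, the other a negative one. Features are binary: base identity
at offsets −2..+5 (the site itself omitted — always C) one-hot coded
with a reference category dropped, plus per-position paired status over
±50 nt for Type I (101 bits; 122 features total) or −20..+20 for Type
II (41 bits). No interactions. The reference category defaults to a
fixed base (`A`) so that simulated and refitted designs align by
construction; dropping the per-position modal base instead is available
for data analysis. `fitLogistic()` is iteratively reweighted least
squares on the (optionally ridge-stabilized, default 1e-6) Bernoulli
likelihood, converging when the largest coefficient change drops below
1e-8; complete separation without ridge is reported as
non-convergence, never returned silently. With ridge 0 it matches
`stats::glm` to 1e-6 on small instances, which the tests assert as an
independent oracle.

## Targeted mutagenesis assays

`assignReads()` matches amplicon BS reads to substrate variants by
Hamming distance against C-to-T converted references (exact-match fast
path, distance ≤ 5, ties discarded), `dedupeBarcodes()` keeps reads
whose barcode is unique in both the BS and DNA libraries, and
`variantLevel()` computes C/(C+T) at the assayed site.
`motifSeries()` summarizes levels by motif G count and per motif
position. One synthetic-design note: all 256 motif 4-mers cannot be
distinguished after bisulfite conversion (motif C and U both read T),
so `makeSubstratePool()` embeds a unique per-variant tag drawn from
{A, G, U} — bases unaffected by conversion — away from the motif, and
validates the converted references for collisions. Real pools must
satisfy the same identifiability requirement through their own design.

## What the synthetic generator does and does not emulate

`makeTranscriptome()`, `plantTruth()`, `simulateReads()` and
`makeSpeciesPair()` reproduce the statistical structure the caller
assumes: per-gene conversion around 99–99.9%, a minority (default 2%,
deliberately a placeholder — real libraries are usually cleaner) of
all-or-none conversion-failure reads, planted levels ≥ 10% in
classifiable Type I / Type II contexts, two replicates, Phred qualities
as a Q37/Q20 mixture exercising the Q ≥ 30 filter, and species pairs
related by independent point substitutions with methylation retention
drawn from a known logistic model. Default transcript regions are
220/1100/880 nt — a human-like ~2.2 kb mRNA with the 1:5:4 region
ratio of the human metagene layout, large enough at 200 genes to
provide over 1e5 covered background cytosines.

They do **not** emulate spliced alignment, indels, PCR duplicates,
sequencing-error substitutions beyond the quality mixture, coverage
biases, or thermodynamic folding, so green tests here demonstrate
correctness of the statistical machinery on its stated model, not
robustness to every artifact of real libraries.

### A known interaction worth understanding

With all-or-none conversion-failure reads at fraction *f*, a true site
with level *L* and coverage *n* accumulates about *f·n* spurious C
reads that the C-cutoff correctly removes; the signal ratio is then
roughly `L·n / (L·n + f·n)`, which at `f = 0.02` dips below the 0.9
threshold with appreciable probability once `L ≲ 0.3`
(`P(Binom(60, 0.02) ≥ 2) ≈ 0.34` against 12 true C reads at `L = 0.2`).
Under these simulation settings the caller's sensitivity for low-level
sites is therefore bounded near 0.8 — not a defect of either filter in
isolation but a direct consequence of combining a strict signal-ratio
gate with a noticeable conversion-failure fraction. On real libraries
with `f` well below 1% the effect is negligible; analysts working with
poorly converted libraries should weigh relaxing `min_signal_ratio`
against the false-positive protection it buys. The test suite asserts
the strict joint condition and the corresponding expectation is
documented as failing by design at `f = 0.02`.

## Problem sizes and determinism

The shipped tests and the acceptance script use 200-gene transcriptomes
(~0.44 Mb), coverage 60 with two replicates (~12 million cytosine
observations), 4000-site species pairs, 1000-replicate bootstraps and
256-variant pools — sizes chosen so every statistical property is
measured with comfortable margins while a full run stays in the
minutes range on a single core. All generators take explicit seeds and
are byte-reproducible; the pipeline driver derives per-stage seeds from
one root seed and stamps every output table with the configuration
hash.
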