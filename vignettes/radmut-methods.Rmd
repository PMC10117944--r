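---
title: "Models and methods behind radmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmut)
```

# Scope

`radmut` re-implements, as a tested pipeline, the computational core of
comparative radiation-mutagenesis studies in *Arabidopsis*: harmonizing
variant catalogs produced by several callers over whole-genome resequencing
of M2 plants, filtering candidate sites, classifying mutation events into an
eight-category scheme, computing spectrum and rearrangement statistics, and
fitting target-theory survival curves. Raw sequencing data from such studies
live in external archives and are not shipped or downloaded; instead a
synthetic-data module generates inputs with the statistical structure the
analysis assumes, so every stage can be exercised against a known ground
truth.

# Site filtering and zygosity

Candidate sites pass three filters, with all thresholds exposed in
`filter_config()` and defaulting to the published values:

* **Recurrence.** True induced mutations cannot recur across independently
  derived M2 lines, so a site observed in two or more samples is treated as
  a systematic false positive and removed everywhere. The source studies
  phrase this as "more than two samples" for the small-variant caller but
  select sites "unique to a single sample" for the SV callers; these
  readings conflict for the two-sample case. We default to excluding at
  ≥ 2 samples — the biologically coherent rule for independent lines — and
  expose `recurrence_min_samples_to_exclude = 3` for the literal reading.
  SV endpoints match across samples within ± 10 bp (configurable), since SV
  callers jitter breakpoints.
* **Allele-fraction floor.** Sites with AF ≤ 25% are excluded. The boundary
  is inclusive, exactly as printed.
* **Zygosity with purity.** 25% < AF < 80% is heterozygous and AF ≥ 80%
  homozygous, in both cases requiring AF < 5% in every other sample
  (strict inequality). Sites above the floor that fail the purity check are
  excluded rather than down-called: the published scheme calls nothing in
  that region.

Among M2 carriers the expected homozygous fraction is 1/3 (Mendelian 1 hom :
2 het), which `zygosity_ratio_test()` tests with an exact binomial test.

# Event classification

Every retained record is decomposed into primitive changes by trimming the
common prefix/suffix of REF/ALT. Equal-length remainders are scanned
base-by-base: each mismatching base is a substitution primitive, and runs of
reference-matching bases separate primitives (the published rule treats runs
of ≥ 2 matching bases as unmutated sequence; since clustering re-merges
anything closer than 10 bp, per-base decomposition yields the same events
and the same indel counts — the `separator_run` parameter is retained for
the interface). Unequal-length remainders are a single net indel; a 10-base
deletion with a 3-base insertion of unknown sequence is a 7-base deletion
(`net_indel_length()`).

Primitives on one sample and chromosome merge into a **complex** event when
every inter-change gap is below 10 bp and the cluster holds at least two
changes. Two design points were genuinely open:

* "More than two consecutive SBSs" could mean ≥ 2 or ≥ 3 changes. A
  two-change cluster has no other category in the scheme, so we read the
  rule as ≥ 2 and expose `min_cluster_size = 3` for the literal reading.
* The studies do not bound the indels allowed inside a complex event. We cap
  participating indels at |net| < 10 bp — the same scale as the gap rule —
  so that complex events stay local; larger indels terminate a cluster and
  are categorized on their own.

Simple events map onto: SBS, ±1 bp, insertions/deletions of 2–99 bp, and
deletions ≥ 100 bp. Insertions ≥ 100 bp were not observed in the source
studies and have no category; `categorize()` raises an explicit error rather
than inventing one. Inversions and translocations are **SV**; a mated
breakend pair is one SV event, with junctions stored in canonical
(chromosome, position) order so that multi-caller and truth comparisons are
representation-independent. SV and Del ≥ 100 bp together form the
**rearrangement** class (`group_rearrangements()`), interpreted as rejoining
of two distant double-strand breaks. Complex events are subclassified by
their indel content (0 / 1 / ≥ 2 indels) for cross-treatment comparisons of
complexity. No attempt is made to deduce the overall structure of an SV from
read evidence; `structure_resolved` is metadata, set `FALSE` by the
classifier, and such events are excluded from gene-impact counting as the
source figures do.

# Statistics

* **Mutation frequency** is events per reference bp.
* **SBS spectrum**: complementary substitutions merge into six classes.
  Ti/Tv is transitions over transversions (flagged `NA`, not infinite, when
  no transversions exist). The G:C/A:T ratio of original base pairs is
  compared against genome composition with a one-sample exact binomial test
  on the count of G:C originals with null probability = genome GC content
  (0.36 for the Arabidopsis reference, giving the expected ratio
  0.36/0.64 = 0.56). The test construction is not specified in the source;
  a one-sample test against the fixed composition is the natural choice
  because the comparison is against a constant, not a second sample.
* **Group comparisons**: pairwise 2×2 Fisher exact tests for category
  proportions and one-way ANOVA with Tukey HSD for per-sample means.
  The multiple-comparison method for the exact tests is unspecified in the
  source; we default to Holm (conservative and valid for exact tests), with
  Bonferroni/BH selectable. Compact letter displays use the insert-absorb
  algorithm; letters are consistent with the adjusted significance graph by
  construction, which the test suite verifies against a brute-force check.
  Groups with zero events (Fisher) or fewer than two samples (ANOVA) are
  excluded with a warning. Constant input data are flagged degenerate and
  share a single letter.
* Reporting precision follows the source tables: percentages to whole
  percent, ratios/folds/means to one decimal.

# Survival model

Seedling/seed survival follows single-hit multitarget theory,

$$S(D) = 1 - \left(1 - e^{-D/D_0}\right)^m,$$

with $D_0$ the 37%-survival dose and $m$ the extrapolation number. The
shoulder dose is $D_q = D_0 \ln m$, the x-intercept of the log-linear
high-dose asymptote (an identity the tests verify geometrically).
`fit_survival()` minimizes unweighted squared error on per-replicate
survival fractions — the source states least squares without weights —
with a binomial-weighting option. Starting values come from the classical
graphical method (terminal log-slope → $D_0$; zero-dose intercept of the
asymptote → $m$), making the fit deterministic. Sensitivity between
materials is judged as a ratio of shoulder doses. One source sentence
reports a seedling relative-effectiveness figure (5.9) that does not equal
the ratio of the printed seedling shoulder doses (155/41 ≈ 3.8); the basis
of that figure is unstated, so the package computes $D_q$-based ratios only
and no check is taken from that sentence.

# Synthetic data: the stated world

The generator emulates the statistical structure the analysis assumes:

* i.i.d. genomes at GC 0.36 (the Arabidopsis reference composition);
* Poisson event counts per plant, with default means per treatment equal to
  the published events-per-plant (73, 41, 35, 21 for gamma-dry,
  gamma-seedling, carbon-dry, carbon-seedling);
* eight-way category mixes whose rearrangement mass matches the published
  per-plant rearrangement rates (0.8, 0.9, 1.6, 1.5 events/plant) and whose
  qualitative contrasts follow the published figures (carbon ions richer in
  2–99 bp deletions and rearrangements, gamma richer in SBS, dry-seed
  spectra showing elevated A:T→T:A). The source prints no numeric
  composition vectors, so these mixes are documented as illustrative
  defaults, not estimates;
* six-class SBS mixes with Ti/Tv in the published 0.7–1.1 range and
  G:C/A:T in 0.7–1.8;
* deletion sizes: point mass at 1 bp, log-uniform on 2–99 bp, log-uniform
  on ≥ 100 bp capped at 400 kb and 1/20 of the genome (so large deletions
  remain placeable on test-scale genomes);
* zygosity Bernoulli(1/3) homozygous;
* caller emission: a small-variant caller sees substitutions, short indels
  and complex components; SV callers see large deletions, inversions and
  breakend pairs, each thinned by a per-caller, per-category sensitivity;
  allele fractions are 0.5/1.0 by zygosity, optionally with
  Poisson-depth/binomial-read noise; shared false-positive SNV sites can be
  injected across ≥ 2 samples to exercise the recurrence filter;
* survival assays: binomial survivors at 3 replicates × 30 seedlings per
  dose, the published assay size.

Events within a plant are placed at least 200 bp apart so independent
events never co-cluster under the 10 bp rule; this also means the generator
does not emulate genuinely overlapping or adjacent independent events, nor
mapping artifacts, repeat-mediated miscalls, or coverage dropouts. A green
end-to-end test therefore establishes that the bookkeeping chain
(emission → parsing → filtering → classification → statistics) is lossless
and correctly categorized under the stated world — not that the pipeline
would overcome the alignment-level pathologies of real short-read data.

A single global seed fans out to deterministic per-stage streams
(`run_config()`), so each stage is independently reproducible and a rerun
of the demo is byte-identical.

# Numerical choices and degenerate inputs

* Boundary handling in filters is exactly as printed (AF = 25% excluded,
  AF = 80% homozygous, other-sample AF = 5% fails purity).
* `fit_survival()` refuses designs with fewer than three distinct doses and
  all-survival/all-death tables; non-convergence raises an error carrying
  the starting values.
* Ratios with zero denominators (Ti/Tv without transversions, G:C/A:T
  without A:T originals, SV fold from zero) are flagged `NA`, never
  infinite.
* Catalog TSVs round-trip byte-identically; coordinates are 1-based closed
  throughout, matching VCF POS/END; symbolic deletions and explicit-allele
  deletions normalize to the same internal representation, so
  classification depends on content, not on caller dialect.

# Known limitations

* Gene impact counts genes overlapped by qualifying events; codon-level
  synonymous/non-synonymous prediction is out of scope, so counts are an
  upper bound on genes with non-synonymous mutations. For translocations
  and breakend-defined inversions only the junction points (± 1 bp) count
  as affected loci (configurable in spirit; whole-segment counting for
  inversions was not used by the source figures as far as stated).
* The per-caller AF extraction convention (AD/DP, falling back to
  alt-reads/depth) is package plumbing; the source does not state how AF
  was extracted per caller.
* Read-level simulation (FASTQ) and alignment are out of scope.
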