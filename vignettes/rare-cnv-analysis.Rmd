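---
title: "Methods: rare CNV burden, recurrence and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare CNV burden, recurrence and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the parameter defaults and
the reasons behind them, what the synthetic-cohort generator does and does
not emulate, and the numerical choices made in the implementation. Every
number quoted here is computed by the package's test suite or by
`scripts/acceptance.R`; the vignette adds no empirical claims of its own.

## Pipeline model

The package operates on CNV calls produced by an HMM-based caller from
SNP-array intensities (the PennCNV output dialect is parsed by
`read_cnv_calls()`). All coordinates are 1-based and inclusive:
`size = end − start + 1`, and two intervals overlap iff they share at least
one base. BED input (0-based, half-open) is converted at the boundary by
`bed_to_tibble()` and `read_gene_models()`.

### Sample quality control

`apply_qc()` excludes a sample iff its raw call count exceeds
`max_num_cnv = 30` or its LogR-ratio standard deviation exceeds
`max_lrr_sd = 0.24`. Both comparisons are strict: a sample at exactly 30
calls or exactly 0.24 passes. The count is taken on raw, pre-merge calls
(`compute_num_cnv()`), because over-segmentation noise is precisely the
signal the threshold screens for; merging first would mask it.

### Call post-processing

`process_calls()` applies, in order:

1. **Merging** (`merge_adjacent()`): within one (sample, chromosome, state),
   adjacent calls `A`, `B` (sorted by start) merge iff
   `gap < span / 2`, where `gap = start_B − end_A − 1` and
   `span = end_B − start_A + 1`; the scan repeats until no pair merges.
   Algebraically `gap < span/2` is equivalent to `gap < size_A + size_B`,
   which is how one can reason about which intervals can ever coalesce.
   Deletions never merge with duplications; overlapping opposite-state calls
   are both kept with a warning (they usually flag sample artifacts).
   Marker counts of merged calls are recounted from the marker map when one
   is supplied, otherwise summed. Calls with different copy numbers but the
   same state (e.g. cn 0 and cn 1) merge on state, with a message.
2. **Marker filter** (`filter_min_snps()`): calls supported by fewer than
   `min_snps = 10` markers are dropped — below that, HMM calls are
   dominated by false positives. The comparison is `>=`, so a 10-marker
   call survives.
3. **Region exclusion** (`exclude_regions()`): calls overlapping annotated
   centromeres or telomeres by ≥ 1 bp are dropped; intensity artifacts
   concentrate there.

Sizes are binned `<10 kb`, `10–100 kb`, `100–500 kb`, `>500 kb`; each bin
includes its upper bound, so a 500,000 bp call is `100–500 kb` and the
large class is strictly `> 500,000`.

### Burden statistics

The headline comparison is carrier-based, not event-based: for a size bin,
`a` of `n₁` cases and `c` of `n₂` controls carry at least one call
(`carrier_table()`; a double carrier counts once). `fisher_one_sided()`
computes the exact hypergeometric upper tail `P(X ≥ a)` with all margins
fixed — one-sided because the hypothesis (excess burden in cases) is
directional. The mid-p variant (`p − ½·P(X = a)`) is available via
`mid_p = TRUE` but is not the default, the standard tail being the
conservative convention.

`carrier_excess_ci()` reports the excess in percentage points with the
unpooled Wald 95% interval. Values are kept unrounded internally and
displayed at one decimal; for carrier counts 25/179 vs 15/234 this gives
an excess of 7.6 with interval (1.6, 13.5). Note that rounding the point
estimate and margin *before* adding them yields 13.6 — a display-order
artifact worth knowing about when comparing against hand-computed tables.
`odds_ratio_ci()` uses `ad/bc` with Woolf's log-normal interval and the
Haldane–Anscombe +0.5 correction when any cell is zero.

`build_burden_table()` reports per-bin event counts and per-individual
frequencies (`count / n`) descriptively alongside the carrier p-values.

### Recurrence

`recurrent_genes()` reports genes whose exons are hit (≥ 1 exon base;
intron-only overlap does not count) by CNVs of a size class in at least
`min_cases = 2` distinct cases, with **zero** control calls of any size or
state on their exons. Two cases are enough to be noteworthy because large
rare CNVs are individually so infrequent; the zero-control rule is strict
because a single control carrier undermines a causal interpretation. Case
hits are not required to share state — the deletion/duplication composition
is reported (`n_del`, `n_dup`) rather than enforced.

### Stratification checks

`pc_association()` correlates the 0/1 carrier indicator with ancestry
principal components (point-biserial `r`, exact t-transform p-value,
two-sided, no multiplicity correction — the check is diagnostic, not
confirmatory). `batch_association()` applies a two-sided Fisher exact test
to the carrier-by-batch 2×2.

### MLPA validation and trios

MLPA reports one normalized ratio per probe relative to the two-copy state.
`call_mlpa_cnv()` turns maximal runs of consecutive probes with ratio
`<= 0.75` into one deletion call and `>= 1.30` into one duplication call.
The exact normalization of any given assay varies, so these are
conventional single-copy loss/gain thresholds — roughly midway between the
expected 0.5/1.5 and the diploid 1.0, asymmetric because gain (1.5/1.0) is
a smaller relative change than loss (0.5/1.0); both are tunable arguments.
Probes labelled `REF` are reference probes, excluded from calling and used
only for a sanity message when they stray from 1.0.

`classify_inheritance()` calls parents on the same probes: a parent carries
the proband's variant iff it has a same-state call in the same gene sharing
at least one affected probe (MLPA cannot resolve breakpoints, so exact
coordinate equality is not required). Verdicts are `DE_NOVO`,
`INHERITED_PATERNAL`/`MATERNAL`/`BOTH`, or `UNRESOLVED` when a parent has
no measurements. `aggregate_gene_counts()` combines SNP-array cases,
MLPA-only additional cases and a follow-up cohort per gene without
double-counting validations, and applies the one-sided exact test to the
aggregated totals.

## The synthetic-cohort generator

`simulate_cohort()` exists so every pipeline stage can be tested end to end
with known truth. Its design goal is *exact recoverability*: with the
default configuration, running QC, merging, the marker filter and region
exclusion on its output reproduces the planted call set with zero
discrepancies. The test suite and `scripts/acceptance.R` assert this.

**Genome layout.** 22 autosomes of 25 Mb with markers every 4 kb. Each
chromosome is partitioned into non-interacting zones: p/q telomeres and a
centromere (the excluded regions), a gene zone (2–5.5 Mb), a zone of 2-Mb
slots for planted large CNVs (6–12 Mb) and a background zone (14–23.5 Mb).
Because two calls can only ever merge when their gap is below the sum of
their sizes, and the inter-zone gaps exceed the largest possible size sum,
nothing merges across zones — planted features cannot contaminate each
other. Large case calls occupy odd-indexed slots and control calls
even-indexed ones, so planted case regions are control-free by
construction.

**Defaults** (`simulation_config()`) emulate a two-population case-control
study after QC: 179 cases and 234 controls, a Poisson mean of 3.5 final
calls per subject, 60% deletions among background calls, log-normal
background sizes truncated to 44–450 kb, large-CNV carrier rates of 14%
(cases, two of them double carriers) versus 6.4% (controls) realized as
`round(rate × n)` — 25 vs 15 carriers — with a duplication excess among
large calls, one recurrent large-duplication gene hit in 4 cases and one
recurrent small-deletion gene hit in 2 cases, 15% of calls emitted as 2–3
fragments the merge stage must reassemble, 8 QC-outlier samples, and decoy
calls exercising the marker filter and the region exclusion.

**What it does not emulate.** Markers sit on a uniform 4 kb grid, so every
true call has ≥ 10 markers and no final call can be smaller than ~40 kb:
the `<10 kb` bin of a simulated cohort is empty, unlike real array data.
There is no LRR/BAF signal level — QC statistics are planted directly.
Breakpoint uncertainty, polymorphic CNV regions, segmental duplications and
X/Y chromosomes are out of scope. Carrier counts are exact by construction,
not sampled, so the generator demonstrates pipeline correctness, not
sampling variability (the calibration properties of the test itself are
checked separately by simulation from binomial nulls). MLPA ratios default
to noiseless 0.5/1.0/1.5 so trio recovery is deterministic; `mlpa_noise_sd`
adds Gaussian noise when wanted.

## Numerical choices

- The exact tail is summed with `stats::dhyper()` over the support —
  numerically stable and, per the test suite, within 10 significant digits
  of direct `choose()` enumeration for every 2×2 table with `N ≤ 60`.
  `stats::fisher.test()` is used only as an independent cross-check in
  tests, never as the implementation (its two-sided definition and its
  conditional-MLE odds ratio differ from the conventions used here).
- Merging is implemented as an adjacent-pair scan iterated to a fixed
  point; tests verify it against an any-pair fixed-point oracle on
  exhaustive small instances, confirming order independence.
- Marker recounting uses a per-chromosome sorted position index with
  `findInterval()` (binary search) rather than scanning the map per call.
- Interval overlap is delegated to Bioconductor's `IRanges` behind a small
  wrapper; the tibble-based interfaces never expose those classes.
- All statistics are returned unrounded; rounding happens only in print
  methods, to avoid compounding display rounding into downstream numbers.

## Limitations

The one-sided test is appropriate only for the directional burden
hypothesis; reusing it for non-directional questions would be
anti-conservative. The Wald excess interval is a large-sample
approximation — its ≥ 93% empirical coverage at the default cohort sizes
is asserted by the test suite, but it degrades for very small carrier
counts (where the exact test, not the interval, should carry the
inference). PC and batch checks are association diagnostics, not
adjustments; a confounded cohort needs matched reanalysis, not a p-value.
Gene hits are exon-overlap based and do not model regulatory disruption.
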