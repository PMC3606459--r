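# rarecnv

Burden and recurrence analysis of rare copy-number variants (CNVs) in
case-control cohorts, from raw SNP-array caller output to the headline
statistics: sample quality control, call post-processing (merging of
over-segmented calls, marker and region filters), size-stratified burden
tables, a carrier-level exact test, case-only recurrent gene regions,
stratification checks, MLPA-based validation with trio inheritance
classification, and a synthetic-cohort generator with planted ground truth
for end-to-end verification.

All tabular inputs and outputs are tibbles, so every step chains with the
pipe and standard dplyr verbs; fitted test objects provide broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()`/`plot_*()` graphics.

## The scientific problem

Rare CNVs — deletions and duplications of genomic segments relative to the
diploid state — are a recognized source of risk for neurodevelopmental
disorders. A typical study design calls CNVs from SNP-array intensity data
(e.g. with PennCNV) in cases and controls, then asks three questions:

1. **Burden**: do cases carry more CNVs than controls, overall or in a size
   class? Large (>500 kb) events are of particular interest because they are
   rare, gene-rich and under strong negative selection.
2. **Recurrence**: are specific genes disrupted by CNVs in multiple
   independent cases but never in controls?
3. **Origin**: are candidate variants inherited or de novo, established by
   re-assaying probands and parents with a targeted method (MLPA)?

Raw caller output cannot answer these directly: noisy samples inflate
counts, the HMM over-segments large CNVs into fragments, and calls in
centromeric/telomeric regions or supported by few markers are unreliable.
The pipeline here implements the standard post-processing and the exact
statistics on what remains.

## Core model

Coordinates are 1-based and inclusive throughout, so a call on
`[start, end]` has size `end − start + 1`.

**Quality control.** A sample is excluded iff `NumCNV > 30` or
`LRR_SD > 0.24`, where `NumCNV` is its raw (pre-merge) call count and
`LRR_SD` the standard deviation of its LogR ratio.

**Merging.** Within one (sample, chromosome, state), two neighbouring calls
`A`, `B` are merged iff

```
gap(A, B) < span(A, B) / 2
```

with `gap = start_B − end_A − 1` and `span = end_B − start_A + 1`,
repeated left-to-right to a fixed point. Merged calls are then filtered:
calls with fewer than 10 markers and calls overlapping centromeres or
telomeres (by ≥ 1 bp) are dropped. Sizes are binned as `<10 kb`,
`10–100 kb`, `100–500 kb` (inclusive of 500,000) and `>500 kb`.

**Carrier test.** For a size bin, let `a` of `n₁` cases and `c` of `n₂`
controls carry ≥ 1 call. With all margins fixed, the one-sided exact
p-value is the hypergeometric upper tail

```
p = P(X ≥ a) = Σ_{k ≥ a} C(a+c, k) · C(n₁+n₂−a−c, n₁−k) / C(n₁+n₂, n₁)
```

(`fisher_one_sided()`, with an optional mid-p variant). The carrier excess
`Δ = 100·(a/n₁ − c/n₂)` percentage points gets the unpooled Wald interval
`Δ ± 1.96·100·√(p₁(1−p₁)/n₁ + p₂(1−p₂)/n₂)`, and the odds ratio `ad/bc`
gets Woolf's log-normal interval (Haldane–Anscombe +0.5 correction when a
cell is zero).

**Recurrence.** A call hits a gene iff it overlaps ≥ 1 exon base
(intron-only overlap does not count). A gene is reported iff hit by calls of
the chosen size class in ≥ 2 distinct cases and its exons are overlapped by
zero control calls of any size.

## Worked example

The generator emits a full synthetic cohort — raw calls, sample table,
marker map, gene models, excluded regions — with the planted truth attached:

```r
library(rarecnv)
library(dplyr)

sim  <- simulate_cohort(simulation_config(seed = 7))
qc   <- apply_qc(compute_num_cnv(sim$samples, sim$calls))
pass <- qc_passing(qc)
nrow(qc_excluded(qc))   # 8 samples fail QC, leaving 413

final <- sim$calls |>
  semi_join(pass, by = "sample_id") |>
  process_calls(sim$marker_map, sim$regions, quiet = TRUE)
# 1754 raw calls -> 1457 merged, filtered calls

build_burden_table(final, pass)
#> CNV burden: 179 cases, 234 controls
#> # A tibble: 5 × 6
#>   size_bin   count_case freq_case count_control freq_control p_value
#>   <chr>           <int>     <dbl>         <int>        <dbl>   <dbl>
#> 1 <10 kb              0      0                0         0     1
#> 2 10-100 kb         320      1.79           402         1.72  0.16
#> 3 100-500 kb        302      1.69           391         1.67  0.84
#> 4 >500 kb            27      0.15            15         0.06  0.0083
#> 5 Total             649      3.63           808         3.45 NA

carrier_test(final, pass)
#> Carriers of >500 kb CNVs: 25/179 cases (14.0%) vs 15/234 controls (6.4%)
#> Excess in cases: 7.6% (95% CI 1.6-13.5%)
#> One-sided Fisher p = 0.0083; OR = 2.37 (95% CI 1.21-4.64)

recurrent_genes(final, pass, sim$genes, "large") |> select(-case_calls)
#> # A tibble: 1 × 6
#>   gene   size_class n_cases_hit n_control_hits n_del n_dup
#>   <chr>  <chr>            <int>          <int> <int> <int>
#> 1 GENE01 large                4              0     0     4
```

`carrier_test()` objects tidy into one-row tibbles (`tidy()`, `glance()`)
and the burden table plots with `autoplot()`. Real PennCNV output enters the
same pipeline through `read_cnv_calls()`; MLPA validation and trio
classification are covered by `call_mlpa_cnv()`, `classify_inheritance()`
and `aggregate_gene_counts()` (see the vignette in `vignettes/`).

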