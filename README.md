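# hmrkit

Comparing whole-genome bisulfite methylomes between two cell types:
hypomethylated-region (HMR) calling, cross-tissue HMR overlap
classification, methylation profiling, motif enrichment, and
ChIP-peak methylation annotation — with a synthetic two-tissue genome
generator so the entire pipeline is testable against planted truth.

Intended users are epigenomics analysts who have per-CpG methylation
count tables (chrom, position, strand, context, methylated reads,
total reads) for two samples — e.g. keratinocytes at ~36X and dermal
fibroblasts at ~91X — plus interval tracks (CpG islands, repeats, motif
occurrences, ChIP peaks) and gene models, and who want the comparative
region-level analyses those data support.

## What it computes

**HMR calling.** A two-state HMM over each chromosome's ordered CpGs.
Emissions are beta-binomial: for methylated/total counts `(m, n)` in
state `s`,

    P(m | n, α_s, β_s) = C(n, m) · B(m + α_s, n − m + β_s) / B(α_s, β_s)

so evidence scales with coverage and zero-coverage sites are carried
as uninformative. Fitting is Baum–Welch (exact transition updates, a
moment-seeded likelihood-ascent M-step for the Beta shapes, states
relabelled so state 1 is hypomethylated); decoding keeps maximal runs
of CpGs with hypo posterior > 0.5, splits runs at gaps > 1 kb, and
drops runs with < 4 CpGs.

**Overlap taxonomy.** Connected components of the A–B overlap graph,
classified as S1 (tissue-specific), C1 (shared boundaries within a
tolerance τ), C2 (one shared boundary; the extra span is the
*extension*), C3 (1:1, no shared boundary), C4 (1:many), C5
(many:many), with per-class counts, bp totals and genome fractions.

**Profiles.** Level classes (<10%, 10–50%, >50%), per-feature means
(Promoter −2..0 kb, Upstream −12..−2 kb from the TSS, UTRs, exons,
introns), the four-level summary of a two-tissue comparison
(common ≪ own-specific < other-tissue footprint < background),
region-scaled heat-map matrices, and neighbour-CpG Pearson correlation
by distance.

**Motif enrichment.** For a motif with `N` genome-wide occurrences and
`OCC_obs` of them overlapping a region set of `L_r` bp in an `L_g` bp
genome:

    OCC_exp = N · L_r / L_g,    E = OCC_obs / OCC_exp

**Peak annotation.** A peak is hypomethylated in a tissue when ≥ φ
(default 0.5) of its length lies in that tissue's HMRs; the two flags
give unmethylated-in-both / methylated-in-both / differential states,
cross-tabulated against genomic features and CGI context.

## Worked example

```r
library(hmrkit)

sim <- simulate_two_tissues(sim_config(seed = 1))  # 2 Mb, ~23,500 CpGs
hmr_a <- call_hmrs(sim$A)   # tissue A, 36X
hmr_b <- call_hmrs(sim$B)   # tissue B, 91X
cmp <- compare_sets(hmr_a, hmr_b, sim_config()$chrom_sizes, tau = 20)
print(cmp)
```

```
HMR comparison (tau = 20 bp, genome 2e+06 bp)
       class n_components n_hmrs_a n_hmrs_b  bp_a  bp_b frac_a frac_b
        S1_A           15       15        0 12838     0 0.642% 0.000%
        S1_B           15        0       15     0 11596 0.000% 0.580%
          C1           30       30       30 27844 27844 1.392% 1.392%
 C2_A_LONGER           10       10       10  8814  6143 0.441% 0.307%
 C2_B_LONGER           10       10       10  6102  8656 0.305% 0.433%
          C3            4        4        4  5298  3867 0.265% 0.193%
          C4            4        8        4  4549  6649 0.227% 0.332%
          C5            2        4        4  2505  2510 0.125% 0.126%
```

The simulator planted exactly 30 common, 15 + 15 tissue-specific,
10 + 10 extension, 4 + 4 + 2 complex templates — every component is
recovered in its planted class. The four characteristic methylation
levels of a two-tissue comparison come back within noise of their
planted values (0.03 / 0.25 / 0.60 / 0.70):

```r
four_level_summary(cmp, sim$A, sim$B)
```

```
  tissue      class mean_level n_cpg
1      A     common 0.03040743  4338
2      B     common 0.02899126  4338
3      A     ts_own 0.24840632  1108
4      B     ts_own 0.24932227  1026
5      A   ts_other 0.60594313  1026
6      B   ts_other 0.60143518  1108
7      A background 0.69794582 16109
8      B background 0.69943330 16109
```

Adjacent CpGs are strongly correlated and the correlation decays with
distance, as in real methylomes:

```r
head(neighbor_correlation(sim$A), 3)
#   bin_start bin_end         r n_pairs
# 1         0      10 0.8951024    6619
# 2        10      20 0.8880839    7535
# 3        20      30 0.8826014    7463
```

A motif planted at 5-fold density inside A-specific HMRs scores E ≈ 5
there and ≈ 1 elsewhere; called-vs-planted HMR agreement is
base-level Jaccard 0.997 (A) / 0.998 (B).

The whole pipeline — simulate, call, compare, profile, enrich, annotate
peaks, with an md5 manifest of every output — runs from one config:

```r
res <- run_pipeline(pipeline_config(out_dir = "out", seed = 1))
# or: Rscript scripts/run_pipeline.R --out-dir out --seed 1
```

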