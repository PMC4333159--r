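---
title: "Comparing two methylomes with hmrkit: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two methylomes with hmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmrkit)
```

# The problem

Whole-genome bisulfite sequencing yields, for every CpG, a methylated
read count and a total read count. In differentiated mammalian cells
most CpGs are heavily methylated, but regulatory sequence sits in
*hypomethylated regions* (HMRs): contiguous clusters of CpGs whose
methylation falls far below the genomic background. When two cell types
are profiled — say keratinocytes at roughly 36X and dermal fibroblasts at
roughly 91X — three questions arise:

1. Where are each tissue's HMRs?
2. How do the two HMR sets relate — which regions are shared, which are
   tissue-specific, which share one boundary but extend further in one
   tissue?
3. What distinguishes these region classes: methylation level
   composition, genomic context, transcription-factor motif content,
   and the methylation state of ChIP-seq binding sites?

`hmrkit` implements this comparison as a reusable pipeline and ships a
synthetic two-tissue genome generator with planted ground truth, so
every stage is testable end-to-end without any sequencing data.

# The segmentation model

HMR calling uses a two-state hidden Markov model over the ordered CpGs
of each chromosome. State 1 is hypomethylated, state 2 is the
methylated background. The emission at a CpG with counts
$(m_i, n_i)$ is beta-binomial,

$$ P(m_i \mid n_i, \alpha_s, \beta_s) = \binom{n_i}{m_i}
   \frac{B(m_i + \alpha_s,\; n_i - m_i + \beta_s)}{B(\alpha_s, \beta_s)}, $$

which respects varying coverage (a site covered by 3 reads is weaker
evidence than one covered by 90) and absorbs site-to-site
overdispersion through the Beta mixing. A site with zero coverage has
likelihood 1 in both states: it occupies a position in the chain but
contributes no evidence.

Inference is scaled forward–backward (implemented in C++ for long
chromosomes; posteriors are exact, validated against exhaustive path
enumeration in the test suite). Parameters are fitted by Baum–Welch:

* Initial and transition probabilities get their exact closed-form
  updates.
* The Beta emission shapes have no closed-form M-step. We compute a
  posterior-weighted method-of-moments estimate from the site levels
  and use it to seed a Nelder–Mead maximisation of the expected
  complete-data log-likelihood; a candidate is accepted only if it does
  not lower that objective. This keeps the familiar moment-matching
  behaviour while preserving the EM guarantee that the log-likelihood
  trace never decreases — a pure moment update can (and in testing
  occasionally does) violate it. Shapes are clipped to
  $[10^{-2}, 10^{3}]$.
* After every iteration states are relabelled so state 1 has the lower
  emission mean; if a single-state dataset collapses both means
  together, the hypo state simply receives vanishing occupancy.

Fitting is deterministic: fixed initialisation (hypo mean 0.25, hyper
mean 0.75, concentration 4, self-transitions 0.99, uniform initial
vector), no random restarts, relative-change tolerance $10^{-4}$, at
most 100 iterations. On the default synthetic genome EM converges in a
handful of iterations.

Decoding is posterior thresholding, not Viterbi: maximal runs of CpGs
with hypo posterior above 0.5 become candidate HMRs, runs are broken at
inter-CpG gaps above `maxgap` (default 1000 bp, so CpG deserts cannot
bridge two regions), and candidates with fewer than `min_cpgs` CpGs
(default 4) are dropped. Each HMR records its span (first CpG to last
CpG + 2 bp), CpG count, unweighted mean level, and the summed hypo
posterior as a score. Transitions are distance-independent
(homogeneous chain); a duration- or distance-dependent variant is out
of scope.

# The overlap taxonomy

Two HMR sets are compared by building the bipartite overlap graph
(edges are ≥ 1 bp overlaps between an A-HMR and a B-HMR; within-tissue
overlaps cannot occur since each set is disjoint) and classifying each
connected component:

| label | meaning |
|---|---|
| S1_A / S1_B | tissue-specific: no partner in the other tissue |
| C1 | 1:1, both boundaries agree within `tau` |
| C2_A_LONGER / C2_B_LONGER | 1:1, exactly one boundary agrees; the non-shared span is the *extension* |
| C3 | 1:1, no boundary agrees (containment or stagger) |
| C4 | one HMR vs several |
| C5 | several vs several |

The boundary tolerance `tau` defaults to 20 bp — below typical intra-HMR
CpG spacing, so "same boundary" means agreement finer than the data's
own resolution; unit tests use `tau = 0` for exactness. The complex
classes are defined structurally (1:1 / 1:many / many:many) because no
finer text definition exists; this is declared as this package's
convention. Genome fractions divide class bp by the sum of the supplied
chromosome sizes. Classification is validated against an independent
quadratic brute-force implementation on a thousand random instances.

# Methylation summaries

* **Level classes.** CpGs are sparsely methylated below 10%,
  low-methylated from 10% to 50% inclusive, highly methylated above
  50%. The inclusive upper boundary follows from reading the bins as
  "<10%", "10 to 50%", ">50%".
* **Feature assignment.** Each position gets exactly one label using
  strand-aware windows: promoter −2..0 kb from the TSS, upstream
  −12..−2 kb, UTRs as exonic bp outside the CDS, with precedence
  Promoter > 5'UTR > 3'UTR > Exon > Intron > Upstream > Intergenic.
  Feature means are unweighted per-CpG averages (per-region weighting
  would be an equally defensible choice; per-CpG is simpler and stated).
* **Four-level summary.** The signature of a two-tissue comparison:
  mean methylation inside the intersection of the two HMR sets
  (shared, near zero), inside a tissue's own specific HMRs (low),
  over the other tissue's specific HMRs (intermediate "footprint"),
  and outside all HMRs (high background).
* **Scaled matrices.** Heat-map input: each region's body rescaled to a
  fixed number of bins plus fixed-width flanks; cells are bin means and
  empty bins are missing, never zero.
* **Neighbour correlation.** All ordered CpG pairs within `max_dist`
  (default 1000 bp, 10 bp bins, consecutive and non-consecutive alike)
  contribute their two levels to their distance bin's Pearson
  correlation; bins with fewer than 3 pairs, or zero variance in either
  margin, are reported missing — a constant methylome has no defined
  correlation, and reporting 0 or 1 would be wrong.

# Motif enrichment

For a motif with $N$ occurrences genome-wide, of which $OCC_{obs}$
overlap a region set of total length $L_r$ in a genome of length $L_g$:

$$ OCC_{exp} = N \cdot L_r / L_g, \qquad E = OCC_{obs} / OCC_{exp}. $$

Overlap is ≥ 1 bp; regions are merged before $L_r$ is computed (which
provably cannot change $OCC_{obs}$); a hit overlapping regions of two
different classes counts once in each class; duplicate hits at the same
coordinates are distinct occurrences. $E$ carries no significance
statement — an optional one-sided binomial tail ($N$ trials at rate
$L_r/L_g$) is available behind a flag as supplementary plumbing.

# Peak annotation

A ChIP peak is hypomethylated in a tissue when at least a fraction
$\varphi$ (default 0.5, inclusive) of its length lies inside that
tissue's HMRs; the two flags give four states (unmethylated in both,
methylated in both, differential either way). Raising $\varphi$ can
only move peaks toward "methylated", a monotonicity the tests assert.
An alternative rule (hypo when the peak's mean CpG level is below 0.25)
is available behind a flag. The full interval is used — plain BED peak
files carry no summit column.

# The synthetic genome

The generator is the pipeline's test bed and defines the conditions all
recovery claims refer to. Defaults: two 1 Mb chromosomes; exponential
inter-CpG gaps with mean 120 bp in background and 12 bp inside planted
segments (HMRs in real data are CG-dense, which is also what makes
segmentation well-posed); per-tissue coverage Poisson with mean 36 (A)
and 91 (B); per-site methylation probability Beta-distributed around
its true mean with concentration $k = 20$, counts binomial. The level
model plants four levels: 0.03 in shared (common) segments — near-total
unmethylation, kept slightly above zero so the Beta noise model stays
non-degenerate; 0.25 inside a tissue's own specific segments (midpoint
of the 10–40% band typical of tissue-specific HMRs); 0.60 over the
same span in the tissue where it is not an HMR; 0.70 in background.
C2 extensions carry 0.15 in the longer tissue (the 10–20% band).
Planted units: 30 common, 15 + 15 tissue-specific, 10 + 10 one-sided
extensions, 4 stagger/containment (C3), 4 one-vs-two (C4), 2 two-vs-two
(C5) templates, placed in per-chromosome slots with ≥ 3 kb separation —
roughly 25,000 CpGs and 3.4% of the genome in HMRs per tissue. Complex
classes come from explicit interval templates, not a stochastic
process, so taxonomy tests are definitional. One master seed drives
per-stage substreams (truth, each methylome, motifs, peaks, genes), so
any stage can be re-drawn independently and the whole pipeline is
reproducible bit-for-bit.

What the generator does *not* emulate: read-level artefacts (bisulfite
conversion failure, mapping bias, strand asymmetries), CpG islands as a
sequence feature (CGIs are consumed as interval tracks), partially
methylated domains, copy-number structure, and any coupling between
methylation and the toy gene models beyond promoter placement. Passing
recovery tests therefore demonstrates correctness of the statistical
machinery under the stated noise model, not performance on real
libraries. The Beta concentration $k$ is a stand-in for noise the
underlying publication-scale data would show; it is not calibratable
from summary statistics alone and is fixed at 20 throughout.

# Numerical choices and degenerate inputs

* Forward–backward uses per-site rescaling (and a per-site max-shift on
  the log emissions), stable over millions of sites.
* Zero-coverage sites: uninformative emissions, retained in the chain.
* All-zero-coverage input: error (nothing to fit).
* Empty HMR sets, empty region or peak lists, empty components: defined
  results or informative errors, exercised in the test suite.
* Coordinates are BED-convention throughout: 0-based, half-open.
  "Overlap" always means a non-empty half-open intersection.
* Strand-split CpG records can be collapsed to dyads with
  `merge_symmetric()` (sums counts; lone minus-strand records shift to
  the plus-strand position). It is opt-in because published count
  tables come in both conventions and either can be reproduced.

# Problem sizes used in the tests

The shipped tests run the full pipeline on the default 2 Mb / ~25k-CpG
genome (seconds per HMR call), exhaustive-enumeration HMM oracles up to
12 sites, EM monotonicity over 100 random small fixtures, taxonomy
brute-force over 1000 random instances, and Monte-Carlo enrichment
calibration at reduced hit counts with replicate draws. These sizes
make the whole suite run in a couple of minutes while keeping every
statistical check well-powered.

# Known limitations

* **Boundary resolution under the four-level mixture.** The two-state
  model pools all hypomethylated CpGs into one emission distribution.
  On the default genome that distribution is dominated by near-zero
  common-HMR CpGs, so the first or last CpG of a 0.25-level
  tissue-specific segment that happens to draw a high per-site
  probability (observed level ≈ 0.4 at 36X) can be assigned to the
  background state. The result is an occasional 3-CpG boundary offset
  (about one segment end in a hundred at 36X) even though base-level
  recovery is essentially perfect (Jaccard ≈ 0.997). A decoder that
  knew the per-class emission means would recover these sites; the
  pooled two-state design cannot, and we keep the design rather than
  special-case it.
* Replicates, single-CpG differential statistics, partially methylated
  domains, and >2-sample taxonomies are out of scope; multi-methylome
  questions are handled by running pairwise comparisons.
* `compare_sets()` reports structure and fractions, not significance;
  no test is attached to fraction differences.

# A short session

```{r example, eval = FALSE}
library(hmrkit)

sim <- simulate_two_tissues(sim_config(seed = 1))
hmr_a <- call_hmrs(sim$A)   # 36X tissue
hmr_b <- call_hmrs(sim$B)   # 91X tissue

cmp <- compare_sets(hmr_a, hmr_b, sim_config()$chrom_sizes, tau = 20)
print(cmp)

four_level_summary(cmp, sim$A, sim$B)
neighbor_correlation(sim$A)[1:5, ]
```
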