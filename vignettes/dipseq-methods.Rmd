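---
title: "Methods: enriched-domain segmentation, differential methylation and expression integration for DIP-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DIP-Seq segmentation and integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipseqr)
```

## Scope and model

`dipseqr` analyzes methyl- and hydroxymethyl-DNA immunoprecipitation
sequencing (meDIP/hmeDIP, collectively "DIP-Seq") alongside RNA-Seq, for
study designs that ask whether a treatment (e.g. irradiation of brain
tissue) shifts 5mC/5hmC territory and whether those shifts track gene
expression. The input is deliberately minimal: uniquely-mapped sequencing
tags reduced to genomic points (BED), RefSeq-style gene models (BED12 or
refFlat), and per-gene RNA counts. All coordinates are 0-based half-open
internally, matching the on-disk BED dialect; a tag is the 5' start of
its read (optional fragment extension exists but defaults to 0, since a
sonication-based protocol gives no reliable fragment model).

The pipeline has five analysis stages. Each is a pure function of its
inputs, the configuration and the seed, so stages can be re-run
independently from files and a full run is reproducible from its
manifest.

### Enriched-domain segmentation

Tag counts are taken in sliding windows (default 1000 bp, step half a
window; the step must divide the window so counting reduces to base-bin
tabulation plus a rolling sum). The background model is Monte-Carlo
permutation: all tags of a chromosome are re-placed uniformly at random,
preserving per-chromosome totals, `n_permutations` times (default 500),
and the per-window null counts are pooled. The enrichment threshold is
the smallest count whose pooled null tail probability is at most
`enrich_alpha`; empirical window p-values use the add-one rule
(r+1)/(n+1) and therefore never reach zero. Chromosomes that carry no
tags contribute neither observed calls nor null mass, so concatenating
an empty chromosome never changes a call.

Two numerical choices matter here:

* **`enrich_alpha` defaults to 1e-4**, not a conventional 0.01. The
  threshold is applied per window and a 10-Mb genome already holds about
  2e4 windows, so a per-window 0.01 would admit hundreds of false
  windows genome-wide; 1e-4 is of Bonferroni order for that window count
  and keeps false domains rare while costing essentially no power
  against several-fold enrichments (a fold-8 domain at background 0.01
  tags/bp yields window counts far beyond either threshold). With 500
  permutations over 2e4 windows the pooled null holds ~1e7 draws, so the
  1e-4 tail is still resolved with ~1e3 exceedances.
* **Boundary trimming.** Windows exceeding the threshold are merged when
  overlapping or book-ended, but a union of half-overlapping windows
  systematically overshoots a domain's edges by up to a window on each
  side. Merged calls are therefore trimmed to the positions supported by
  at least two overlapping significant windows (the window-intersection
  core); an isolated single significant window keeps its full extent.
  With the default half-window step this recovers planted 1-kb domains
  at close to their true boundaries, which is what makes
  reciprocal-overlap scoring (below) strict at 50% meaningful.

The permutation unit is the tag, and the re-placement is uniform within
the chromosome. No mappability or CpG-density covariates are modelled;
if tag placement in real data is biased at the window scale, the uniform
null is anti-conservative there, and a mappability-aware null would be
the natural extension.

Window-size selection follows the convention of maximizing the number of
called enriched regions over a candidate grid (default 250–4000 bp,
bracketing the conventional 1000 bp); ties break toward the smaller
size, and the full per-size table is returned for audit.

### Differential methylation

Per-sample domains are merged across all samples (union, book-ends
merged) and the merged territory is re-tiled into 5-kb testing units
(`dmr_window_bp`; testing whole merged regions is a flag). Counts per
unit and condition are compared either by a 2x2 chi-square on pooled
counts (default — matching a two-pools-per-condition design, continuity
correction off) or by a replicate-aware negative-binomial Wald test with
size-factor offsets and a pooled method-of-moments dispersion. A region
is a DMR when its BH q is below `dmr_q_threshold` (0.01) **and** its
library-size-normalized tag difference exceeds `dmr_min_tag_diff` (50
tags); direction is the sign of the difference. The "difference > 50
tags" filter is interpreted on the normalized scale (raw mode is a
flag), and both the per-5-kb-unit and whole-region testing modes are
provided because the convention leaves the unit ambiguous.

**Depth normalization is region-median, not whole-library.** DIP-Seq
libraries are dominated by enriched territory, so a genuine gain of
methylation in one condition inflates that condition's total library
size and, under whole-library normalization, shifts *every* null
region's expected proportion — a composition bias that visibly inflates
the false discovery rate in simulations. The default therefore estimates
the between-condition depth ratio by median-of-ratios over the tested
regions themselves (the same estimator used for RNA size factors), which
is robust as long as most regions are non-differential; whole-library
normalization remains available (`normalization = "library"`), and is
the automatic fallback when fewer than 50 regions are testable.

### Differential expression

RNA tags are counted per gene when they fall in an exon (whole-span
counting is a flag); tags assignable to more than one gene are dropped
and reported. Testing is a compact DESeq2-style negative-binomial Wald
test written in-package so the pipeline is self-contained: median-of-
ratios size factors, one pooled dispersion, no fold-change shrinkage.
The dispersion estimator is a ratio-of-sums method-of-moments form,
`sum(s² − q̄·mean(1/sf)) / sum(q̄² − s²/n)`: the denominator correction
(subtracting `s²/n`) removes the small-sample bias of `q̄²` as an
estimate of `μ²`, without which the dispersion is underestimated by
roughly `2/(n·CV²)` and null Wald statistics are visibly over-dispersed
at 4-vs-4 designs. With the correction the null z variance is 1.00 and
p-values pass a KS test against uniformity at 2000 genes; the test also
agrees with DESeq2 (rank correlation of p > 0.99 on a shared dataset in
the test suite, with identical size factors). Genes with all-zero counts
are excluded from testing and multiplicity.

Multiplicity uses Storey q-values: pi0 is estimated by the smoother
(natural cubic spline of pi0(lambda) over lambda = 0.05…0.95, evaluated
at 0.95, clamped to (0,1]), and q is the usual step-up minimum. Below
100 p-values the smoother is unstable and pi0 is pinned to 1, which
makes the procedure exactly BH — the same reduction used as an identity
test.

### Integration

Tested regions are ranked (q, then p, then |normalized difference|) and
annotated to the gene with the nearest TSS within `tss_max_dist_bp`
(default 50 kb; 25 kb is the common alternate and every report names
the window used). The anchor is the region midpoint (edge-distance is a
flag); distance is signed in the gene's reading direction; equidistant
ties break toward the lexicographically smaller gene id, making
annotation deterministic under input shuffling; the list is truncated to
`top_n_dmrs` and de-duplicated to one best-ranked region per gene.

The methylation/expression overlap statistic is a one-sided
hypergeometric test between the genes of the top `top_n_overlap`
annotated regions (per methylation direction) and the significantly
regulated genes (per expression direction, ranked by p, truncated to the
same cap — when fewer genes are significant, the set is smaller, as
"significantly regulated" implies). The universe is the set of genes
with at least one RNA count and at least one annotatable region, and the
report carries all four direction pairs.

Meta-gene matrices hold median-normalized tag density (tags/bp per bin,
matrix divided by its median positive value) over fixed-bp flanks and a
gene body rescaled to a fixed bin count, rows ordered by an expression
statistic and flipped so 5' is always left; the rendering ceiling is the
`heatmap_quantile` (default 0.80) of the normalized values, and an
all-zero matrix short-circuits the normalizer rather than producing
NaN. The intragenic-difference score of a gene is the sum over body bins
of (condition B − condition A) density from two such matrices; the top
`top_n_intragenic` (500) genes form the "most up-regulated regions" set
carried into enrichment.

### Gene-set enrichment

The enrichment engine is generic: category content (GO, KEGG, custom) is
always a user-supplied two-column table and never bundled, since
category-level findings depend on database versions. Three tests are
provided: one-sided Fisher/hypergeometric; a Wallenius noncentral
hypergeometric test whose per-category odds are the mean bias weight
(e.g. mappable gene length) inside versus outside the category — the
length-bias correction style of RNA-Seq ontology tools — computed by
numerical integration of the Wallenius density and renormalized over its
support (with unit weights this reduces to Fisher within 1e-6, which is
asserted in the tests); and a two-sample KS test of a per-gene statistic
inside versus outside a category. BH q-values are reported per family of
categories with q < 0.01 as the conventional significance line.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions under which the package validates itself:

* one 10-Mb chromosome at background 0.01 tags/bp (1e5 tags per
  sample); tags are homogeneous Poisson, the same process the
  permutation null assumes;
* 200 planted 1-kb domains at rate fold 8 over background (domains
  multiply the local rate; overlapping plantings superpose);
* differential domains are fold-ratio changes (default 3) on existing
  domains, not de-novo domains, so merged-territory testing is
  exercised; two DIP pools per condition;
* RNA counts are negative binomial (dispersion 0.1, per-gene means
  log-normal around 100), 4 replicates per condition, with a planted DE
  subset at |log2FC| = 1;
* coupled genes are a subset of up-regulated DE genes (log2FC 2) that
  additionally receive an intragenic domain, always differential
  upward — the joint 5hmC/expression structure.

One seed drives every stage, and all generated data serialize through
the package's standard formats losslessly.

Benchmark scenarios depart from the defaults only where a property needs
a different geometry, and those sizes are fixed in the benchmark
functions: differential recovery uses 1000 domains with 100 differential
ones; the coupling benchmark uses 5000 short genes (1.5–2.5 kb) on a
25-Mb chromosome at background 0.005 so that gene bodies are dense
enough for meta-gene work at realistic tag totals, with 1200 background
domains and 100 coupled genes among 300 DE; the expression power
benchmark plants |log2FC| = 1 at mean 100, dispersion 0.1, 4-vs-4, in a
dense-signal configuration (half of 2000 genes differential). That last
choice deserves its justification: at those settings the Wald statistic
of a true effect is approximately N(3, 1), so a power of 0.8 requires
the multiplicity-adjusted rejection line near z ≈ 2.1 — attainable at
q < 0.05 only when the discovery fraction is large. A sparse-signal
design at the same per-gene effect cannot reach 0.8 power at q < 0.05
regardless of implementation; the dense benchmark measures the test, not
the scenario. The generator's own default stays sparse (50 DE genes of
500), which is the realistic regime.

What the generator does **not** emulate: sequence content (no CpG
density, no GC bias), mappability structure, fragment-length variation,
replicate batch effects, or input/IgG controls. Passing the recovery
benchmarks therefore demonstrates the statistical machinery under its
stated noise model, not robustness to real-library artifacts.

## Recovery scoring and the validation suite

Domain recovery is scored by reciprocal overlap: a planted domain counts
as recovered when a called domain covers at least 50% of each of the
two widths; precision is the mirror image. Differential recovery uses
≥1-bp overlap between called DMR units and planted differential domains,
with empirical FDR the fraction of called units touching no planted
one. The test suite asserts, among others: null calibration of the
segmentation (fraction of windows called at alpha 0.01 stays below 0.02
across 20 background simulations), domain sensitivity and precision
≥ 0.90, DMR sensitivity ≥ 0.80 at empirical FDR ≤ 0.05, exactness of
the 2x2 machinery against brute-force enumeration over all tables with
margins ≤ 30, the Storey-to-BH reduction at pi0 = 1, expression null
uniformity and ≥ 0.8 power, recovery of the coupled structure (overlap
p < 1e-6, ≥ 80% of coupled genes in the top-500 intragenic ranking,
top-vs-bottom expression-decile score contrast significant in ≥ 9/10
replicates) together with its absence in an uncoupled control, and the
Wallenius reduction and bias-absorption properties. The same
computations are re-run from scratch by `scripts/acceptance.R`.

Problem sizes in the suite are the generator's study-scale conditions
(10–25 Mb genomes, 1e5–2.5e5 tags per sample, 500 permutations, up to
5000 genes); the full suite and the acceptance script each complete in a
few minutes on a single CPU.

## Degenerate inputs and tie-breaks

Empty tag files yield empty TagSets; empty region lists write
header-only files that read back empty; a permutation request whose
resolution cannot reach the requested alpha errors with the attainable
resolution; all-zero count rows are excluded from testing; the meta-gene
median normalizer returns zeros (not NaN) on all-zero matrices; both
region counts zero gives p = 1 by convention; sort ties in the
intragenic ranking preserve input order; nearest-TSS ties go to the
lexicographically smaller gene id; duplicate tags are kept by default
(collapsing is a flag, since the protocol leaves duplicate handling
unstated).

## Known limitations

* The permutation null is uniform within chromosomes; mappability and
  CpG-density covariates are out of scope.
* The NB expression test is a minimal DESeq2-style stand-in (pooled
  dispersion, no shrinkage, Wald only); numerical differences from
  DESeq2 are expected even though rankings agree closely.
* The chi-square path tests pooled counts and cannot see
  within-condition variability; the NB path requires ≥ 2 pools.
* Gene placement in the generator is uniform and non-overlapping;
  real annotations overlap, and the RNA ambiguity policy (drop) is only
  exercised by hand-built cases in the tests.
* No isoform structure: simulated genes are single-exon, so exon-mode
  counting equals span-mode counting on generated data.
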