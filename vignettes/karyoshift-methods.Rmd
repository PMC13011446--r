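---
title: "Methods: rearrangement detection, breakpoint enrichment, and divergence scans in karyoshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rearrangement detection, breakpoint enrichment, and divergence scans in karyoshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoshift)
```

karyoshift implements the comparative-genomics workflow used to study
large-scale chromosomal rearrangements in closely related fish genomes:
repeat-density landscapes and their association with inversion breakpoints,
gene-order synteny and the fusion/translocation calls it supports, windowed
population-genetic divergence between two species, and a phylogenetic
regression of karyotype (chromosome number) on distribution. This vignette
explains each model, its assumptions, the defaults, and the numerical
choices; it also spells out what the synthetic-data generator does and does
not emulate, and therefore what a passing test suite does and does not show
about real data.

## Coordinates and containers

Intervals live in `GRanges`/`Seqinfo` objects and follow the Bioconductor
1-based closed convention internally. Conversions happen once, at the format
boundary: BED input/output is 0-based half-open; RepeatMasker `.out`, VCF
and the TSV interval dialect are 1-based inclusive (the TSV reader takes
`oneBased =` to disambiguate). All width, coverage and density arithmetic is
convention-independent.

Repeat classes are derived from the family string's prefix before `/`
("DNA/MITE-224" is class DNA); unknown prefixes map to `Unknown` with a
warning. The default `CategoryScheme` groups classes the way repeat-density
figures in comparative fish genomics are drawn: retroelements (LINE, SINE,
LTR), DNA elements (DNA, RC), total interspersed repeats ("all TEs" =
retroelements + DNA elements + Unknown), and simple tandem repeats
(Simple_repeat, Low_complexity, Satellite). `Unknown` counts toward "all
TEs" but neither subcategory, which preserves the additive structure of the
three-curve density plots.

## Windowed repeat density and peak calling

`computeWindowDensities()` tiles every chromosome from its first base with
non-overlapping windows (default `w = 10000` bp, the scale used for
chromosome-wide density scans). Density is the *merged-coverage fraction*:
per category, features are merged and the covered bases of each window are
divided by the window's true width, giving values in [0, 1]. Element counts
or unmerged base sums would double-count nested and overlapping annotations,
which are common in RepeatMasker output. The final partial window is kept
and normalized by its true width — telomeric windows carry real signal for
translocation-prone chromosome ends and discarding them would censor exactly
the regions of interest.

`callPeaks()` compares each window against its own chromosome: a window is a
peak when its density strictly exceeds the chromosome's 95th percentile
(linear interpolation between order statistics, `quantile` type 7). Strict
exceedance means a degenerate all-equal chromosome has no peaks. The
percentile reference includes all windows of the chromosome — including
putatively centromeric high-density regions; excluding those would require a
centromere annotation the inputs do not carry, and including them only makes
peak calls more conservative. Chromosomes with fewer than 20 windows warn,
because a 95th percentile over so few values is order-statistics noise.

`clusterDensity()` is the same computation at gene-cluster scale: the
cluster region extended by 25-kb flanks, tiled at 500 bp — fine enough to
see individual TE insertions flanking genes in a tandem array.
`sharedTeFamilies()` supports the cluster comparison: families present in at
least two of the supplied regions, with their per-region insertions;
family-private insertions are dropped as uninformative for shared origin.

## The breakpoint enrichment permutation test

The question: are repeat densities near inversion breakpoints elevated
relative to the rest of the chromosome? Each inversion contributes two
breakpoint regions (boundary ± 50 kb, i.e. 100-kb regions, clipped at
chromosome ends). The observed statistic pools the 10-kb subwindow densities
of both regions of one inversion and takes a single median — one test per
inversion, symmetric in the two breakpoints. The null distribution comes
from 1,000 pairs of 100-kb regions placed uniformly at random on the same
chromosome, with three constraints: each null interval avoids *every*
breakpoint region of every inversion on that chromosome (the stricter
reading of "non-breakpoint regions", which keeps enriched flanks out of the
null), the two members of a pair are mutually disjoint, and pairs across
replicates are independent (overlap across replicates is allowed — pure
Monte Carlo with replacement). Each null statistic is the identically pooled
median of its pair.

An inversion is *significant* when its observed median strictly exceeds the
95th percentile of the null statistics. Alongside the flag, the add-one
empirical p-value (1 + #{null >= observed}) / (n + 1) is reported; ties
count against significance, so a spatially constant landscape gives p = 1.
Near the boundary the flag and the p-value can disagree by one rank; the
flag is authoritative because it is the published decision rule.
`enrichmentReport()` optionally Bonferroni-adjusts the p-values over the
inversions tested; the raw values are always kept, since the original rule
carries no multiplicity adjustment.

**Calibration and chromosome length.** A property worth knowing: the
percentile rule is only nominally calibrated when the chromosome is long
relative to the 100-kb regions. On a 1-Mb chromosome there are ~8 disjoint
100-kb placements, so 1,000 null pairs resample the same few patches; the
percentile estimate becomes noisy and the exceedance probability of an
independent observation exceeds 5% markedly (we measure ~14% at that scale —
a consequence of tail convexity, not a coding artifact). On 20-Mb
chromosomes (the scale of real chromosome-level assemblies in this clade,
10–49 Mb) the rule is statistically consistent with 5%, which is what the
calibration test asserts over 2,000 simulated inversions. Users applying the
test to short scaffolds should treat the flag as anti-conservative.

## Synteny blocks, fusions, translocations, overlaps

The homology input is a precomputed ortholog-pair table (one pair per gene;
query and reference coordinates). Running the underlying protein searches is
out of scope — the synthetic generator provides exact pairs, and real use
accepts any such table. Anchors are ranked densely per chromosome by start
coordinate.

`chainBlocks()` extracts collinear chains per query chromosome with a
dynamic program: the longest chain whose consecutive anchors share a
reference chromosome, differ by at most `maxGap = 10` ranks on both genomes
(at most 9 skipped genes — the MCScanX-style default gene gap), and have
strictly monotone reference ranks with a fixed sign, is found, removed, and
the search repeats until no chain of `minAnchors = 5` remains. Iterative
best-chain extraction (rather than a single greedy sweep) guarantees the
first block is the brute-force-optimal single chain, so total block coverage
can never fall below it; a one-pass greedy can strand the head of the
optimal chain behind a non-collinear anchor. A caveat at the gap boundary:
an inverted run of at most `2 * maxGap` genes can be legally "bridged" by a
chain that hops from the background into the run's tail, so such short
inversions may not segment into their own reverse block. Runs longer than
`2 * maxGap` genes are provably unbridgeable and always segment cleanly;
at the default gene densities this corresponds to inversions of roughly
0.6 Mb and larger.

`detectFusions()` calls a query chromosome a fusion product when at least
two reference partners each hold at least 10% of its anchors and jointly at
least 80% (`partnerMinFrac`, `coverageMin`; both exposed). The thresholds are
set so a clean two-way fusion carrying up to ~10% translocated content from
a third chromosome is still called with the two true partners — the
configuration real fused chromosomes show, where a central segment of a
third chromosome sits near the fusion point. The junction estimate is the
midpoint between adjacent partner spans, accurate to about one anchor
spacing. `detectTranslocations()` reports maximal runs of non-major-partner
blocks: embedded between major-partner flanks they are "internal" (the
pattern seen in centrally-located translocations of fused chromosomes);
unflanked runs are "terminal" (telomeric reallocations).

`projectInterval()` maps a query interval into reference coordinates by
linear interpolation between block endpoints, flipping under reverse
orientation, merging the per-block pieces per reference chromosome.
Projection is anchor-interpolated, not base-resolved: its uncertainty is
bounded by the local anchor spacing, which is why recovery tests use "within
one anchor spacing" as the tolerance. `inversionOverlap()` projects
inversion A into genome B, intersects with inversion B, reports the overlap
length and both reciprocal fractions, and calls the pair "partly
overlapping" at `minOverlap = 10` kb — a default chosen as one window of
the density analyses; there is no published minimum, and the threshold is
exposed. Per-side breakpoint flags indicate whether A's projected ±50-kb
breakpoint regions intersect either of B's.

## Windowed pi, DXY and FST

Estimators follow the ratio-of-sums form that motivated the use of
invariant-site-aware tools in divergence scans: per window, numerators and
denominators are summed over sites *first* and divided once. Mean-of-ratios
per site would weight sites by their missingness and bias windows with
uneven coverage.

Per site with non-missing reference/alternate counts: pi uses differences
`n1*n2` over comparisons `n(n-1)/2` (invariant sites contribute comparisons
only — dropping them strictly inflates pi, hence the warning when the input
has no invariant sites); DXY uses `x1*y2 + x2*y1` over `nx*ny`; both are
invariant to allele relabeling and DXY is symmetric in the populations.
Windows with zero comparisons are NA, never 0 — a window of missing data is
unknown, not undiverged. FST is Weir–Cockerham's variance-components theta
in the haploid-sample (haplotype-count) form, summed as a/(a+b) over
polymorphic biallelic sites; monomorphic windows are NA and negative
estimates are reported as computed. Hudson's estimator is available behind
`estimator = "hudson"` for sensitivity analysis. Multiallelic VCF records
are dropped with a count rather than decomposed — hard-filtering upstream is
assumed, as in the standard GATK-style pipelines these inputs come from.

`scanConservedTracts()` turns the FST track into intervals: maximal runs of
windows strictly below 0.5 (the threshold used to flag high-similarity
stretches against a 0.8–0.9 background), merged across at most one missing
window so that a single no-data window does not split a biological tract.

## Brownian-motion phylogenetic regression

`pglsBM()` fits y ~ x by generalized least squares with residual covariance
sigma^2 * C, where C_ij is the shared root-to-tip path length — the exact BM
covariance for a fixed tree. For BM the rate sigma^2 profiles out in closed
form, so no iteration is needed and the estimates match a maximum-likelihood
BM fit up to numerics: beta = (X'C^-1 X)^-1 X'C^-1 y via a Cholesky
transform, sigma^2 from the transformed residual sum of squares over n - 2,
two-sided p from the t distribution on n - 2 df. On a star tree with equal
depths C is proportional to the identity and the fit reduces to OLS — a
useful exactness check. The response (chromosome number) is treated as
continuous, matching how such regressions are run in practice; a count model
is deliberately not offered. Bonferroni adjustment (`bonferroniAdjust()`,
a wrapper over `p.adjust`) defaults its test count to the number of models
fitted in one invocation.

The supporting phylogenomic utilities: `alignmentStats()` counts variable
columns (>= 2 distinct non-gap states), parsimony-informative columns (>= 2
states each seen >= 2 times, gaps never counted as states) and
gap-containing columns; `filterAlignments()` applies the published boundary
semantics exactly — length and variability thresholds are strict (length
exactly 500 or PI exactly 2.5% is removed) while the gap threshold is
inclusive (30% exactly is kept). `quartetFrequencies()` prunes each gene
tree to four taxon groups and classifies it by whichever internal
bipartition splits the groups cleanly two-against-two; polytomies and
unclean splits count as unresolved and leave the frequency denominator.

## The synthetic-data generator

`simConfig()` fixes the study conditions; the generator is deterministic in
its seed (per-chromosome, per-stage substreams keep partial re-runs stable).

* **Repeat landscape** — per family, a homogeneous Poisson process at the
  configured per-bp insertion rate with uniform lengths; inside ±50 kb of a
  planted inversion breakpoint, enriched families are drawn at rate × lambda
  (a step function over the flank — the data motivating the enrichment test
  report elevated flank densities, not a gradient shape). Overlaps between
  simulated repeats are allowed, as in real annotations. Defaults give a
  TE complement across DNA/LINE/LTR/SINE/simple classes at ~25–30% combined
  coverage, in the range of repeat-rich teleost genomes.
* **Anchor tables** — genes laid uniformly at 35 genes/Mb (a compact
  teleost's ~22,000 genes over ~600 Mb), then fusions concatenate ancestral
  chromosome pairs, inversions reflect fully contained genes, and
  translocations move contained gene runs; ground truth records partners,
  junctions and destination spans.
* **Genotypes** — haplotype-level sites on one synthetic chromosome: with
  probability d (default 0.02; reduced inside conserved tracts) a site is a
  fixed inter-population difference; otherwise each population may carry a
  singleton polymorphism with per-site probability calibrated so the
  expected pi equals piX / piY *exactly* (defaults 0.002 and 0.004, two
  populations of 14 diploids each). These defaults put background FST near
  0.87 and expected DXY at d + (piX + piY)/2 — matching a strongly diverged
  species pair with a 0.8–0.9 FST baseline. Singleton-only polymorphism is a
  simplification: it reproduces first moments exactly but not the site
  frequency spectrum, so tests passing on these data validate estimator
  algebra and window bookkeeping, not robustness to realistic allele
  frequency distributions, linkage, or reference bias (the lower diversity
  typically measured on the reference species' own assembly is a mapping
  artifact this generator does not model).
* **BM traits** — residuals drawn with covariance sigma^2 * C via Cholesky;
  sigma^2 = 0 degenerates to the noiseless linear predictor.

More generally the generator has no nucleotide sequences, no reads, no
coalescent: recovery tests demonstrate that the detectors invert the
generative rearrangement model, not that they are robust to assembly error,
annotation noise, or missing orthologs.

## Numerical choices and problem sizes

Percentiles and quantiles everywhere use linear interpolation (type 7).
Empirical p-values use the add-one estimator, bounded in [1/(n+1), 1]. The
permutation sampler draws first members uniformly over start positions for
which a disjoint partner exists, then partners uniformly over the remaining
valid positions — exact, with a bounded rejection loop and a per-replicate
exact fallback, so the degenerate "exactly two slots" chromosome still
yields its unique valid pair. Cholesky factorization backs both the GLS fit
and the BM simulator; a singular phylogenetic covariance (duplicate
zero-length tips) is an error, as is a constant predictor.

The test suite and acceptance script run at deliberately chosen sizes: the
calibration uses 2,000 inversions on 20-Mb chromosomes (the smallest scale
at which the percentile rule is nominal, see above); rearrangement recovery
uses 50 genome pairs of four ~8–14-Mb chromosomes at 35 genes/Mb; the
chaining oracle is exhaustive over all anchor orders up to 9 plus 200 random
15-anchor instances; popgen recovery uses 10^5 sites with analytic
Monte-Carlo standard errors; the PGLS null uses 1,000 simulations on a
13-tip tree, the size of the real codfish trait analysis.

## Known limitations

* Enrichment is tested per category, not per TE family; family-level claims
  remain descriptive.
* Null regions are not matched on GC, gene density, or centromere proximity;
  an optional exclusion mask is the only covariate control.
* Fusion junctions and projected intervals are anchor-resolution estimates.
* The genotype model is exchangeable across sites (no LD), so window-level
  variances of real data will exceed the simulated ones.
* Reproducing the published per-species rearrangement counts (fused
  chromosomes and overlapping inversions in the Arctic codfishes) requires
  the published coordinate and homology tables, which are third-party data
  and cannot be bundled here; the acceptance test for that reproduction
  fails cleanly in their absence rather than substituting synthetic
  stand-ins.
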