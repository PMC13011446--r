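# karyoshift

Comparative genomics of chromosomal rearrangements: repeat landscapes at
inversion breakpoints, gene-order synteny and fusion detection, windowed
divergence between diverged populations, and phylogenetic regression of
karyotype on distribution.

## The problem

Closely related fish lineages — the Arctic codfishes are the motivating
case — can differ dramatically in genome architecture over a few million
years: whole-chromosome fusions that reduce the haploid count, large partly
overlapping inversions, and a scatter of inter-chromosomal translocations,
with transposable elements (TEs) implicated as the mechanistic substrate.
Testing that picture requires a chain of quantitative steps that usually
live in one-off scripts: windowed TE densities and peak calls, a
permutation test for breakpoint enrichment, synteny-block construction from
gene-order anchors, projection of inversion coordinates across genomes,
invariant-site-aware π/D<sub>XY</sub>/F<sub>ST</sub> scans, and a
Brownian-motion phylogenetic regression of chromosome number on
distribution. karyoshift packages those steps as tested, reusable R
(Bioconductor-style) functions, together with a ground-truthed
synthetic-data generator so every detector can be validated against planted
rearrangements.

## The statistics at the core

* **Breakpoint enrichment.** For an inversion with breakpoint regions
  *b* ± 50 kb, the observed statistic is the median TE density over the
  pooled 10-kb subwindows of both 100-kb regions. The null is the same
  statistic on 1,000 random pairs of 100-kb non-breakpoint regions from the
  same chromosome (members mutually disjoint, all breakpoint regions
  excluded). Significant ⇔ observed > 95th percentile of the null; an
  add-one empirical p-value, p = (1 + #{null ≥ obs})/(n + 1), is reported
  alongside.
* **Density.** density(window) = covered bases after merging / window
  width ∈ [0, 1], per category (all TEs, DNA elements, retroelements,
  simple repeats); peaks exceed the chromosome's 95th percentile.
* **Synteny.** Collinear chains of ortholog anchors (rank gap ≤ 10 on both
  genomes, fixed orientation, ≥ 5 anchors) found by iterative optimal
  extraction; a query chromosome with ≥ 2 major reference partners (each
  ≥ 10% of anchors, jointly ≥ 80%) is a fusion product.
* **Divergence.** Ratio-of-sums estimators with invariant sites:
  π = Σ n₁n₂ / Σ n(n−1)/2, D<sub>XY</sub> = Σ (x₁y₂ + x₂y₁) / Σ nₓn_y,
  F<sub>ST</sub> = Σa / Σ(a+b) (Weir–Cockerham, haplotype counts);
  conserved tracts are runs of windows with F<sub>ST</sub> < 0.5.
* **Karyotype regression.** GLS of chromosome number on a range limit or
  temperature with residual covariance σ²C, C the Brownian-motion shared
  path-length matrix; Bonferroni adjustment across the models fitted.

## Worked example

Simulate a derived genome with one fusion (`ne1 + ne2`) and one inversion
on `ne3` whose breakpoint flanks are TE-enriched (rate × 4), then run the
enrichment test, chain synteny blocks, and detect the fusion:

```r
library(karyoshift)

cfg <- simConfig(
  seed = 42,
  chromosomes = data.frame(name = c("ne1", "ne2", "ne3"),
                           length = c(12e6, 9e6, 10e6)),
  fusions = data.frame(chromA = "ne1", chromB = "ne2"),
  inversions = data.frame(chrom = "ne3", start = 3e6, end = 6e6,
                          lambda = 4, families = ""))

land <- simulateLandscape(cfg)
enrichmentTest(land$repeats, land$truth$inversions, land$genome,
               n = 1000, seed = 1)
#>   inversion chrom observed null_ref        p significant
#> 1      inv1   ne3    0.893      0.5 0.000999        TRUE
```

The observed pooled-median density in the two breakpoint regions (0.893) is
far above the null 95th percentile (0.5); p = 1/1001 is the smallest value
1,000 replicates can produce, so the planted enrichment is recovered.

```r
at <- simulateAnchorTable(cfg)
sb <- chainBlocks(at$anchors)
sb
#> SyntenyBlocks: 5 blocks over 1085 of 1085 anchors (max_gap = 10 , min_anchors = 5 )
detectFusions(sb)
#>    qchrom n_partners partners partner_anchors coverage junctions
#> 1 ne1_ne2          2  ne1,ne2         420,315        1  11993086
```

The fused chromosome is called with exactly its two ancestral partners, and
the junction estimate (11,993,086 bp) lands within one anchor spacing of
the true junction at 12 Mb.

```r
set.seed(7)
tree <- ape::rcoal(13)
northLimit <- setNames(runif(13, 40, 80), tree$tip.label)
traits <- simulateBMTraits(tree, intercept = 28, slope = -0.12,
                           sigma2 = 1.5, x = northLimit, seed = 7)
pglsBM(tree, setNames(traits$trait, traits$species), northLimit)
#> Brownian-motion PGLS fit (n = 13 )
#>               Estimate         SE         t            p
#> (Intercept) 28.6658702 1.61165139 17.786644 1.873433e-09
#> slope       -0.1104198 0.01395309 -7.913648 7.241189e-06
#>   sigma2 = 3.338, df = 11
```

The fitted slope (−0.110 chromosomes per degree of latitude) recovers the
generating value (−0.12) within one standard error: species reaching
further north carry fewer chromosomes in this simulation.

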