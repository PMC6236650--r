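---
title: "Locating the origin of a population expansion from georeferenced genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the origin of a population expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A radial range expansion that proceeds by serial founder events — small
groups repeatedly budding off the wavefront to colonise new territory,
without admixing into resident populations — leaves a characteristic
signature: expected genetic diversity declines monotonically with distance
from the source. `expansionOrigin` turns that expectation into a spatially
explicit discriminative scan for georeferenced multilocus genotype panels
such as microsatellite-typed crop landraces.

The procedure has three stages.

1. **Kernel diversity.** A regular latitude/longitude grid is scanned; at
   every node whose great-circle disc of radius 500 km holds at least five
   geolocated samples (an *accepted kernel*), local diversity is measured
   as the mean across loci of Nei's unbiased gene diversity,
   $h = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$, where $n$ is the
   number of scored allele copies in the kernel and $p_i$ the allele
   frequencies. $h$ is the probability that two copies drawn without
   replacement differ, so it is comparable across kernels of different
   size.
2. **Origin correlation surface.** Every grid node is then treated as a
   candidate origin and scored by the Pearson correlation between
   great-circle distance from the node to each accepted kernel and kernel
   diversity. Under the serial-founder model the true origin should sit in
   the most negative region of the surface.
3. **Permutation comparison of two candidate sites.** For two hypothesised
   origins $A$ and $B$ the statistic is $\Delta r = r(A) - r(B)$. Whole
   genotype vectors (all loci jointly) are reassigned at random across the
   fixed sampling coordinates; kernel memberships depend only on
   coordinates and are computed once, while kernel diversities and
   $\Delta r$ are recomputed for each of 1000 permutations. The two-tailed
   p value is $(1 + \#\{|\Delta r_{perm}| \ge |\Delta r_{obs}|\})/(n+1)$.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `radiusKm` | 500 km | kernel disc radius; sets the spatial smoothing scale |
| `minSamples` | 5 | minimum samples for an accepted kernel |
| `resolution` | 0.5° | working grid spacing; 0.1° and finer are available but only change surface granularity, never the kernel rule |
| `nPerm` | 1000 | permutations for the two-site comparison |

Distances are haversine great-circle distances on a sphere of mean radius
6371.0088 km. At a 500-km kernel scale the sub-0.5% ellipsoidal error is
immaterial, so no projection or datum handling is used; grids are
node-registered lattices (nodes at the lower bound plus integer multiples
of the resolution). Disc membership is boundary-inclusive
(distance ≤ radius), which makes ties at exactly the radius deterministic.
Samples sharing identical coordinates are all counted; there is no jitter
and no location deduplication.

Neighbouring grid nodes usually trap exactly the same member set, so
member sets are stored deduplicated and diversity is computed once per
distinct set. Every accepted node keeps its own centre and distances, so
this is an exact optimisation: deduplicated and naive scans are
bit-identical, as a test asserts.

## Worked example

```{r example}
library(expansionOrigin)

sim <- simulateExpansion(expansionConfig(seed = 1))
grid <- buildGrid(c(30, 40), c(95, 115), 1)
surf <- correlationSurface(sim$table, grid)
bestOrigin(surf)                    # most negative node(s)
plotOriginSurface(interpolateSurface(surf, 4), samples = sim$table)

cmp <- compareOrigins(sim$table, sim$truth@origin, c(35, 138), grid,
                      labels = c("true origin", "distant site"),
                      nPerm = 999, seed = 1)
cmp
plotNullDistribution(cmp)
```

## The synthetic expansion generator

Because the headline analyses of any real panel hinge on one supplementary
genotype table, every stage of the pipeline is exercised against a
generative model with known ground truth. `simulateExpansion()` colonises
a deme lattice breadth-first (rook adjacency) from the deme nearest the
configured origin. The founding pool of each new deme is the pooled allele
copies of its already-colonised neighbours — wavefront mixing, without
which adjacent demes would descend from anciently diverged lineages and
kernel-pooled diversity would not track the expansion. Founders are drawn
Wright–Fisher style (with replacement), so expected gene diversity decays
by $(1 - 1/\text{founderCopies})$ per colonisation step and by
$(1 - 1/\text{demeCapacity})$ per growth generation; on a one-dimensional
chain this closed form is exact and a test checks the realised per-step
loss against it. Mutation follows the stepwise model standard for
microsatellites: ±1 repeat unit with probability `mutationRate` per copy
per generation, reflecting at the repeat-length bounds.

Defaults describe a desk-scale landrace panel: a 20° × 10° domain on a
1° lattice, an 8-copy bottleneck into demes of 120 copies, 3 generations
per step, 16 loci mutating at 5 × 10⁻⁴, 200 sampled accessions placed at
their deme centres (optional jitter), 2% missing calls. Individuals are
haploid allele vectors — one scored copy per locus — matching the scoring
convention for strongly selfing crops, where within-individual
heterozygosity is negligible and genebank SSR tables record a single
allele.

What the generator does *not* emulate: admixture with resident
populations, long-distance dispersal, selection (the GBSSI waxy alleles
carry no fitness effect and are painted on only for mapping examples),
uneven per-locus mutation rates, and the geographic irregularity of real
sampling (a "clustered" sampling mode gives a coarse approximation).
Passing tests therefore demonstrate correctness of the machinery and
recoverability under the model's own assumptions, not that any real panel
satisfies those assumptions.

## Numerical and design choices

- **Missing data.** Per locus, $n$ counts only scored copies among kernel
  members; loci with $n < 2$ are excluded from the kernel mean rather
  than imputed, keeping $h$ unbiased and well defined. Kernels in which
  every locus is undefined are flagged (`h_mean = NA`) and excluded from
  surfaces.
- **Zero variance.** A constant diversity vector gives an undefined
  correlation (`NA`, flagged), never a silent 0.
- **Permutation unit.** Whole genotype vectors are reassigned across
  sample coordinates. This preserves within-sample linkage and the
  marginal allele pool exactly. The alternative — shuffling grouped
  site-level data — would be coarser; sample-level shuffling is the
  stricter null of no geographic structure.
- **p-value convention.** The $+1/(n+1)$ correction guarantees $p > 0$,
  and ties ($|\Delta r_{perm}| = |\Delta r_{obs}|$) count as exceedances
  (conservative). Under exchangeability $p$ is then discrete-uniform, so
  the rejection rate at $\alpha = 0.05$ with 199 permutations is exactly
  0.05 — the calibration a dedicated test verifies on 200 shuffled
  tables.
- **Analysable-sample rule.** Panels are reduced to records with both
  coordinates present and in range (`geolocatedSubset()`); accessions
  with only vague provenance cannot enter a spatial kernel. Any further
  study-specific exclusions must be applied upstream by the user.
- **Interpolation.** `interpolateSurface()` is bilinear, node-exact and
  display-only; statistics are always computed on the raw lattice.
- **PCA encoding.** Samples × (locus, allele) indicators holding the
  within-sample copy fraction of each allele; samples missing a locus
  receive that locus's column means (keeping them in the analysis without
  biasing centroids); columns are centred, not scaled, before the
  decomposition (scaling is available as an option); zero-variance
  columns are dropped with a warning.
- **ΔK.** The Evanno statistic — the mean absolute second difference of
  replicate log-likelihoods scaled by their replicate standard deviation
  — is computed from a plain delimited log schema (`K`, `run`, `lnP`);
  the Bayesian clustering itself always runs externally. Boundary K
  values are undefined by construction, and zero replicate variance flags
  ΔK as undefined rather than infinite. The inconsistently capitalised
  wild-type L allele is treated as the single label `LC`.
- **GBSSI phenotypes.** Any S0 allele ⇒ wild type (S0 is dominant);
  S-15 homozygotes are waxy, and those carrying no wild-type LC allele at
  the L locus are classed fully waxy. The L-locus refinement is an
  interpretive rule and is switchable (`useL = FALSE`).
- **Candidate-site coordinates.** The early sites conventionally compared
  (Dadiwan, Xinglonggou, Sokol'tsy) have documented default coordinates
  in `studySites()`, taken from the archaeological literature at
  village-level precision; comparisons at that scale are insensitive to
  kilometre-level error.

## Problem sizes used by the test-suite experiments

Chosen as desk-scale defaults: origin recovery uses 20 replicate
simulations at default conditions scanned at 1°; null calibration uses
200 shuffled tables with 199 permutations each at a 2° kernel grid (199
makes the 0.05 rejection probability exact, see above); the
strong-gradient comparison uses a 20° × 80° domain at 2° with 400 samples
and 999 permutations. The 0.1° and 0.01° resolutions of
continental-scale scans are supported but bring no statistical change,
only finer maps.

## Limitations

- The scan is discriminative, not generative: it ranks candidate origins
  under the monotonic-decline assumption and cannot detect that the
  assumption itself fails (e.g. under strong admixture, refugial
  structure, or collection bias).
- Overlapping kernels are spatially autocorrelated, so the correlation
  surface is smooth and the permutation null of $\Delta r$ is wide;
  nearby candidate sites are rarely distinguishable — an honest property
  of the method, visible in the worked example.
- Unbiased $h$ corrects sample size but very unequal kernel occupancy
  still leaves heteroscedastic diversity estimates; the Pearson scan does
  not weight kernels by occupancy.
- The simulator's lattice anisotropy (rook adjacency) makes colonisation
  distance differ slightly from great-circle distance along diagonals;
  tolerated since all inference uses great-circle distance.
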