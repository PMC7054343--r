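---
title: "Stage-aware detection of recurrent copy number alterations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-aware detection of recurrent copy number alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageCNA)
```

## The model

The unit of analysis is a pathology stage: a cohort of `N` tumor
samples measured at `M` genomic probes, summarized as a ternary call
matrix `A` with `A[i, j] = +1` if sample `i` carries a copy number
gain at probe `j`, `-1` for a loss, and `0` otherwise. Probes are held
in a probe map sorted into genome order (chromosomes in natural order,
positions ascending) with ranks `1..M`; all interval arithmetic is
1-based and closed. `A` splits losslessly into two binary indicator
matrices, `AL = 1(A == +1)` for gains and `AD = 1(A == -1)` for
losses, which are analyzed independently and symmetrically.

The scientific question is which regions are *recurrently* altered
within each stage — altered in more samples than a sample-specific
chance model explains — and how the affected pathways change between
consecutive stages.

## Marker significance by permutation

The null model preserves each sample's aberration load per chromosome
but randomizes where on the chromosome the aberrations sit: row `i` of
the binary matrix, restricted to a chromosome with `M_c` probes and
carrying `L_i` aberrant cells, is equally likely to place those cells
at any positions. Under this null the count at any single marker is a
sum of independent `Bernoulli(L_i / M_c)` draws across samples, so the
per-marker null distribution can be sampled directly without
materializing whole-row shuffles; `permutation_pvalues()` draws
`n_perm` such counts once per chromosome and converts observed counts
to upper-tail p-values with the add-one estimator
`p = (1 + #{null >= obs}) / (1 + n_perm)`, which is never zero and has
bias at most `1 / (n_perm + 1)`. Sample loads are sorted before
drawing and each (chromosome, aberration type, peel-off iteration)
gets its own seeded substream, so p-values are invariant to sample and
chromosome ordering. P-values are corrected to q-values with the
Benjamini–Hochberg procedure across all markers of the matrix.

The test suite checks this scheme against exhaustive enumeration of
all per-row arrangements for every binary matrix with `N <= 3`,
`M <= 4`. Because that sweep makes thousands of comparisons, agreement
is asserted at the family level — at least 99% of comparisons within 3
Monte-Carlo standard errors and all within 5 — since a correct
Monte-Carlo estimator still produces isolated 3-SE excursions by
chance, whereas a mis-specified null fails broadly. Fixed small
matrices are additionally held to the strict 3-SE bound.

## Homogeneous peel-off detection

Significant markers are grouped into regions by a peel-off loop. For
adjacent probe pairs `(j, j+1)` on the same chromosome, the
homogeneity matrix `H` scores each sample's concordance: `0` when the
two states are equal (both aberrant or both not), `0.5` when both are
aberrant but at different magnitude levels (only possible with
multi-level calls), and `1` when exactly one is aberrant. The
*h-profile* `h_j` is the column mean of `H` — the fraction of samples
whose aberration status changes across the junction. We deliberately
score concordant-normal pairs as homogeneous (0): at an interior
junction of a region altered in a fraction `f` of samples, roughly
`1 - f` of samples are normal on both sides, and penalizing them would
make `h_j` large inside any region with `f < 1`, preventing boundary
expansion at realistic frequencies. Under our mapping, interior
junctions of a clean planted region have `h ~ 0` and its edges have
`h ~ f`, which is exactly the contrast the detector needs.

Each iteration takes the marker with the smallest q-value as the peak
and expands it into `[l, r]`: the left boundary moves from `l` to
`l - 1` while `q[l-1] <= q_thr` and `h[l-1] <= h_thr`, and
symmetrically on the right, never crossing a chromosome end. The
expanded region is reported, the peak's carrier samples have their
calls zeroed across `[l, r]` (the *peel*), and testing repeats on the
reduced matrix, so overlapping events driven by different sample
subsets are resolved separately. The loop stops when no marker remains
significant, the matrix empties, or `max_iterations` is reached.

Defaults (`detection_config()`): `q_thr = 0.10` (FDR level),
`h_thr = 0.12` (at most 12% of samples may switch status at a junction
inside a region), `n_perm = 10000`, `max_iterations = 10`. All are
plain numbers, not tuned per dataset; `h_thr` trades boundary
tightness against tolerance of ragged region edges.

`find_shared_runs()` exposes the underlying primitive on small
matrices: all maximal (sample subset × probe interval) blocks sharing
one aberration state, useful for inspecting who exactly carries a
candidate region.

## Genes, pathways, and the evolution network

A gene is assigned to a stage's amplified (or deleted) set when it
lies fully within a significant gain (loss) region on its chromosome
— closed-interval containment, boundary contact included, strand
ignored. Containment uses `GenomicRanges::findOverlaps(type =
"within")`; coordinates are 1-based inclusive in memory and 0-based
half-open in BED files on disk.

Hit genes are intersected with a GMT pathway database
(`assign_genes_to_pathways()`). Two filters follow: pathways whose
database gene-set size is not strictly greater than
`min_pathway_size = 5` are dropped (tiny sets carry little
interpretable biology), and pathways must be hit in at least
`min_stages = 2` distinct stages — the network is about change across
stages, so single-stage hits contribute no edges.

`build_evolution_network()` connects consecutive stages only: for each
adjacent stage pair `(s, s+1)` and each pair of *distinct* pathways
hit at `s` and `s+1` with at least one shared gene, an edge is drawn
with weight `W = k^2 / (p * q)`, where `k` is the shared gene count
and `p`, `q` the two gene-set sizes. `W` is symmetric, lies in
`(0, 1]`, and equals 1 exactly for identical sets. By default the
shared-gene basis is the stage-specific *hit* subsets, so `W` reflects
aberrant biology at those stages and the network is genuinely
stage-dependent; `gene_basis = "full"` switches to full database gene
sets, which measures static pathway crosstalk instead. Nodes carry
stage membership and total distinct hit-gene counts; exports are
GraphML (attribute-preserving round trip via `igraph`), SIF plus an
edge-attribute sidecar, or plain TSV.

## The simulator

`simulate_stage_calls()` generates per-stage cohorts with independent
background noise (each cell is aberrant with probability
`background_rate` per type; simultaneous gain and loss collisions are
resolved by a fair coin) and planted rectangular regions: for each
planted region, carriers are drawn per sample at the given frequency
and span the full probe interval (partial spans are available through
`carrier_overlap`). Each stage consumes its own RNG substream derived
from the master seed, so adding a stage to a configuration does not
perturb the data of existing stages. The simulator is a scope-limited
instrument for validating the detector: it produces exchangeable
samples, sharp region boundaries, and position-independent noise, and
makes no attempt to model real aCGH/sequencing artifacts such as wavy
baselines, segmentation errors, length-dependent noise, or correlated
breakpoints.

`simulate_gene_annotation()` scatters non-degenerate gene intervals
over the probe space, and `simulate_pathway_db()` builds gene sets
whose pairwise sharing is controlled by `overlap_fraction`: a shared
core pool of `round(overlap_fraction * max(size))` genes is set aside
and each pathway draws `round(overlap_fraction * size)` members from
it, the rest being pathway-exclusive. `overlap_fraction = 0` gives
pairwise disjoint sets; `1` with equal sizes gives identical sets. The
default of 0.5 makes simulated databases exhibit the pervasive gene
sharing typical of curated pathway collections, so downstream network
code is exercised on non-degenerate inputs.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds through isolated
  RNG scopes that save and restore the global RNG state, so library
  calls never perturb user sessions and identical configurations yield
  byte-identical pipeline output directories (verified in the tests by
  comparing full runs byte for byte).
* The pipeline manifest (`manifest.json`) records a hash of the
  analysis configuration (excluding the output location), the seed,
  package version, per-stage counts, and the file inventory; it
  contains no timestamps.
* Validation-problem sizes used in the tests and acceptance script
  (cohorts of 50 × 500 with 20-probe plants at frequency 0.6 over 1%
  background, 20 replicates) are chosen to finish in seconds per run
  on one CPU while keeping the detection problem non-trivial: at these
  sizes a marker inside the plant is far beyond the null's reach while
  background-only cohorts stay below the q-value threshold.

## Limitations

* Calls are discrete and two-sided only; the detector does not use
  underlying log2 magnitudes beyond the initial thresholding, and
  high-level amplifications are not distinguished from single-copy
  gains.
* The permutation null conditions on per-chromosome aberration load
  and assumes within-stage sample exchangeability; confounders such as
  batch or tumor purity must be handled upstream.
* Boundary expansion is greedy and symmetric; a region whose true edge
  sits in a run of non-significant markers will be truncated at the
  last significant one.
* The evolution network connects consecutive stages only and does not
  model pathway persistence beyond adjacency or test edge weights for
  significance.
* Stages are treated as independent cohorts (cross-sectional design);
  the simulator likewise plants regions per stage without an explicit
  lineage model linking carriers across stages.
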