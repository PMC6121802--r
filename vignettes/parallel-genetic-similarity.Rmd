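---
title: "Quantifying parallel genetic evolution across environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parallel genetic evolution across environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoparallel)
```

## The scientific problem

Replicate bacterial populations evolving under controlled conditions often
acquire mutations in the same genes — parallel evolution. When environments
are not identical but share a selection pressure (the same carbon level, or
the same mode of growth), do the populations still evolve in parallel? And is
a population's genetic similarity to the residents of an environment
predictive of its fitness there?

`evoparallel` implements the full quantitative workflow for answering these
questions from whole-population (pooled) sequencing of an experiment with a
2×2 factorial core (carbon: high/low × growth mode: biofilm/planktonic) plus
a bead-size control treatment, six replicate populations per treatment.
Because pooled sequencing reports the *frequency* of every mutation, not just
its presence, the workflow operates on gene-level mutation-frequency
profiles rather than on fixed-difference counts.

## From mutation calls to profiles

The unit of analysis is the curated mutation call: one row per polymorphism
per population, with a frequency in (0, 1]. Curation applies three rules
before any statistics:

1. **Indel consolidation.** Variant callers report a multi-base indel as a
   run of single-base calls at consecutive positions. Runs of same-type,
   same-population calls at consecutive positions with matching frequencies
   are merged into one record. The frequency-match tolerance is 0.01: pooled
   frequencies are noisy at the third decimal, and an exact-equality rule
   would leave genuine runs split. Consolidation is idempotent.
2. **Gene context.** Each mutation must be *unambiguously* attributable to
   one gene. A position inside exactly one annotated gene is `within_gene`;
   inside two overlapping genes, `multi_gene` (excluded). An intergenic
   position within the 150 bp window upstream of exactly one gene — the
   likely promoter region — is `upstream_of_gene`; inside two genes'
   windows, `ambiguous` (excluded); otherwise `distal_intergenic`
   (excluded). The window is strand-aware (5′ of the coding strand):
   the recurrent regulatory site 61 bp upstream of the bacterioferritin
   gene only makes sense as a promoter variant if "upstream" follows the
   gene's orientation. When a position falls inside one gene *and* within
   another gene's upstream window, containment wins: a coding change is the
   more direct attribution.
3. **Inclusion filters.** Synonymous calls, multi-gene calls, distal or
   ambiguous intergenic calls, and calls below the minimum frequency
   (default 0.05, the polymorphism-calling detection floor; 0.10 for the
   sensitivity re-run) are excluded. The filter report assigns every
   excluded record exactly one reason, applied in a fixed order (frequency
   first, then synonymous, multi-gene, ambiguous, distal); the totals always
   reconcile with the input count. Nonsense and non-coding in-gene calls are
   retained — only synonymous changes are presumed silent.

Retained mutations are summed per gene within each population into the
profile matrix: entry \(n_{ig}\) is the total mutation frequency in gene
\(g\) in population \(i\), over the gene body plus its upstream window.
\(n_{ig}\) is deliberately not capped at 1: competing lineages can carry
different mutations in the same gene, and their joint frequency is real
signal. Profiles can optionally be collapsed to operons, which groups genes
that function as one regulatory unit.

## Genetic similarity

The central statistic is the Bray–Curtis similarity applied to gene-level
mutation-frequency profiles,

\[
BC_{ij} \;=\; 1 - \frac{\sum_g |n_{ig} - n_{jg}|}{\sum_g (n_{ig} + n_{jg})},
\]

which is 1 for identical profiles and 0 for populations with no mutated gene
in common; genes mutated in neither population drop out of both sums.
Jaccard similarity (presence/absence) and Euclidean distance are provided as
alternates. If a population has an all-zero profile the ratio is 0/0; the
value is reported as missing — never 0 or 1 — and downstream means skip it.

`treatment_summary()` pools pairs: `bc_within` is the unweighted mean over
all pairs of replicate populations sharing a treatment, pooled across
treatments, and `bc_between` the mean over all cross-treatment pairs.
Pooling with equal pair weights (rather than averaging per-treatment means)
was chosen because the quantities of interest are single overall numbers,
and it keeps the test statistic linear in the pair values.

## Randomization tests

All tests hold the pairwise similarity matrix fixed and permute the
population-to-treatment assignment, preserving group sizes, so the null
hypothesis is that treatment labels carry no information about genetic
similarity:

* `test_within_vs_between()` — statistic \(BC_\mathrm{within} -
  BC_\mathrm{between}\), one-sided.
* `test_treatment_pair()` — the same statistic restricted to two
  treatments; run over all pairs and corrected with the sequential
  Bonferroni (Holm) step-down at target α = 0.05.
* `test_shared_trait()` — for the 2×2 factorial cells (the bead-size
  control is excluded, since it duplicates the high-carbon biofilm cell),
  the mean of the per-treatment-pair similarities over "edge" pairs
  (sharing exactly one factor) minus the mean over "diagonal" pairs
  (sharing neither).

When the number of distinct assignments is no larger than the requested
permutation count the null is enumerated exhaustively and
\(p = \#\{T^* \ge T\}/N\); otherwise the null is sampled and
\(p = (1 + \#\{T^* \ge T\})/(1 + B)\). Ties count toward the numerator
(conservative), sampled results are reproducible from the seed, and the
observed statistic is always a member of the exhaustive null multiset.

One design choice deserves emphasis. For the shared-trait test, permuting
the four *intact treatment groups* across the four factorial cells looks
natural but is statistically vacuous: the statistic depends only on which
perfect matching of the cells forms the diagonal pairs, and four cells admit
exactly three matchings, so that null takes three distinct values and its
smallest attainable p is 1/3. The default therefore permutes *population*
labels across the four cells — the same exchangeability unit as the other
tests — which gives the null genuine resolution; the intact-group variant is
retained as `unit = "treatment"` for illustration. Similarly, two groups of
three populations admit only 10 distinct partitions, so pairwise tests at
that size cannot reach p ≤ 0.05; calibration simulations use five
populations per group to keep the discrete null finer than α.

## Fitness and reciprocal adaptation

Competition assays against the ancestor yield the selection rate, the
difference in realized Malthusian parameters per day:

\[
r \;=\; \frac{\ln(E_{d}/E_{0}) - \ln(A_{d}/A_{0})}{d},
\]

positive when the evolved competitor is fitter, zero when both change by the
same factor. Note an orientation subtlety: written with initial/final ratios
\(\ln(E_0/E_d)\) the same formula yields negative values for fitter evolved
strains, contradicting the usual sign convention; `selection_rate()` uses
the growth orientation by default and exposes `orientation = "printed"` for
the initial/final-ratio form (the exact negation). The rate is invariant to
common dilution factors and antisymmetric under swapping competitors.
Replicate assays of one population × environment pair are averaged.

`similarity_fitness_correlation()` asks whether a population's mean
similarity to the populations that evolved in an environment predicts its
selection rate there. Native populations exclude their own self-similarity
(which is 1 by definition); setting `include_native = FALSE` removes them
entirely, testing whether the association survives without the resident
populations. Because there is no reason to expect linearity, association is
measured with Kendall's rank correlation; the tie-corrected τ_b is used
because similarity means tie readily on sparse profiles (computed via
`stats::cor.test`, with exact small-sample p-values when there are no ties).

## The synthetic-experiment generator

`generate_experiment()` draws a complete experiment — design, annotation,
mutation table with ground truth, competition counts — so every stage is
testable without any sequencing data, and calibration/power/recovery suites
are runnable. It emulates the statistical structure of the emulated study,
not its sequences:

* 5 treatments × 6 replicates; by default one high-carbon large-bead
  replicate is dropped from the usable set (29 usable populations),
  mirroring the exclusion of a cross-contaminated replicate.
* Calls per population ~ Poisson(15); a call is fixed (frequency 1) with
  probability 0.15, otherwise its frequency is uniform on [0.05, 0.95] — the
  detection floor and the fixed/intermediate split are the only constraints
  the emulated accounting imposes, so a maximally uninformative law is used
  in between.
* 13% synonymous and 6% distal-intergenic decoy calls exercise the filters
  (matching the emulated accounting of 55/432 synonymous and 25/432 distal
  calls over 29 populations, i.e. 432 calls ≈ 14.9 per population with 352
  retained).
* Adaptive calls hit genes drawn from a mixture of pools: one global pool
  (beneficial everywhere), one pool per factor level (carbon high/low,
  mode biofilm/planktonic), and one private pool per factorial cell, with
  the bead-size control sharing the high-carbon biofilm cell pool. The
  `divergence` weight shifts draws away from the global pool and
  `factor_share` splits the shifted weight between factor-level and
  cell-private pools. A `low_carbon_tradeoff` switch makes low-carbon
  populations skip the shared low-carbon pool, reproducing the scenario in
  which the two low-carbon environments select almost disjoint mutation
  sets.
* Default pool sizes and weights (global 3, factor 4, cell 5 genes;
  divergence 0.9, factor share 0.65) were calibrated so the preset
  reproduces the emulated similarity structure — mean within-treatment
  Bray–Curtis ≈ 0.37, between ≈ 0.12–0.13, low-carbon cross-mode ≈ 0.02 —
  averaged over seeds. Individual realizations scatter around these values.
* True selection rates are affine in a population's adaptive content
  (summed frequency over genes adaptive in the assay environment):
  `0.3 + 0.35 × content` plus Gaussian noise (sd 0.15), which puts native
  rates near 2.5/day. Competition counts invert the selection-rate formula
  exactly and then receive Poisson colony-counting noise at a dilution
  targeting ~200 colonies; with noise disabled the rates are recovered to
  machine precision.

What the generator does **not** emulate: real genome sequences and read
alignment, linkage between mutations within a lineage, clonal-interference
dynamics through time, mutation-rate heterogeneity along the genome, and
environment-specific assay noise. Passing tests on synthetic data therefore
demonstrate that the statistical machinery is correct and calibrated under
the declared generative structure — not that the biological conclusions of
any particular dataset are right.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive (GFF3 convention) throughout.
* Permutation-statistic ties use a 10⁻¹² tolerance so the observed value
  always counts as ≥ itself.
* Exhaustive enumeration is used whenever the assignment count does not
  exceed the permutation budget (hard cap 250,000 assignments).
* All-zero profiles propagate as missing values with warnings; empty inputs
  return empty, well-typed results rather than errors wherever a vacuous
  answer exists.
* Degenerate designs (one treatment, a treatment with one population, a
  missing factorial cell) raise errors naming the offending unit.

## Problem sizes used by the test suite

The calibration suites are scaled to run on one CPU in minutes: type-I
error uses 1000 null datasets (4–5 populations × 5 treatments, 80-gene
genomes, 200 permutations per test; rejection rates are required to fall in
the central 99% binomial band around α = 0.05), and power uses 200 datasets
at the full default preset. The acceptance script runs the complete default
preset with 10⁵ permutations for the two headline tests.

## Known limitations

* Ordination (NMDS) and PERMANOVA are intentionally out of scope; the
  exported square/long distance matrices are the hand-off to `vegan`.
* The shared-trait test assumes the full 2×2 factorial is present.
* Kendall p-values for n > 10 with ties rely on the normal approximation.
* The generator's fitness coupling uses one slope for all environments;
  differences between biofilm and planktonic assay dynamics are not
  modelled.
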