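# evoparallel

Quantifies **parallel genetic evolution** across replicate bacterial
populations from whole-population (pooled) sequencing, and asks whether
genetic similarity predicts **reciprocal fitness**.

The package is aimed at experimental-evolution studies with a factorial
design — e.g. high/low carbon availability crossed with biofilm/planktonic
selection, six replicate populations per treatment — where each evolved
population is sequenced as a pool so that every mutation has a frequency,
not just a presence call. It covers the full analysis path downstream of
variant calling:

1. **Curation** — read curated mutation tables (TSV/CSV), consolidate runs
   of single-base indel calls, and assign every mutation an unambiguous gene
   context using a strand-aware 150 bp upstream promoter window over a GFF3
   annotation.
2. **Profiles** — apply the inclusion filters (drop synonymous, multi-gene,
   ambiguous and distal-intergenic calls and calls below the 0.05 detection
   floor) and build the populations × genes matrix of summed mutation
   frequencies *n<sub>ig</sub>*, optionally collapsed to operons.
3. **Similarity** — pairwise genetic similarity between populations,

   *BC<sub>ij</sub>* = 1 − Σ<sub>g</sub>|*n<sub>ig</sub>* − *n<sub>jg</sub>*| / Σ<sub>g</sub>(*n<sub>ig</sub>* + *n<sub>jg</sub>*),

   plus Jaccard and Euclidean alternates, with within-/between-treatment
   summaries and square/long exports for external NMDS/PERMANOVA.
4. **Inference** — one-sided randomization tests (label permutation on the
   fixed similarity matrix, exhaustive when feasible) for within- versus
   between-treatment similarity, for every treatment pair (with sequential
   Bonferroni/Holm control), and for the shared-selection-pressure contrast
   (treatment pairs sharing one environmental factor versus pairs sharing
   none); gene- and nucleotide-level parallelism summaries.
5. **Fitness** — competition-assay selection rates (difference of Malthusian
   parameters, per day) and Kendall rank correlations between a
   population's mean similarity to an environment's residents and its
   fitness there, with and without the native populations.
6. **Synthetic experiments** — a generator that emulates the statistical
   structure of such an experiment (Poisson mutation counts, fixation
   probability, decoy calls, adaptive gene pools shared along factorial
   structure, noisy competition counts) with full ground truth, used by the
   calibration, power, and recovery test suites.

## Worked example

```r
library(evoparallel)

experiment <- generate_experiment(synthetic_config(seed = 11))
# drop the generator's ground-truth context columns and re-derive them from
# the annotation, exactly as one would for a real mutation table
records <- assign_gene_contexts(experiment$records[, 1:7], experiment$genes)
flt <- filter_mutations(records, min_frequency = 0.05)
flt$report
#> Mutation inclusion filter (min frequency 0.05)
#>   input:               427
#>   below frequency:     0
#>   synonymous:          60
#>   multi-gene:          0
#>   ambiguous upstream:  0
#>   distal intergenic:   27
#>   retained:            340

profiles <- build_profiles(flt$records,
                           populations = experiment$usable_design$population)
sim <- pairwise_matrix(profiles, metric = "bray_curtis")
treatment_summary(sim, experiment$usable_design)
#> Treatment-level bray_curtis summary
#>   mean within-treatment:   0.3478
#>   mean between-treatment:  0.1195

test_within_vs_between(sim, experiment$usable_design,
                       n_permutations = 10000, seed = 11)
#> Randomization test: bc_within - bc_between
#>   observed = 0.22838, p = 9.999e-05 (sampled, 10000 permutations)

test_shared_trait(sim, experiment$usable_design,
                  n_permutations = 10000, seed = 11)
#> Randomization test: edge mean - diagonal mean
#>   observed = 0.10763, p = 9.999e-05 (sampled, 10000 permutations)

rates <- selection_rates(experiment$assays)
similarity_fitness_correlation(sim, rates, experiment$usable_design, "lc_plank")
#> Similarity-fitness correlation in lc_plank
#>   Kendall tau = 0.7291, p = 4.812e-10, n = 29
```

Reading the output: replicate populations that evolved under the same
treatment share mutated genes far beyond chance (within-treatment
Bray–Curtis 0.35 versus 0.12 between; permutation p ≈ 10⁻⁴, the smallest
value 10⁴ permutations can resolve), treatments sharing a carbon level or a
growth mode are more similar than treatments sharing neither, and a
population's similarity to an environment's resident populations strongly
predicts its competitive fitness there (τ = 0.73).

On real data, replace the simulated inputs with
`read_mutation_table()`, `read_gene_annotation()`, `read_design_table()`,
and `read_competition_table()`, or drive everything from a YAML config via
`run_config()`/`run_pipeline()` or the thin CLI at
`inst/cli/evoparallel.R`:

```sh
Rscript inst/cli/evoparallel.R all --seed 11 --out results_dir
```

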