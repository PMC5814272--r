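# neoimmune

Immunogenomic analysis of tumor cohorts in R: who is this for, and what
does it compute?

Tumors that carry mutations in DNA repair genes — the homologous
recombination (HR) pathway, the mismatch repair (MMR) pathway, or the
replicative polymerase *POLE* — accumulate somatic mutations at an
elevated rate. More nonsynonymous mutations mean more chances that a
mutated peptide is presented on class-I MHC and recognized by T cells as
a **neoantigen**, and neoantigen-rich tumors tend to be infiltrated by
activated T cells and to respond to immune checkpoint blockade.
`neoimmune` packages the full analysis chain that connects these layers
for a cohort of tumors, together with a seeded synthetic cohort generator
so every stage is testable offline.

## What it computes

1. **Immunophenotype.** For each sample and each immune cell type
   (described by a *metagene* set), a single-sample weighted
   Kolmogorov–Smirnov enrichment score of the set in the sample's
   z-score-ranked expression profile,

   ES = max deviation of Σ_hits |z_i|^α / Σ|z|^α − Σ_misses 1/(N − n_h),

   a gene-label permutation p-value, and Benjamini–Hochberg q-values
   across cell types within the sample. A cell type is *positively
   infiltrating* when q ≤ 10% and ES > 0. Prevalence (per cell type, any
   T cell subtype, any immune cell) and pairwise co-occurrence (two-sided
   Fisher exact test) summarize the cohort.
2. **Burden and repair status.** Per-sample nonsynonymous mutation count,
   strand-collapsed substitution spectrum (C>A, C>G, C>T, T>A, T>C, T>G),
   and HR/MMR/POLE status: a sample is pathway-mutant iff it carries ≥ 1
   nonsynonymous mutation in the pathway's gene list (15 HR genes, 18 MMR
   genes, *POLE*).
3. **Neoantigens.** For every missense mutation, all 9-mer peptides
   containing the mutated residue are paired with their wildtype
   homologs and scored against the sample's 6 class-I HLA alleles. A
   mutation is a neoantigen iff some peptide–allele pair has mutant
   IC50 < 500 nM, wildtype IC50 > 500 nM, and the gene is expressed
   (> 0) in that sample. Load = number of neoantigen mutations.
4. **Association statistics.** Two-proportion z tests, Welch/Student t
   tests (mean ± SEM), Pearson correlation, BH FDR, Kaplan–Meier curves
   with the log-rank test, and fold-change tables of infiltration
   prevalence between sample groups (median burden split, repair status,
   top neoantigen-load quartile).

External binding predictors are consumed through an adapter
(`parse_predictor_output()`); a deterministic toy position-weight-matrix
predictor ships in the package for simulation and testing.

## Worked example

```r
library(neoimmune)

co  <- generate_cohort(cohort_config(n_samples = 100,
                                     panel = synthetic_panel(8, 30),
                                     seed = 42))
inf <- call_infiltration(co$expression, co$panel,
                         calling_config(n_permutations = 499, seed = 42))
infiltration_prevalence(inf)$per_cell_type[1:2, ]
#>              cell_type n_positive   n percent_positive
#> 1 Activated CD4 T cell         30 100               30
#> 2 Activated CD8 T cell         35 100               35

b  <- mutation_burden(co$mutations, samples = co$samples)
st <- classify_repair(co$mutations, samples = co$samples)
mean_test(b$burden[st$hr_mut], b$burden[!st$hr_mut])[c("mean1","mean2","p")]
#> $mean1 15.64  $mean2 7.29  $p 1.95e-07
```

HR-mutant tumors in this seeded cohort carry 15.6 ± 1.0 nonsynonymous
mutations versus 7.3 ± 0.6 in repair-wildtype tumors (Welch p ≈ 2e-07) —
the planted burden multiplier (rho = 3, attenuated by the shared
oncogene/forced-mutation floor) recovered from the emitted MAF alone.
Downstream, the same cohort yields a median neoantigen load of 5,
significantly higher load in HR-mutant samples (11.9 vs 5.8, p ≈ 6e-06),
and a strong load–expression correlation for the coupled checkpoint gene
*PDCD1* (r = 0.92), because the generator plants exactly these effects.

The full pipeline, writing every report table plus a run manifest:

```r
run_pipeline(default_run_config(seed = 1), out_dir = "out/")
```

or from the shell:

```sh
Rscript inst/cli/neoimmune run-all --config demo.yaml --out out/ --seed 1
Rscript inst/cli/neoimmune simulate --seed 7 --out cohort/
Rscript inst/cli/neoimmune config-init --out demo.yaml
```

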