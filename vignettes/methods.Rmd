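---
title: "Methods: immunophenotyping, repair stratification and neoantigen calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoimmune)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their
defaults and units, what the synthetic cohort emulates (and what it does
not), and the numerical decisions taken where the underlying methodology
leaves room.

## 1. Single-sample metagene enrichment

**Model.** Infiltration of a bulk tumor sample by an immune cell type is
inferred from the coordinated over-expression of that cell type's
*metagene* set. Within a sample, all genes are ranked by their cohort
z-score (per gene, `(x − mean)/sd` across samples, sample SD with
ddof = 1; a constant gene has z ≡ 0), descending, with ties broken by
gene name so that runs are deterministic. The enrichment score is the
weighted Kolmogorov–Smirnov running-sum statistic: walking down the
ranked list, the sum gains `|z_i|^α / Σ_hits |z|^α` at set genes and
loses `1/(N − n_h)` elsewhere; ES is the deviation of maximal magnitude,
in [−1, 1]. When the positive and negative extremes tie exactly, the
positive one is reported (the tie is resolved with a 1e-9 tolerance so
floating-point noise in the two running sums cannot flip the sign).

**Null and calling.** Because calls are per-sample, a phenotype
permutation null is undefined; the package permutes *gene labels*:
`n_permutations` random sets of the same size are scored on the same
ranked list and `p = (1 + #{|ES_perm| ≥ |ES_obs|}) / (n_permutations + 1)`.
Within each sample, p-values for the panel's cell types are adjusted by
Benjamini–Hochberg — the FDR family is the cell types within one sample,
matching the per-sample decision "is this tumor infiltrated?". A cell
type is called positive at `q ≤ q_threshold` (default **0.10**) with
`ES > 0` (positive infiltration means enrichment, not depletion). Inside
`call_infiltration()` the permutation draws are shared across cell types
of equal set size within a sample; the null law depends only on set
size, so each p-value is marginally identical to an independent draw,
and the shared draws keep the 999-permutation default affordable.

Note the resolution limit: the smallest achievable p is
`1/(n_permutations + 1)`, and after BH across `m` cell types the smallest
achievable q is roughly `m/(n_permutations + 1)`. With 28 cell types,
fewer than ~300 permutations can make a q ≤ 0.10 call impossible; the
default of 999 leaves headroom.

**Parameters.** `n_permutations` (≥ 100, default 999), `q_threshold`
(default 0.10), `weight_exponent` α (default 1; 0 gives the classic
unweighted KS statistic), `require_positive_es` (default TRUE), `seed`.

## 2. Burden, spectrum and DNA repair status

"Mutation count" counts **nonsynonymous** records (missense, nonsense,
frameshift, splice; silent excluded) — the downstream neoantigen logic
concerns nonsynonymous mutations — and is configurable to include silent
records. Cohort splits: the **median split** labels a sample `high` iff
its count is strictly above the cohort median (ties at the median go to
`low`, so `#high ≤ n/2`); the **top-quartile split** uses the
linear-interpolation 75th percentile with ties excluded from the top.
Both tie rules are arbitrary where the underlying convention is silent;
they are fixed, documented here, and stated in output metadata through
the split labels themselves.

Repair status is deliberately crude, by design of the underlying
methodology: a sample is HR/MMR/POLE-mutant iff it carries ≥ 1
nonsynonymous mutation in the pathway's gene list, with no pathogenicity
scoring. The default lists are 15 HR genes (ATR, ATM, CHEK1, CHEK2,
BRCA1, BRCA2, BAP1, BARD1, FANCD2, FANCE, FANCC, FANCA, RAD50, RAD51,
PALB2), 18 MMR genes (MLH1, MLH3, MSH2, MSH3, MSH4, MSH5, MSH6, PMS1,
PMS2, PMS2L3, PCNA, EXO1, POLD1, RFC1, RFC2, RFC3, RFC4, RFC5) and POLE;
all overridable. The substitution spectrum complements purine-reference
SNVs onto the six pyrimidine-reference classes (G>T ≡ C>A), reporting
per-sample fractions; samples without SNVs are flagged undefined rather
than given fractions. Type-I-interferon-pathway mutation rates
(GO:0060337) are computed from a user-supplied GMT — GO releases drift,
so the membership is configuration, not code.

## 3. Neoantigen enumeration and filtering

Scope: **missense SNVs only**. Frameshift and stop-loss neopeptides are
excluded because the 9-mer "window around a substituted residue"
procedure does not define them; the variant table keeps an extension
point. For a mutation at protein position `p` in a protein of length
`L`, the mutant windows are starts `s ∈ [max(1, p−k+1), min(p, L−k+1)]`
(k = 9 by default): every k-mer containing the site, exactly k of them
for interior sites. Each mutant peptide is paired with the homologous
wildtype k-mer; pairs differ at exactly one position. Peptides containing
`X` are dropped (binding prediction is undefined on them).

Each pair is scored against the sample's six class-I alleles
(homozygous repeats collapse — irrelevant to the variant-level count
unit). The filter is, with **strict** inequalities exactly as the
thresholds are conventionally printed:

* mutant IC50 **< 500 nM** (predicted binder),
* wildtype IC50 **> 500 nM** (wildtype is a weak or non-binder),
* expression of the mutated gene in that sample **> 0** on the linear
  normalized scale ("positive expression"; whether the original analyses
  used a z-score cut instead is unstated — the linear-scale rule is the
  default and `expression_min` is configurable).

A mutation is a neoantigen iff ≥ 1 pair passes; **load counts
mutations**, not pairs (pair-level tables are emitted for transparency).
Raising `mutant_ic50_max` or lowering `wt_ic50_min` can only add passing
pairs, so load is monotone in the thresholds — a property the test suite
asserts.

The package never runs an external predictor. It ships (a) an adapter
for tabular predictor output and (b) a deterministic toy predictor: per
allele, a packaged 9×20 position-weight table; a peptide's score `s` is
the sum of per-position weights, mapped to nanomolar through the
decreasing function `IC50 = 50000^(1 − s/9)`, the conventional affinity
transform. The weights are uniform on [0, 1] (frozen in
`inst/extdata/toy_pwm.tsv`), which puts the 500 nM threshold
(`s ≈ 3.83`) below the central score (`E[s] = 4.5`): single-residue
changes frequently cross it in either direction, so mutant-binder /
wildtype-non-binder events are common enough for loads to track burden
without being trivial. The table is a synthetic stand-in, not a model of
any real allele.

## 4. Statistics

Two-proportion comparisons use the pooled z statistic (two-sided normal
p; degenerate pooled proportions return z = 0, p = 1 with a warning) —
its square is algebraically the uncorrected 2×2 chi-square, an identity
the tests verify exhaustively for n ≤ 30. Mean comparisons are unpaired
two-tailed t tests; **Welch is the default** (which comparisons
originally used Student vs Welch is unstated; the choice is configurable
per call) with Welch–Satterthwaite degrees of freedom, reported as
mean ± SEM. Pearson correlations get p from the t transform with n − 2
df. Co-occurrence uses Fisher's exact test (hypergeometric
point-probability rule, the `fisher.test` convention including its 1e-7
relative tolerance) rather than the proportion z — call matrices have
small cells; the z test remains the instrument for prevalence
comparisons. Survival uses the product-limit estimator and the
Mantel–Haenszel log-rank chi-square with G − 1 df (singular variance
matrices fall back to a pseudoinverse). Fold-change tables exclude cell
types with fewer than 10 positive calls overall (configurable), report
`Inf` over a zero denominator, and carry the `*`/`**`/`***` significance
stars (p < 0.05 / 0.01 / 0.001) as a presentation column. No
multiple-testing correction is applied across the gene-correlation panel
by default (per-gene significance is reported); `bh_fdr()` is available
when a corrected view is wanted.

## 5. The synthetic cohort: what it emulates

`generate_cohort()` plants exactly the statistical structure the
analysis assumes, with ground truth recorded for every layer:

* **Burden.** Nonsynonymous counts are Poisson(λ₀) for repair-wildtype
  samples and Poisson(ρ·λ₀) for repair-mutant ones (defaults λ₀ = 5,
  ρ = 3 — small counts chosen so the whole chain, including peptide
  scoring, runs in seconds; the effect *ratio* is what matters, not the
  absolute TMB scale of real lung tumors). Every flagged sample is
  guaranteed ≥ 1 missense mutation in its pathway's list; bulk mutations
  avoid repair genes, so planted flags are recoverable *exactly* from
  the MAF. Substitution classes are drawn from a configurable 6-class
  distribution (default C>A-rich, echoing a smoking-like spectrum) and
  emitted on either strand to exercise collapsing.
* **Expression.** Per-gene log-normal baseline (log-mean per gene from
  N(2, 1), noise SD σ = 0.5). Truly infiltrated samples (fraction 0.3
  per cell type; optionally two cell types co-planted on the same
  samples) get +δ added to the log-expression of the cell type's
  metagene set (default δ = 1 = 2σ; recovery tests use δ = 3σ as their
  stated operating point).
* **Coupling.** A configurable immune-response gene list (checkpoints,
  cytotoxicity, IFN-γ axis) has expression α + β·load + noise
  (α = 5, β = 0.5, noise SD 1) — these genes are never mutated, so the
  coupling cannot feed back into the load itself.
* **Survival.** Exponential, hazard h₀·exp(−γ·1[top load quartile])
  (h₀ = log 2 / 30 months, γ = 0.7), independent exponential censoring
  (median 90 months), administrative cap at 240 months.
* **Mutation realism.** Mutations are generated at protein level (gene,
  position, ref→alt residue) with genomic fields synthesized
  consistently; the analysis consumes protein-level changes, so
  nucleotide-level realism would add nothing the pipeline reads.

What it does **not** emulate: mutational signatures in sequence context,
germline variation, transcript isoforms, realistic TMB scales,
inter-gene expression correlation beyond the planted structure, or a
real metagene panel (sets are disjoint synthetic symbols). A green
recovery test therefore establishes that the pipeline's inference is
correct *under its own assumptions* — not that those assumptions hold in
any real cohort.

## 6. Reproducibility and degenerate inputs

All randomness flows from explicit integer seeds through a private RNG
scope (the caller's `.Random.seed` is never touched); identical
configuration gives byte-identical emitted files and report tables, and
the run manifest records a configuration hash that changes iff any
configuration value changes. Degenerate inputs have defined behavior
rather than errors where a value is representable: constant genes have
zero z-scores, all-equal burdens split entirely to `low` with a warning,
`q_threshold = 0` produces no calls, degenerate 2×2 margins give `ns`
with a warning, and all-censored survival input is a hard error (the
log-rank test does not exist there).

## 7. Open choices made here

* Config files are YAML (JSON accepted), validated against the defaults
  tree, with every threshold — 500 nM, q ≤ 0.10, α = 0.05, quartile
  boundaries — inspectable in one place (`config-init`).
* The expression file carries linear-scale normalized values; z-scores
  are always recomputed internally rather than read, since both views
  are needed (ranking vs the positivity filter) and recomputation keeps
  them consistent.
* Which cell types count as "T cell subtypes" for the any-T-cell
  aggregate is panel configuration (`tcell_subtypes`), not code: the
  canonical 28-type panel does not itself fix the grouping.
* The MAF reader takes a configurable column map (defaults:
  `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`,
  `HGVSp_Short`) because MAF dialects vary across portals.
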