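Package: neoimmune
Title: Tumor Immunophenotyping, DNA Repair Stratification and Neoantigen
    Calling for Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested pipeline for immunogenomic analysis of
    tumor cohorts: metagene-based immune cell infiltration calling from
    bulk expression (per-sample weighted Kolmogorov-Smirnov enrichment
    with a gene-permutation null and Benjamini-Hochberg calling),
    DNA-repair-pathway (homologous recombination, mismatch repair, POLE)
    mutation stratification, class-I MHC neoantigen enumeration and
    filtering from missense mutations, and the downstream association
    statistics (proportion z tests, t tests, Pearson correlation,
    Fisher exact co-occurrence, Kaplan-Meier/log-rank survival). Ships a
    fully seeded synthetic cohort generator with planted ground truth so
    the complete analysis is testable without external data, plus a
    command-line entry point orchestrating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
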