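#' Mutational burden, substitution spectrum and DNA repair stratification
#'
#' Per-sample nonsynonymous mutation counts, strand-collapsed substitution
#' spectra, classification of samples by mutations in DNA repair pathways
#' (homologous recombination, mismatch repair, POLE), median/quartile
#' group splits, per-gene mutation-rate comparisons between groups, and an
#' oncogene-positivity rule engine.
#'
#' @name mutation_repair
NULL

NONSYN_CLASSES <- c("missense", "nonsense", "frameshift", "splice")

#' DNA repair pathway gene lists
#'
#' Default homologous recombination (15 genes), mismatch repair (18 genes)
#' and POLE lists used for repair-status classification. Each component
#' can be overridden.
#'
#' @param hr,mmr,pole Character vectors of gene symbols.
#' @return Named list of the three gene sets.
#' @export
repair_gene_sets <- function(
    hr = c("ATR", "ATM", "CHEK1", "CHEK2", "BRCA1", "BRCA2", "BAP1",
           "BARD1", "FANCD2", "FANCE", "FANCC", "FANCA", "RAD50", "RAD51",
           "PALB2"),
    mmr = c("MLH1", "MLH3", "MSH2", "MSH3", "MSH4", "MSH5", "MSH6",
            "PMS1", "PMS2", "PMS2L3", "PCNA", "EXO1", "POLD1", "RFC1",
            "RFC2", "RFC3", "RFC4", "RFC5"),
    pole = "POLE") {
  list(hr = unique(hr), mmr = unique(mmr), pole = unique(pole))
}

#' Per-sample mutational burden
#'
#' Counts records whose normalized variant class falls in
#' `counted_classes` (default: the nonsynonymous classes; silent
#' excluded). Samples listed in `samples` but absent from the table get
#' count 0.
#'
#' @param muts Mutation data frame (see [read_maf()]).
#' @param counted_classes Character vector of counted classes.
#' @param samples Optional cohort roster (character vector).
#' @return Object of class `burden_table`: data frame `sample_id`,
#'   `burden`, with attributes `median` and `quartiles`.
#' @export
mutation_burden <- function(muts, counted_classes = NONSYN_CLASSES,
                            samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(muts$sample_id))
  counted <- muts$variant_classification %in% counted_classes
  counts <- tabulate(match(muts$sample_id[counted], samples),
                     nbins = length(samples))
  out <- data.frame(sample_id = samples, burden = counts,
                    stringsAsFactors = FALSE)
  attr(out, "median") <- stats::median(counts)
  attr(out, "quartiles") <- quantile(counts, c(0.25, 0.5, 0.75))
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Classify samples by DNA repair pathway mutations
#'
#' A sample is pathway-mutant iff it carries at least one mutation of a
#' counted (default nonsynonymous) class in any gene of that pathway's
#' list; no pathogenicity scoring is applied. Also counts the number of
#' distinct mutated pathway genes per sample.
#'
#' @param muts Mutation data frame.
#' @param sets Pathway lists from [repair_gene_sets()].
#' @param counted_classes Qualifying variant classes.
#' @param samples Optional cohort roster.
#' @return Data frame: sample_id, hr_mut, mmr_mut, pole_mut, n_hr_genes,
#'   n_mmr_genes.
#' @export
classify_repair <- function(muts, sets = repair_gene_sets(),
                            counted_classes = NONSYN_CLASSES,
                            samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(muts$sample_id))
  counted <- muts[muts$variant_classification %in% counted_classes, ,
                  drop = FALSE]
  n_genes_in <- function(genes) {
    sub <- counted[counted$hugo_symbol %in% genes,
                   c("sample_id", "hugo_symbol")]
    sub <- unique(sub)
    tabulate(match(sub$sample_id, samples), nbins = length(samples))
  }
  n_hr <- n_genes_in(sets$hr)
  n_mmr <- n_genes_in(sets$mmr)
  n_pole <- n_genes_in(sets$pole)
  data.frame(sample_id = samples,
             hr_mut = n_hr >= 1L, mmr_mut = n_mmr >= 1L,
             pole_mut = n_pole >= 1L,
             n_hr_genes = n_hr, n_mmr_genes = n_mmr,
             stringsAsFactors = FALSE)
}

#' Strand-collapsed substitution spectrum
#'
#' Single-nucleotide substitutions with a purine reference are
#' complemented onto the six pyrimidine-reference classes (`G>T` counts as
#' `C>A`, etc.); per-sample class fractions are returned. Non-SNV records
#' are ignored (their count is reported as an attribute); samples without
#' any SNV get `NA` fractions and `defined = FALSE`.
#'
#' @param muts Mutation data frame.
#' @param samples Optional cohort roster.
#' @return Data frame: sample_id, n_snv, defined, and one fraction column
#'   per class `C>A, C>G, C>T, T>A, T>C, T>G`; attribute `n_non_snv`.
#' @export
substitution_spectrum <- function(muts, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(muts$sample_id))
  is_snv <- nchar(muts$ref_allele) == 1L & nchar(muts$alt_allele) == 1L &
    muts$ref_allele %in% names(COMPLEMENT) &
    muts$alt_allele %in% names(COMPLEMENT)
  snv <- muts[is_snv, , drop = FALSE]
  ref <- snv$ref_allele
  alt <- snv$alt_allele
  flip <- ref %in% c("A", "G")
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  cls <- paste0(ref, ">", alt)
  tab <- table(factor(snv$sample_id, levels = samples),
               factor(cls, levels = SUBST_CLASSES))
  counts <- matrix(as.integer(tab), nrow = length(samples),
                   dimnames = list(samples, SUBST_CLASSES))
  n_snv <- rowSums(counts)
  frac <- counts / ifelse(n_snv > 0, n_snv, 1)
  frac[n_snv == 0, ] <- NA_real_
  out <- data.frame(sample_id = samples, n_snv = n_snv,
                    defined = n_snv > 0, frac, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_non_snv") <- sum(!is_snv)
  out
}

#' Median split of a burden table
#'
#' `high` iff count strictly above the cohort median; ties at the median
#' are assigned `low`.
#'
#' @param b A `burden_table` (or data frame with `sample_id`, `burden`).
#' @return Named character vector (`high`/`low`) over samples.
#' @export
median_split <- function(b) {
  if (nrow(b) < 2L) data_error("median split needs >= 2 samples")
  med <- stats::median(b$burden)
  if (all(b$burden == b$burden[1])) {
    warning("all burden values identical; every sample labelled low",
            call. = FALSE)
  }
  setNames(ifelse(b$burden > med, "high", "low"), b$sample_id)
}

#' Top-quartile split
#'
#' `top_quartile` iff the value is strictly above the 75th percentile
#' (linear-interpolation percentile, R type 7); ties at the boundary are
#' excluded from the top.
#'
#' @param values Named numeric vector (names = sample ids).
#' @return Named character vector (`top_quartile`/`rest`).
#' @export
quartile_split <- function(values) {
  if (length(values) < 4L) data_error("quartile split needs >= 4 samples")
  p75 <- unname(quantile(values, 0.75, type = 7))
  if (all(values == values[1])) {
    warning("all values identical; top quartile is empty", call. = FALSE)
  }
  setNames(ifelse(values > p75, "top_quartile", "rest"), names(values))
}

#' Per-gene mutation rates between two sample groups
#'
#' For every gene of a panel: the fraction of samples carrying a counted
#' mutation in each group, with the two-proportion z test.
#'
#' @param muts Mutation data frame.
#' @param genes Character vector of panel genes.
#' @param groups Named character/factor vector over all samples (two
#'   levels).
#' @param counted_classes Qualifying variant classes.
#' @return Data frame: gene, per-group n/x/fraction, z, p, stars.
#' @export
gene_panel_mutation_rates <- function(muts, genes, groups,
                                      counted_classes = NONSYN_CLASSES) {
  if (!length(genes)) {
    return(data.frame(gene = character(0), stringsAsFactors = FALSE))
  }
  lv <- unique(as.character(groups))
  if (length(lv) != 2L) config_error("groups must have exactly two levels")
  samples <- names(groups)
  counted <- muts[muts$variant_classification %in% counted_classes &
                    muts$hugo_symbol %in% genes, c("sample_id", "hugo_symbol")]
  counted <- unique(counted)
  out <- lapply(genes, function(g) {
    mut_samples <- counted$sample_id[counted$hugo_symbol == g]
    x1 <- sum(samples[groups == lv[1]] %in% mut_samples)
    x2 <- sum(samples[groups == lv[2]] %in% mut_samples)
    n1 <- sum(groups == lv[1]); n2 <- sum(groups == lv[2])
    zt <- two_proportion_z(x1, n1, x2, n2)
    data.frame(gene = g, group1 = lv[1], group2 = lv[2],
               n1 = n1, x1 = x1, frac1 = x1 / n1,
               n2 = n2, x2 = x2, frac2 = x2 / n2,
               z = zt$z, p = zt$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$stars <- p_stars(res$p)
  res
}

#' Default RTK/RAS/RAF oncogene positivity rules
#'
#' Ships as an editable TSV (`extdata/oncogene_rules.tsv`): columns
#' `gene`, `match` (`protein` or `class`), `value` (a protein-change glob
#' like `p.G12*`, or a variant class name).
#'
#' @return Data frame of rules.
#' @export
oncogene_rules <- function() {
  read_tsv(system.file("extdata", "oncogene_rules.tsv",
                       package = "neoimmune", mustWork = TRUE))
}

glob_to_regex <- function(glob) utils::glob2rx(glob)

#' Oncogene positivity per sample
#'
#' A sample is positive iff at least one mutation matches a rule: same
#' gene, and either protein_change matching the rule's glob pattern
#' (`match = "protein"`) or variant class equal to the rule's value
#' (`match = "class"`).
#'
#' @param muts Mutation data frame.
#' @param rules Rule table, see [oncogene_rules()].
#' @param samples Optional cohort roster.
#' @return Named logical vector per sample.
#' @export
oncogene_positive <- function(muts, rules = oncogene_rules(),
                              samples = NULL) {
  if (is.null(rules) || !nrow(rules)) {
    config_error("oncogene rule set is empty")
  }
  if (!all(c("gene", "match", "value") %in% names(rules)) ||
      !all(rules$match %in% c("protein", "class"))) {
    config_error("malformed oncogene rules: need gene/match/value with match in protein|class")
  }
  if (is.null(samples)) samples <- sort(unique(muts$sample_id))
  hit <- rep(FALSE, nrow(muts))
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    sel <- muts$hugo_symbol == r$gene
    if (r$match == "protein") {
      sel <- sel & grepl(glob_to_regex(r$value), muts$protein_change)
    } else {
      sel <- sel & muts$variant_classification == r$value
    }
    hit <- hit | sel
  }
  pos_samples <- unique(muts$sample_id[hit])
  setNames(samples %in% pos_samples, samples)
}
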