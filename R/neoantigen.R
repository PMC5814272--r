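#' Neoantigen enumeration and filtering
#'
#' From each missense mutation, all k-mer (default 9-mer) mutant peptides
#' containing the mutated residue are enumerated together with their
#' homologous wildtype peptides, scored against the sample's six class-I
#' HLA alleles, and filtered: a peptide-allele pair passes when the mutant
#' IC50 is below 500 nM, the wildtype peptide is a weak or non-binder
#' (IC50 above 500 nM), and the mutated gene has positive expression in
#' that sample (all strict inequalities). A mutation is a neoantigen when
#' at least one pair passes; the per-sample neoantigen load counts such
#' mutations (not pairs).
#'
#' @name neoantigen
NULL

#' Neoantigen filter thresholds
#'
#' @param k Peptide length (>= 8; the packaged toy predictor supports 9).
#' @param mutant_ic50_max Mutant binding threshold, nM (pass iff strictly
#'   below).
#' @param wt_ic50_min Wildtype non-binder threshold, nM (pass iff strictly
#'   above).
#' @param expression_min Exclusive lower bound on the mutated gene's
#'   linear-scale expression in the sample.
#' @return Object of class `neoantigen_thresholds`.
#' @export
neoantigen_thresholds <- function(k = 9L, mutant_ic50_max = 500,
                                  wt_ic50_min = 500, expression_min = 0) {
  if (!is_count(k) || k < 8L) config_error("k must be an integer >= 8")
  if (!(mutant_ic50_max > 0) || !(wt_ic50_min > 0)) {
    config_error("IC50 thresholds must be > 0")
  }
  if (expression_min < 0) config_error("expression_min must be >= 0")
  structure(list(k = as.integer(k), mutant_ic50_max = mutant_ic50_max,
                 wt_ic50_min = wt_ic50_min, expression_min = expression_min),
            class = "neoantigen_thresholds")
}

#' Extract protein variants from a mutation table
#'
#' Missense SNVs only (the core scope); each row's HGVS-short protein
#' change is parsed into (position, ref_aa, alt_aa).
#'
#' @param muts Mutation data frame (see [read_maf()]).
#' @return Data frame: variant_id, sample_id, gene, transcript_id,
#'   position, ref_aa, alt_aa.
#' @export
variants_from_maf <- function(muts) {
  mis <- muts[muts$variant_classification == "missense", , drop = FALSE]
  pc <- parse_protein_change(mis$protein_change)
  data.frame(variant_id = seq_len(nrow(mis)),
             sample_id = mis$sample_id, gene = mis$hugo_symbol,
             transcript_id = mis$transcript_id,
             position = pc$position, ref_aa = pc$ref_aa, alt_aa = pc$alt_aa,
             stringsAsFactors = FALSE)
}

#' Apply a protein variant to a sequence
#'
#' @param protein Protein sequence (string).
#' @param position 1-based residue index.
#' @param ref_aa Expected reference residue at `position`.
#' @param alt_aa Replacement residue.
#' @return Mutant sequence, differing from the input only at `position`.
#' @export
apply_variant <- function(protein, position, ref_aa, alt_aa) {
  if (position < 1L || position > nchar(protein)) {
    stop_fmt("neoimmune_variant_mismatch",
             "variant position %d outside protein of length %d",
             position, nchar(protein))
  }
  if (substr(protein, position, position) != ref_aa) {
    stop_fmt("neoimmune_variant_mismatch",
             "reference mismatch at position %d: protein has '%s', variant expects '%s'",
             position, substr(protein, position, position), ref_aa)
  }
  substr(protein, position, position) <- alt_aa
  protein
}

#' Enumerate mutant/wildtype peptide pairs covering a mutated site
#'
#' All k-mer windows of the protein containing position `p`: window
#' starts `s` in `[max(1, p - k + 1), min(p, L - k + 1)]`, ordered by
#' `s`. For an interior site (`k <= p <= L - k + 1`) this yields exactly
#' `k` pairs. A protein shorter than `k` yields an empty list with a
#' warning.
#'
#' @param wt_seq,mut_seq Wildtype and mutant sequences (equal length,
#'   differing only at `p`).
#' @param p Mutated 1-based position.
#' @param k Peptide length.
#' @return Data frame: window_start, offset (mutated-residue index within
#'   the peptide, 1..k), wildtype_peptide, mutant_peptide.
#' @export
enumerate_peptides <- function(wt_seq, mut_seq, p, k = 9L) {
  L <- nchar(wt_seq)
  if (nchar(mut_seq) != L) data_error("sequences differ in length")
  if (p < 1L || p > L) data_error("mutated position outside sequence")
  if (substr(wt_seq, p, p) == substr(mut_seq, p, p)) {
    data_error("sequences do not differ at the mutated position")
  }
  if (L < k) {
    warning(sprintf("protein of length %d shorter than k = %d: no peptides",
                    L, k), call. = FALSE)
    return(data.frame(window_start = integer(0), offset = integer(0),
                      wildtype_peptide = character(0),
                      mutant_peptide = character(0)))
  }
  starts <- max(1L, p - k + 1L):min(p, L - k + 1L)
  data.frame(window_start = starts,
             offset = p - starts + 1L,
             wildtype_peptide = substring(wt_seq, starts, starts + k - 1L),
             mutant_peptide = substring(mut_seq, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Score peptide pairs against a sample's HLA genotype
#'
#' One row per pair and distinct allele (homozygous repeats collapse);
#' alleles on which the predictor fails are skipped with a warning.
#'
#' @param pairs Peptide-pair data frame from [enumerate_peptides()].
#' @param alleles Character vector of class-I alleles (typically 6).
#' @param predictor Function `(peptide, allele) -> IC50 nM`, vectorized.
#' @return `pairs` crossed with alleles, plus `allele`, `mutant_ic50`,
#'   `wildtype_ic50`.
#' @export
predict_pairs <- function(pairs, alleles, predictor = toy_binding_predictor) {
  alleles <- unique(alleles)
  if (!nrow(pairs)) {
    return(cbind(pairs[0, ], allele = character(0),
                 mutant_ic50 = numeric(0), wildtype_ic50 = numeric(0)))
  }
  out <- lapply(alleles, function(al) {
    res <- tryCatch({
      data.frame(pairs, allele = al,
                 mutant_ic50 = predictor(pairs$mutant_peptide, al),
                 wildtype_ic50 = predictor(pairs$wildtype_peptide, al),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("predictor failed for allele %s: %s (allele skipped)",
                      al, conditionMessage(e)), call. = FALSE)
      NULL
    })
    res
  })
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) data_error("predictor failed on every allele")
  rownames(res) <- NULL
  res
}

#' Filter scored pairs into neoantigen calls
#'
#' A (pair, allele) row passes iff `mutant_ic50 < mutant_ic50_max` and
#' `wildtype_ic50 > wt_ic50_min` and the mutated gene's expression in the
#' sample is `> expression_min` (all strict). A variant is a neoantigen
#' iff at least one of its rows passes; the per-sample load counts
#' neoantigen variants once each.
#'
#' @param predictions Data frame with columns `variant_id`, `allele`,
#'   `mutant_ic50`, `wildtype_ic50` (from [predict_pairs()], carrying
#'   `variant_id`).
#' @param variants Variant table (see [variants_from_maf()]); variants
#'   with no prediction rows are retained as non-neoantigens.
#' @param expr An `expr_matrix` for the expression filter. Genes absent
#'   from the matrix are treated as expression 0 and flagged with a
#'   warning.
#' @param thresholds A [neoantigen_thresholds()].
#' @param samples Optional cohort roster for the load table.
#' @return List: `calls` (variant table + `n_passing_pairs`,
#'   `is_neoantigen`), `passing_pairs` (the passing rows), `load`
#'   (data frame sample_id, load).
#' @export
call_neoantigens <- function(predictions, variants, expr,
                             thresholds = neoantigen_thresholds(),
                             samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  vsub <- variants[match(predictions$variant_id, variants$variant_id), ]
  gene_ok <- vsub$gene %in% rownames(expr$values)
  if (any(!gene_ok)) {
    warning(sprintf("%d prediction rows for genes absent from the expression matrix (expression treated as 0)",
                    sum(!gene_ok)), call. = FALSE)
  }
  expr_val <- numeric(nrow(predictions))
  idx <- which(gene_ok & vsub$sample_id %in% colnames(expr$values))
  expr_val[idx] <- expr$values[cbind(vsub$gene[idx],
                                     vsub$sample_id[idx])]
  pass <- predictions$mutant_ic50 < thresholds$mutant_ic50_max &
    predictions$wildtype_ic50 > thresholds$wt_ic50_min &
    expr_val > thresholds$expression_min
  n_pass <- tabulate(match(predictions$variant_id[pass],
                           variants$variant_id),
                     nbins = nrow(variants))
  calls <- variants
  calls$n_passing_pairs <- n_pass
  calls$is_neoantigen <- n_pass >= 1L
  load <- tabulate(match(calls$sample_id[calls$is_neoantigen], samples),
                   nbins = length(samples))
  list(calls = calls,
       passing_pairs = cbind(predictions[pass, , drop = FALSE],
                             expression = expr_val[pass]),
       load = data.frame(sample_id = samples, load = load,
                         stringsAsFactors = FALSE))
}

#' Run the full neoantigen stage
#'
#' Extracts missense variants from the mutation table, resolves each
#' against the protein FASTA (by transcript id, falling back to gene
#' symbol), applies the variant, enumerates peptide pairs, scores them
#' against the sample's HLA genotype and filters into calls. Variants
#' whose protein is missing, whose reference residue mismatches, or whose
#' peptides contain `X` are skipped with a warning tally.
#'
#' @param muts Mutation data frame.
#' @param proteins Named character vector of protein sequences.
#' @param hla HLA genotype data frame (see [read_hla()]).
#' @param expr An `expr_matrix`.
#' @param predictor Binding predictor function.
#' @param thresholds A [neoantigen_thresholds()].
#' @param samples Optional cohort roster.
#' @return As [call_neoantigens()], plus `skipped` (named counts).
#' @export
neoantigen_pipeline <- function(muts, proteins, hla, expr,
                                predictor = toy_binding_predictor,
                                thresholds = neoantigen_thresholds(),
                                samples = NULL) {
  vars <- variants_from_maf(muts)
  if (is.null(samples)) samples <- sort(unique(muts$sample_id))
  key <- ifelse(vars$transcript_id %in% names(proteins), vars$transcript_id,
                vars$gene)
  skipped <- c(no_protein = 0L, ref_mismatch = 0L, ambiguous_x = 0L,
               too_short = 0L)
  keep <- key %in% names(proteins)
  skipped["no_protein"] <- sum(!keep)
  vars <- vars[keep, , drop = FALSE]
  key <- key[keep]

  alleles_of <- split(
    as.character(unlist(hla[, c("a1", "a2", "b1", "b2", "c1", "c2")])),
    rep(hla$sample_id, 6L))

  pair_list <- vector("list", nrow(vars))
  ok <- logical(nrow(vars))
  for (i in seq_len(nrow(vars))) {
    wt <- proteins[[key[i]]]
    mut <- tryCatch(apply_variant(wt, vars$position[i], vars$ref_aa[i],
                                  vars$alt_aa[i]),
                    neoimmune_variant_mismatch = function(e) NULL)
    if (is.null(mut)) {
      skipped["ref_mismatch"] <- skipped["ref_mismatch"] + 1L
      next
    }
    pairs <- suppressWarnings(
      enumerate_peptides(wt, mut, vars$position[i], thresholds$k))
    if (!nrow(pairs)) {
      skipped["too_short"] <- skipped["too_short"] + 1L
      next
    }
    amb <- grepl("X", pairs$mutant_peptide, fixed = TRUE) |
      grepl("X", pairs$wildtype_peptide, fixed = TRUE)
    if (any(amb)) {
      skipped["ambiguous_x"] <- skipped["ambiguous_x"] + sum(amb)
      pairs <- pairs[!amb, , drop = FALSE]
      if (!nrow(pairs)) next
    }
    pairs$variant_id <- vars$variant_id[i]
    pair_list[[i]] <- pairs
    ok[i] <- TRUE
  }
  if (sum(skipped) > 0) {
    warning(sprintf("neoantigen stage skipped: %s",
                    paste(names(skipped), skipped, sep = "=", collapse = ", ")),
            call. = FALSE)
  }
  pairs_all <- do.call(rbind, pair_list[ok])
  if (is.null(pairs_all) || !nrow(pairs_all)) {
    calls <- vars
    calls$n_passing_pairs <- integer(nrow(vars))
    calls$is_neoantigen <- FALSE
    return(list(calls = calls, passing_pairs = NULL,
                load = data.frame(sample_id = samples,
                                  load = integer(length(samples))),
                skipped = skipped))
  }
  # expand pairs over each sample's distinct alleles, then score in one
  # vectorized predictor call
  vsample <- vars$sample_id[match(pairs_all$variant_id, vars$variant_id)]
  al_list <- lapply(alleles_of[vsample], unique)
  n_al <- lengths(al_list)
  pred <- pairs_all[rep(seq_len(nrow(pairs_all)), n_al), , drop = FALSE]
  pred$allele <- unlist(al_list, use.names = FALSE)
  pred$mutant_ic50 <- predictor(pred$mutant_peptide, pred$allele)
  pred$wildtype_ic50 <- predictor(pred$wildtype_peptide, pred$allele)
  rownames(pred) <- NULL
  out <- call_neoantigens(pred, vars, expr, thresholds, samples)
  out$skipped <- skipped
  out
}

PREDICTOR_DIALECTS <- list(
  tab = list(peptide = "peptide", allele = "allele", ic50 = "ic50"),
  netmhcpan = list(peptide = "Peptide", allele = "HLA", ic50 = "Aff(nM)")
)

#' Parse an external predictor's tabular output
#'
#' Adapter for affinity tables produced outside the package. Registered
#' dialects: `"tab"` (columns `peptide`, `allele`, `ic50`) and
#' `"netmhcpan"` (columns `Peptide`, `HLA`, `Aff(nM)`). Rows are joined
#' back to peptide pairs by exact mutant-peptide match when `pairs` is
#' supplied; unmatched rows are kept and reported via the `unmatched`
#' attribute and a warning.
#'
#' @param path Path to the tab-separated affinity table.
#' @param dialect Registered dialect name.
#' @param pairs Optional peptide-pair table (with `mutant_peptide`) to
#'   join against.
#' @return Data frame: peptide, allele, ic50 (+ pair columns when joined).
#' @export
parse_predictor_output <- function(path, dialect = "tab", pairs = NULL) {
  if (!dialect %in% names(PREDICTOR_DIALECTS)) {
    config_error("unknown predictor output dialect '%s' (registered: %s)",
                 dialect, paste(names(PREDICTOR_DIALECTS), collapse = ", "))
  }
  d <- PREDICTOR_DIALECTS[[dialect]]
  df <- read_tsv(path)
  miss <- setdiff(unlist(d), names(df))
  if (length(miss)) {
    format_error("predictor output %s missing column '%s'", path, miss[1])
  }
  ic50 <- suppressWarnings(as.numeric(df[[d$ic50]]))
  bad <- which(is.na(ic50))
  if (length(bad)) {
    record_error("predictor output %s row %d: non-numeric affinity '%s'",
                 path, bad[1], df[[d$ic50]][bad[1]])
  }
  out <- data.frame(peptide = as.character(df[[d$peptide]]),
                    allele = as.character(df[[d$allele]]),
                    ic50 = ic50, stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    m <- match(out$peptide, pairs$mutant_peptide)
    unmatched <- which(is.na(m))
    if (length(unmatched)) {
      warning(sprintf("%d predictor rows did not match any enumerated peptide",
                      length(unmatched)), call. = FALSE)
    }
    out <- cbind(out, pairs[m, setdiff(names(pairs), names(out)),
                            drop = FALSE])
    attr(out, "unmatched") <- unmatched
  }
  rownames(out) <- NULL
  out
}
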