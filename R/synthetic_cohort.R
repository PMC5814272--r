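#' Synthetic tumor cohort generator with planted ground truth
#'
#' Generates a complete cohort — somatic mutations (MAF-like table),
#' a genes x samples expression matrix, protein sequences, class-I HLA
#' genotypes and a clinical table — whose statistical structure mirrors
#' what the downstream analysis assumes:
#'
#' * per-sample nonsynonymous mutation counts are Poisson with baseline
#'   mean `lambda0`, multiplied by `rho` in DNA-repair-mutant samples;
#'   every repair-mutant sample is guaranteed at least one nonsynonymous
#'   mutation in the corresponding pathway gene list;
#' * samples truly infiltrated by an immune cell type have `delta` added
#'   to the log-expression of every gene in that cell type's metagene set;
#' * a configurable list of immune-response genes has expression
#'   `alpha + beta * (true neoantigen load) + noise`;
#' * survival is exponential with hazard
#'   `h0 * exp(-gamma * 1[top neoantigen-load quartile])`.
#'
#' All randomness derives from `seed`; identical configuration yields
#' byte-identical emitted files.
#'
#' @name synthetic_cohort
NULL

#' Build a metagene panel
#'
#' @param sets Named list of character gene vectors (one per immune cell
#'   type, order defines the cell-type order).
#' @param tcell_subtypes Character vector, subset of `names(sets)`,
#'   counted as T cell subtypes by [infiltration_prevalence()].
#' @return Object of class `metagene_panel`.
#' @export
metagene_panel <- function(sets, tcell_subtypes = character(0)) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    config_error("metagene panel needs at least one named gene set")
  }
  if (anyDuplicated(names(sets))) config_error("duplicate cell type names in panel")
  if (any(lengths(sets) == 0L)) config_error("empty metagene set in panel")
  sets <- lapply(sets, unique)
  if (!all(tcell_subtypes %in% names(sets))) {
    config_error("tcell_subtypes must be a subset of the panel's cell types")
  }
  structure(list(cell_types = names(sets), sets = sets,
                 tcell_subtypes = tcell_subtypes),
            class = "metagene_panel")
}

#' @export
print.metagene_panel <- function(x, ...) {
  cat(sprintf("metagene_panel: %d cell types (%d T cell subtypes), %d genes\n",
              length(x$cell_types), length(x$tcell_subtypes),
              length(unique(unlist(x$sets)))))
  invisible(x)
}

# The 28 immune cell types scored in the field's metagene immunophenotyping.
CELL_TYPES_28 <- c(
  "Activated CD4 T cell", "Activated CD8 T cell", "Effector memory CD4 T cell",
  "Effector memory CD8 T cell", "Central memory CD4 T cell",
  "Central memory CD8 T cell", "Th1 T cell", "Th2 T cell", "Th17 T cell",
  "Follicular helper T cell", "Regulatory T cell", "Gamma delta T cell",
  "NKT cell", "T cell", "Cytotoxic cell", "Activated B cell",
  "Immature B cell", "Memory B cell", "NK cell", "NK56bright cell",
  "Myeloid dendritic cell", "Plasmacytoid dendritic cell",
  "Immature dendritic cell", "Macrophage", "Monocyte", "Neutrophil",
  "Eosinophil", "MDSC")

TCELL_SUBTYPES_DEFAULT <- CELL_TYPES_28[1:15]

#' Synthetic metagene panel
#'
#' Builds a stand-in panel of disjoint synthetic metagene sets named after
#' the 28 immune cell types conventionally scored in tumor
#' immunophenotyping (the published 812-gene panel is not redistributed
#' here). Gene symbols are synthetic (`MG<set>_<idx>`).
#'
#' @param n_cell_types Number of cell types (first `n` of the 28).
#' @param genes_per_set Genes per metagene set.
#' @return A `metagene_panel`.
#' @export
synthetic_panel <- function(n_cell_types = 28L, genes_per_set = 30L) {
  if (n_cell_types < 1L || n_cell_types > length(CELL_TYPES_28)) {
    config_error("n_cell_types must be in 1..%d", length(CELL_TYPES_28))
  }
  types <- CELL_TYPES_28[seq_len(n_cell_types)]
  sets <- lapply(seq_len(n_cell_types), function(i) {
    sprintf("MG%02d_%03d", i, seq_len(genes_per_set))
  })
  names(sets) <- types
  metagene_panel(sets, intersect(TCELL_SUBTYPES_DEFAULT, types))
}

# Immune-response genes whose expression the generator couples to the true
# neoantigen load (names follow the genes highlighted in lung
# immunogenomics: checkpoints, cytotoxicity, IFN-gamma axis, chemokines).
IMMUNE_RESPONSE_GENES_DEFAULT <- c(
  "CD274", "PDCD1", "IFNG", "GZMB", "FASLG", "LAG3", "TAP2", "IL12RB2",
  "IL17RA", "TNFRSF25", "CCR1", "LTBR", "NOS2", "IL23A", "IL21", "CD8A")

# M1 / M2 macrophage polarization marker panels (defaults, configurable).
M1_GENES_DEFAULT <- c("NOS2", "IL23A", "IL12B", "CXCL10", "TNF")
M2_GENES_DEFAULT <- c("SOCS2", "CHIA", "CHI3L1", "CHI3L2", "KLF4", "MRC1")

HLA_POOL <- list(
  A = c("HLA-A*01:01", "HLA-A*02:01"),
  B = c("HLA-B*07:02", "HLA-B*08:01"),
  C = c("HLA-C*07:01", "HLA-C*07:02"))

#' Cohort generator configuration
#'
#' @param n_samples Number of tumor samples.
#' @param frac_hr_mut,frac_mmr_mut,frac_pole_mut Fractions of samples with
#'   a mutated homologous-recombination / mismatch-repair pathway / POLE.
#' @param lambda0 Baseline mean nonsynonymous mutations per sample
#'   (Poisson).
#' @param rho Burden multiplier (>= 1) for repair-mutant samples.
#' @param n_proteins Number of background protein-coding genes (besides
#'   the repair and oncogene loci, which always carry proteins).
#' @param protein_len_range Integer pair, protein length range (residues).
#' @param panel A [metagene_panel()]; defaults to [synthetic_panel()].
#' @param frac_infiltrated Per-cell-type fraction of truly infiltrated
#'   samples.
#' @param delta Log-expression shift added to a metagene set's genes in
#'   truly infiltrated samples.
#' @param sigma Log-expression noise SD.
#' @param alpha,beta Intercept and slope coupling immune-response-gene
#'   expression (linear scale) to the true neoantigen load.
#' @param sigma_irg Noise SD of the immune-response-gene coupling.
#' @param gamma Log-hazard decrement for the top neoantigen-load quartile.
#' @param h0 Baseline exponential hazard (per month).
#' @param censor_rate Exponential censoring hazard (per month).
#' @param spectrum_probs Named length-6 probability vector over the
#'   strand-collapsed substitution classes
#'   `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @param silent_rate Silent mutations as a fraction of the sample's
#'   nonsynonymous mean.
#' @param frac_oncogene Fraction of samples given an activating
#'   RTK/RAS/RAF mutation (KRAS G12C / BRAF V600E / EGFR L858R).
#' @param immune_response_genes Character vector of coupled gene names.
#' @param coplant Optional length-2 character vector of cell types that
#'   share the same infiltrated-sample set (planted co-occurrence).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 200L,
                          frac_hr_mut = 0.15, frac_mmr_mut = 0.15,
                          frac_pole_mut = 0.05,
                          lambda0 = 5, rho = 3,
                          n_proteins = 100L,
                          protein_len_range = c(60L, 300L),
                          panel = synthetic_panel(),
                          frac_infiltrated = 0.3,
                          delta = 1.0, sigma = 0.5,
                          alpha = 5, beta = 0.5, sigma_irg = 1,
                          gamma = 0.7, h0 = log(2) / 30,
                          censor_rate = log(2) / 90,
                          spectrum_probs = c("C>A" = 0.3, "C>G" = 0.1,
                                             "C>T" = 0.3, "T>A" = 0.1,
                                             "T>C" = 0.1, "T>G" = 0.1),
                          silent_rate = 0.15,
                          frac_oncogene = 0.3,
                          immune_response_genes = IMMUNE_RESPONSE_GENES_DEFAULT,
                          coplant = NULL,
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), frac_hr_mut = frac_hr_mut,
              frac_mmr_mut = frac_mmr_mut, frac_pole_mut = frac_pole_mut,
              lambda0 = lambda0, rho = rho, n_proteins = as.integer(n_proteins),
              protein_len_range = as.integer(protein_len_range), panel = panel,
              frac_infiltrated = frac_infiltrated, delta = delta, sigma = sigma,
              alpha = alpha, beta = beta, sigma_irg = sigma_irg, gamma = gamma,
              h0 = h0, censor_rate = censor_rate,
              spectrum_probs = spectrum_probs, silent_rate = silent_rate,
              frac_oncogene = frac_oncogene,
              immune_response_genes = immune_response_genes,
              coplant = coplant, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (f in c("frac_hr_mut", "frac_mmr_mut", "frac_pole_mut",
              "frac_infiltrated", "frac_oncogene")) {
    if (!is_fraction(cfg[[f]])) config_error("%s must be a fraction in [0,1]", f)
  }
  if (!(cfg$lambda0 > 0)) config_error("lambda0 must be > 0")
  if (!(cfg$rho >= 1)) config_error("rho must be >= 1")
  if (!(cfg$sigma > 0)) config_error("sigma must be > 0")
  if (cfg$n_samples < 2L) config_error("n_samples must be >= 2")
  if (length(cfg$protein_len_range) != 2L ||
      cfg$protein_len_range[1] < 20L ||
      cfg$protein_len_range[1] > cfg$protein_len_range[2]) {
    config_error("protein_len_range must be an increasing pair with min >= 20")
  }
  if (!inherits(cfg$panel, "metagene_panel")) {
    config_error("panel must be a metagene_panel")
  }
  if (abs(sum(cfg$spectrum_probs) - 1) > 1e-8 || length(cfg$spectrum_probs) != 6L) {
    config_error("spectrum_probs must be 6 probabilities summing to 1")
  }
  if (!is.null(cfg$coplant) &&
      (length(cfg$coplant) != 2L ||
       !all(cfg$coplant %in% cfg$panel$cell_types))) {
    config_error("coplant must name two cell types present in the panel")
  }
  if (!is_count(cfg$seed)) config_error("seed must be an integer")
  invisible(cfg)
}

SUBST_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# One missense record at a random interior residue of `gene`'s protein.
make_missense <- function(sample_id, gene, proteins, spectrum_probs) {
  seq <- proteins[[gene]]
  L <- nchar(seq)
  p <- sample(2:(L - 1L), 1L)
  ref <- substr(seq, p, p)
  alt <- sample(setdiff(AA20, ref), 1L)
  cls <- sample(SUBST_CLASSES, 1L, prob = spectrum_probs)
  nts <- strsplit(cls, ">")[[1]]
  if (runif(1) < 0.5) nts <- unname(COMPLEMENT[nts])  # emit either strand
  data.frame(sample_id = sample_id, hugo_symbol = gene,
             chrom = as.character(sample(1:22, 1L)),
             pos = sample(1e6:5e7, 1L),
             ref_allele = nts[1], alt_allele = nts[2],
             variant_classification = "missense",
             protein_change = sprintf("p.%s%d%s", ref, p, alt),
             transcript_id = paste0("TX_", gene),
             stringsAsFactors = FALSE)
}

make_nonmissense <- function(sample_id, gene, proteins, class) {
  seq <- proteins[[gene]]
  p <- sample(2:(nchar(seq) - 1L), 1L)
  ref <- substr(seq, p, p)
  pc <- switch(class,
               nonsense = sprintf("p.%s%d*", ref, p),
               frameshift = sprintf("p.%s%dfs", ref, p),
               splice = "",
               silent = sprintf("p.%s%d=", ref, p),
               "")
  alleles <- if (class == "frameshift") c("A", "AT") else {
    nts <- sample(names(COMPLEMENT), 2L)
    nts
  }
  data.frame(sample_id = sample_id, hugo_symbol = gene,
             chrom = as.character(sample(1:22, 1L)),
             pos = sample(1e6:5e7, 1L),
             ref_allele = alleles[1], alt_allele = alleles[2],
             variant_classification = class,
             protein_change = pc,
             transcript_id = paste0("TX_", gene),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' See [synthetic_cohort] for the planted statistical structure. The
#' returned object bundles the cohort tables, in the exact shapes the
#' package's readers produce, together with the planted ground truth.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, all cohort files and the
#'   truth ledger are written there (see [write_cohort()]).
#' @return Object of class `synthetic_cohort`: list with `mutations`,
#'   `expression` (an `expr_matrix`), `proteins`, `hla`, `clinical`,
#'   `panel`, `truth` (list: `repair`, `infiltration`, `load`,
#'   `neoantigen_variants`, `survival_group`) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  validate_cohort_config(config)
  cohort <- with_seed(config$seed, generate_cohort_impl(config))
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  repair_sets <- repair_gene_sets()

  ## --- repair status (planted truth) ------------------------------------
  hr <- runif(n) < cfg$frac_hr_mut
  mmr <- runif(n) < cfg$frac_mmr_mut
  pole <- runif(n) < cfg$frac_pole_mut
  any_repair <- hr | mmr | pole

  ## --- protein universe --------------------------------------------------
  onco_genes <- c("KRAS", "BRAF", "EGFR")
  coding_genes <- c(unlist(repair_sets, use.names = FALSE), onco_genes,
                    sprintf("GENE%04d", seq_len(cfg$n_proteins)))
  lens <- sample(cfg$protein_len_range[1]:cfg$protein_len_range[2],
                 length(coding_genes), replace = TRUE)
  proteins <- setNames(vapply(lens, random_protein, ""), coding_genes)
  # the shipped oncogene rules target KRAS codon 12; make the residue exist
  substr(proteins[["KRAS"]], 12, 12) <- "G"
  bg_genes <- setdiff(coding_genes, c(unlist(repair_sets), onco_genes))

  ## --- mutations ----------------------------------------------------------
  lam <- ifelse(any_repair, cfg$rho * cfg$lambda0, cfg$lambda0)
  nonsyn <- rpois(n, lam)
  forced <- hr + mmr + pole
  nonsyn <- pmax(nonsyn, forced)  # room for the guaranteed pathway hits
  recs <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    sid <- samples[i]
    rows <- list()
    if (hr[i])  rows[[length(rows) + 1L]] <-
      make_missense(sid, sample(repair_sets$hr, 1L), proteins, cfg$spectrum_probs)
    if (mmr[i]) rows[[length(rows) + 1L]] <-
      make_missense(sid, sample(repair_sets$mmr, 1L), proteins, cfg$spectrum_probs)
    if (pole[i]) rows[[length(rows) + 1L]] <-
      make_missense(sid, "POLE", proteins, cfg$spectrum_probs)
    n_rest <- nonsyn[i] - length(rows)
    if (n_rest > 0L) {
      classes <- sample(c("missense", "nonsense", "frameshift"), n_rest,
                        replace = TRUE, prob = c(0.85, 0.10, 0.05))
      for (cl in classes) {
        g <- sample(bg_genes, 1L)
        rows[[length(rows) + 1L]] <- if (cl == "missense") {
          make_missense(sid, g, proteins, cfg$spectrum_probs)
        } else make_nonmissense(sid, g, proteins, cl)
      }
    }
    n_sil <- rpois(1L, cfg$silent_rate * lam[i])
    for (j in seq_len(n_sil)) {
      rows[[length(rows) + 1L]] <-
        make_nonmissense(sid, sample(bg_genes, 1L), proteins, "silent")
    }
    if (runif(1) < cfg$frac_oncogene) {
      # activating RTK/RAS/RAF mutation: KRAS codon 12 missense
      r <- make_missense(sid, "KRAS", proteins, cfg$spectrum_probs)
      r$protein_change <- paste0("p.G12", sample(c("C", "D", "V", "A"), 1L))
      rows[[length(rows) + 1L]] <- r
    }
    k <- k + 1L
    recs[[k]] <- do.call(rbind, rows)
  }
  muts <- do.call(rbind, recs[seq_len(k)])
  rownames(muts) <- NULL
  muts$is_silent <- muts$variant_classification == "silent"

  ## --- expression ---------------------------------------------------------
  panel <- cfg$panel
  genes <- unique(c(unlist(panel$sets, use.names = FALSE),
                    cfg$immune_response_genes,
                    M1_GENES_DEFAULT, M2_GENES_DEFAULT,
                    coding_genes, sprintf("BGR%03d", 1:50)))
  G <- length(genes)
  mu_g <- rnorm(G, mean = 2, sd = 1)
  logexpr <- matrix(rnorm(G * n, mean = mu_g, sd = cfg$sigma), nrow = G,
                    dimnames = list(genes, samples))

  infiltration <- matrix(FALSE, nrow = n, ncol = length(panel$cell_types),
                         dimnames = list(samples, panel$cell_types))
  for (ct in panel$cell_types) {
    infiltration[, ct] <- runif(n) < cfg$frac_infiltrated
  }
  if (!is.null(cfg$coplant)) {
    infiltration[, cfg$coplant[2]] <- infiltration[, cfg$coplant[1]]
  }
  for (ct in panel$cell_types) {
    gs <- intersect(panel$sets[[ct]], genes)
    logexpr[gs, infiltration[, ct]] <-
      logexpr[gs, infiltration[, ct], drop = FALSE] + cfg$delta
  }
  values <- exp(logexpr)

  ## --- HLA ----------------------------------------------------------------
  hla <- data.frame(sample_id = samples,
                    a1 = sample(HLA_POOL$A, n, TRUE),
                    a2 = sample(HLA_POOL$A, n, TRUE),
                    b1 = sample(HLA_POOL$B, n, TRUE),
                    b2 = sample(HLA_POOL$B, n, TRUE),
                    c1 = sample(HLA_POOL$C, n, TRUE),
                    c2 = sample(HLA_POOL$C, n, TRUE),
                    stringsAsFactors = FALSE)

  ## --- true neoantigen load (toy predictor) -------------------------------
  # Immune-response genes are never mutated, so coupling their expression
  # to the load afterwards cannot change the load itself; the expression
  # filter only needs positivity of the mutated genes, already guaranteed.
  expr0 <- expression_matrix(values)
  calls <- neoantigen_pipeline(muts, proteins, hla, expr0,
                               predictor = toy_binding_predictor,
                               thresholds = neoantigen_thresholds(),
                               samples = samples)
  load <- calls$load$load
  names(load) <- calls$load$sample_id
  load <- load[samples]

  irg <- intersect(cfg$immune_response_genes, genes)
  irg_noise <- matrix(rnorm(length(irg) * n, 0, cfg$sigma_irg),
                      nrow = length(irg))
  values[irg, ] <- pmax(cfg$alpha + cfg$beta * rep(load, each = length(irg)) +
                          irg_noise, 0.01)
  expr <- expression_matrix(values)

  ## --- survival ------------------------------------------------------------
  qs <- quartile_split(load)
  top <- qs == "top_quartile"
  t_death <- rexp(n, rate = cfg$h0 * exp(-cfg$gamma * top))
  t_cens <- rexp(n, rate = cfg$censor_rate)
  os <- pmin(t_death, t_cens, 240)
  event <- as.integer(t_death <= t_cens & t_death <= 240)

  burden_true <- tabulate(match(muts$sample_id[!muts$is_silent], samples), n)
  clinical <- data.frame(
    sample_id = samples,
    os_months = round(os, 2),
    os_event = event,
    smoking_pack_years = round(pmax(rnorm(n, 10 + 2 * burden_true, 8), 0), 1),
    cluster_label = sample(c("cluster2", "cluster3", "cluster4"), n, TRUE),
    histology_label = sample(c("TRU", "PI", "PP"), n, TRUE),
    stringsAsFactors = FALSE)

  truth <- list(
    repair = data.frame(sample_id = samples, hr_mut = hr, mmr_mut = mmr,
                        pole_mut = pole, stringsAsFactors = FALSE),
    infiltration = infiltration,
    load = data.frame(sample_id = samples, load = unname(load),
                      stringsAsFactors = FALSE),
    neoantigen_variants = calls$calls[calls$calls$is_neoantigen,
                                      c("sample_id", "gene", "position",
                                        "ref_aa", "alt_aa")],
    survival_group = data.frame(sample_id = samples, group = unname(qs),
                                stringsAsFactors = FALSE))

  structure(list(samples = samples, mutations = muts, expression = expr,
                 proteins = proteins, hla = hla, clinical = clinical,
                 panel = panel, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d samples, %d mutations, ",
                     "%d genes, %d cell types\n"),
              length(x$samples), nrow(x$mutations),
              nrow(x$expression$values), length(x$panel$cell_types)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the package's readers consume: `mutations.maf`
#' (MAF-like TSV), `expression.tsv`, `proteins.fasta`, `panel.gmt` +
#' `tcell_subtypes.tsv`, `hla.tsv`, `clinical.tsv`, and a truth ledger
#' (`truth.tsv` per sample plus `truth.json`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_maf(cohort$mutations, file.path(dir, "mutations.maf"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_fasta(cohort$proteins, file.path(dir, "proteins.fasta"))
  write_gmt(cohort$panel$sets, file.path(dir, "panel.gmt"))
  write_tsv(data.frame(cell_type = cohort$panel$cell_types,
                       is_tcell = cohort$panel$cell_types %in%
                         cohort$panel$tcell_subtypes),
            file.path(dir, "tcell_subtypes.tsv"))
  write_tsv(cohort$hla, file.path(dir, "hla.tsv"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth_flat <- cbind(cohort$truth$repair,
                      load = cohort$truth$load$load,
                      survival_group = cohort$truth$survival_group$group,
                      as.data.frame(cohort$truth$infiltration[
                        cohort$truth$repair$sample_id, , drop = FALSE],
                        check.names = FALSE))
  rownames(truth_flat) <- NULL
  write_tsv(truth_flat, file.path(dir, "truth.tsv"))
  jsonlite::write_json(
    list(n_samples = length(cohort$samples),
         seed = cohort$config$seed,
         neoantigen_variants = cohort$truth$neoantigen_variants),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Verify ground-truth consistency of a generated cohort
#'
#' Checks the generator's contract: every flagged repair-mutant sample
#' carries at least one nonsynonymous mutation in the corresponding
#' pathway list, wildtype samples carry none, infiltration labels match
#' the panel, and the truth load table covers every sample.
#'
#' @param cohort A `synthetic_cohort`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
check_ground_truth <- function(cohort) {
  status <- classify_repair(cohort$mutations, samples = cohort$samples)
  tr <- cohort$truth$repair
  status <- status[match(tr$sample_id, status$sample_id), ]
  if (!identical(status$hr_mut, tr$hr_mut) ||
      !identical(status$mmr_mut, tr$mmr_mut) ||
      !identical(status$pole_mut, tr$pole_mut)) {
    data_error("ground truth inconsistency: repair flags do not match the MAF")
  }
  if (!identical(rownames(cohort$truth$infiltration), cohort$samples) ||
      !identical(colnames(cohort$truth$infiltration),
                 cohort$panel$cell_types)) {
    data_error("ground truth inconsistency: infiltration matrix shape")
  }
  if (!setequal(cohort$truth$load$sample_id, cohort$samples)) {
    data_error("ground truth inconsistency: load table samples")
  }
  invisible(TRUE)
}
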