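#' Pipeline orchestration
#'
#' [run_pipeline()] executes the full analysis — input loading (or
#' synthetic cohort generation), immunophenotyping, burden/repair
#' stratification, neoantigen calling, association statistics — writing
#' each stage's report tables before the next stage begins, plus a JSON
#' run manifest (seed, configuration hash, completed stages). A failure
#' aborts with a stage-labelled error; tables already written are kept.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' The full configuration tree with every threshold in one inspectable
#' place. `synthetic` is used when no `inputs` paths are given.
#'
#' @param seed Integer master seed.
#' @return Nested list (serializable as YAML/JSON).
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(n_samples = 60L, n_cell_types = 8L, genes_per_set = 30L,
                     frac_hr_mut = 0.15, frac_mmr_mut = 0.15,
                     frac_pole_mut = 0.05, lambda0 = 5, rho = 3,
                     frac_infiltrated = 0.3, delta = 1.0, sigma = 0.5,
                     beta = 0.5, gamma = 0.7),
    inputs = NULL,
    calling = list(n_permutations = 499L, q_threshold = 0.10,
                   weight_exponent = 1),
    thresholds = list(k = 9L, mutant_ic50_max = 500, wt_ic50_min = 500,
                      expression_min = 0),
    panels = list(immunomodulatory = IMMUNE_RESPONSE_GENES_DEFAULT,
                  m1 = M1_GENES_DEFAULT, m2 = M2_GENES_DEFAULT,
                  pd_l1 = "CD274", pd_1 = "PDCD1",
                  ifn = NULL, oncogene_rules = NULL),
    stats = list(mean_test = "welch", alpha = 0.05, min_samples_fold = 10L)
  )
}

read_run_config <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

load_cohort_inputs <- function(cfg, out_dir) {
  if (!is.null(cfg$inputs)) {
    ip <- cfg$inputs
    for (f in c("maf", "expression", "panel")) {
      if (is.null(ip[[f]])) config_error("inputs.%s is required", f)
      if (!file.exists(ip[[f]])) {
        data_error("stage io: input file not found: %s", ip[[f]])
      }
    }
    sets <- read_gmt(ip$panel)
    tsub <- character(0)
    if (!is.null(ip$tcell_subtypes) && file.exists(ip$tcell_subtypes)) {
      ts <- read_tsv(ip$tcell_subtypes)
      tsub <- ts$cell_type[as.logical(ts$is_tcell)]
    }
    expr <- read_expression(ip$expression)
    list(mutations = read_maf(ip$maf),
         expression = expr,
         proteins = if (!is.null(ip$proteins)) read_fasta(ip$proteins),
         hla = if (!is.null(ip$hla)) read_hla(ip$hla),
         clinical = if (!is.null(ip$clinical)) read_clinical(ip$clinical),
         panel = metagene_panel(sets, tsub),
         samples = colnames(expr$values),
         truth = NULL)
  } else {
    s <- cfg$synthetic
    cc <- cohort_config(
      n_samples = s$n_samples,
      panel = synthetic_panel(s$n_cell_types, s$genes_per_set),
      frac_hr_mut = s$frac_hr_mut, frac_mmr_mut = s$frac_mmr_mut,
      frac_pole_mut = s$frac_pole_mut, lambda0 = s$lambda0, rho = s$rho,
      frac_infiltrated = s$frac_infiltrated, delta = s$delta,
      sigma = s$sigma, beta = s$beta, gamma = s$gamma,
      seed = cfg$seed)
    cohort <- generate_cohort(cc, out_dir = file.path(out_dir, "cohort"))
    cohort
  }
}

pipeline_log <- function(level, stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", level, stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' @param config Configuration list (see [default_run_config()]) or a
#'   path to a YAML/JSON configuration file.
#' @param out_dir Output directory; created if needed.
#' @param stages Stages to run, in order, among `"immunophenotype"`,
#'   `"mutation_repair"`, `"neoantigen"`, `"stats"` (input loading always
#'   runs first).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results of each stage and
#'   the manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = c("immunophenotype", "mutation_repair",
                                    "neoantigen", "stats"),
                         quiet = FALSE) {
  if (is.character(config)) config <- merge_config(default_run_config(),
                                                   read_run_config(config))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_fn <- if (quiet) function(...) NULL else pipeline_log
  manifest <- list(package = "neoimmune",
                   version = as.character(utils::packageVersion("neoimmune")),
                   seed = config$seed,
                   config_hash = rlang::hash(config),
                   stages_completed = character(0))
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fn) {
    log_fn("info", name, "starting")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      save_manifest()
      stop_fmt("neoimmune_stage_error", "stage %s failed: %s", name,
               conditionMessage(e))
    })
    manifest$stages_completed <<- c(manifest$stages_completed, name)
    save_manifest()
    log_fn("info", name, "done in %.1fs", proc.time()[["elapsed"]] - t0)
    res
  }
  results <- list()

  ## stage io ---------------------------------------------------------------
  co <- run_stage("io", function() load_cohort_inputs(config, out_dir))
  results$cohort <- co
  samples <- co$samples
  expr <- co$expression
  muts <- co$mutations
  burden <- mutation_burden(muts, samples = samples)
  split_burden <- median_split(burden)
  welch <- config$stats$mean_test

  ## stage immunophenotype ---------------------------------------------------
  if ("immunophenotype" %in% stages) {
    results$infiltration <- run_stage("immunophenotype", function() {
      cc <- calling_config(n_permutations = config$calling$n_permutations,
                           q_threshold = config$calling$q_threshold,
                           weight_exponent = config$calling$weight_exponent,
                           seed = config$seed)
      inf <- call_infiltration(expr, co$panel, cc)
      write_tsv(inf$results, file.path(out_dir, "enrichment.tsv"))
      prev <- infiltration_prevalence(inf)
      ptab <- rbind(prev$per_cell_type,
                    data.frame(cell_type = c("any_tcell", "any_immune"),
                               n_positive = NA, n = nrow(inf$calls),
                               percent_positive = c(prev$any_tcell,
                                                    prev$any_immune)))
      write_tsv(ptab, file.path(out_dir, "prevalence.tsv"))
      cooc <- tryCatch(cooccurrence(inf, alpha = config$stats$alpha),
                       error = function(e) {
                         warning(conditionMessage(e), call. = FALSE)
                         NULL
                       })
      if (!is.null(cooc)) write_tsv(cooc, file.path(out_dir,
                                                    "cooccurrence.tsv"))
      list(matrix = inf, prevalence = prev, cooccurrence = cooc)
    })
  }

  ## stage mutation_repair ----------------------------------------------------
  if ("mutation_repair" %in% stages) {
    results$repair <- run_stage("mutation_repair", function() {
      write_tsv(burden, file.path(out_dir, "burden.tsv"))
      status <- classify_repair(muts, samples = samples)
      write_tsv(status, file.path(out_dir, "repair_status.tsv"))
      spec <- substitution_spectrum(muts, samples = samples)
      write_tsv(spec, file.path(out_dir, "spectrum.tsv"))
      groups <- data.frame(sample_id = samples,
                           burden_group = unname(split_burden[samples]),
                           stringsAsFactors = FALSE)
      write_tsv(groups, file.path(out_dir, "burden_groups.tsv"))
      rules <- if (!is.null(config$panels$oncogene_rules)) {
        read_tsv(config$panels$oncogene_rules)
      } else oncogene_rules()
      onco <- oncogene_positive(muts, rules, samples = samples)
      hi <- names(split_burden)[split_burden == "high"]
      lo <- names(split_burden)[split_burden == "low"]
      zt <- suppressWarnings(two_proportion_z(sum(onco[hi]), length(hi),
                                              sum(onco[lo]), length(lo)))
      onco_tab <- data.frame(label = "oncogene_positive",
                             n_high = length(hi), x_high = sum(onco[hi]),
                             percent_high = 100 * mean(onco[hi]),
                             n_low = length(lo), x_low = sum(onco[lo]),
                             percent_low = 100 * mean(onco[lo]),
                             z = zt$z, p = zt$p, stars = p_stars(zt$p))
      write_tsv(onco_tab, file.path(out_dir, "group_oncogene.tsv"))
      # cluster / histology labels: consumed as clinical metadata
      for (lab in c("cluster_label", "histology_label")) {
        cl <- co$clinical
        if (!is.null(cl) && lab %in% names(cl)) {
          labs <- setNames(cl[[lab]], cl$sample_id)[samples]
          tabs <- lapply(sort(unique(stats::na.omit(labs))), function(v) {
            zt <- suppressWarnings(two_proportion_z(
              sum(labs[hi] == v, na.rm = TRUE), length(hi),
              sum(labs[lo] == v, na.rm = TRUE), length(lo)))
            data.frame(label = v,
                       percent_high = 100 * mean(labs[hi] == v, na.rm = TRUE),
                       percent_low = 100 * mean(labs[lo] == v, na.rm = TRUE),
                       z = zt$z, p = zt$p, stars = p_stars(zt$p))
          })
          write_tsv(do.call(rbind, tabs),
                    file.path(out_dir, paste0("group_", sub("_label", "", lab),
                                              ".tsv")))
        }
      }
      ifn_tab <- NULL
      if (!is.null(config$panels$ifn)) {
        ifn_genes <- unlist(read_gmt(config$panels$ifn), use.names = FALSE)
        for (pw in c("hr", "mmr", "pole")) {
          flag <- setNames(status[[paste0(pw, "_mut")]], status$sample_id)
          g <- setNames(ifelse(flag[samples], "mut", "wt"), samples)
          tab <- gene_panel_mutation_rates(muts, unique(ifn_genes), g)
          tab$pathway <- pw
          ifn_tab <- rbind(ifn_tab, tab)
        }
        write_tsv(ifn_tab, file.path(out_dir, "ifn_mutation_rates.tsv"))
      }
      list(status = status, burden = burden, split = split_burden,
           oncogene = onco, spectrum = spec)
    })
  }

  ## stage neoantigen ----------------------------------------------------------
  if ("neoantigen" %in% stages) {
    results$neoantigen <- run_stage("neoantigen", function() {
      if (is.null(co$proteins) || is.null(co$hla)) {
        data_error("neoantigen stage needs proteins (FASTA) and HLA inputs")
      }
      th <- neoantigen_thresholds(
        k = config$thresholds$k,
        mutant_ic50_max = config$thresholds$mutant_ic50_max,
        wt_ic50_min = config$thresholds$wt_ic50_min,
        expression_min = config$thresholds$expression_min)
      neo <- suppressWarnings(
        neoantigen_pipeline(muts, co$proteins, co$hla, expr,
                            predictor = toy_binding_predictor,
                            thresholds = th, samples = samples))
      write_tsv(neo$calls, file.path(out_dir, "neoantigen_calls.tsv"))
      write_tsv(neo$load, file.path(out_dir, "neoantigen_load.tsv"))
      neo
    })
  }

  ## stage stats ---------------------------------------------------------------
  if ("stats" %in% stages) {
    results$stats <- run_stage("stats", function() {
      out <- list()
      status <- classify_repair(muts, samples = samples)
      b <- setNames(burden$burden, burden$sample_id)[samples]

      # burden-split infiltration fold change
      if (!is.null(results$infiltration)) {
        fc <- infiltration_fold_change(
          results$infiltration$matrix, split_burden,
          min_samples = config$stats$min_samples_fold, numerator = "high")
        write_tsv(fc, file.path(out_dir, "fold_change_burden.tsv"))
        out$fold_change_burden <- fc
      }

      # repair status vs burden / infiltration / neoantigen load
      rows <- NULL; inf_rows <- NULL
      loads <- if (!is.null(results$neoantigen)) {
        setNames(results$neoantigen$load$load,
                 results$neoantigen$load$sample_id)[samples]
      }
      for (pw in c("hr", "mmr", "pole")) {
        flag <- setNames(status[[paste0(pw, "_mut")]],
                         status$sample_id)[samples]
        if (sum(flag) >= 2 && sum(!flag) >= 2) {
          mt <- mean_test(b[flag], b[!flag], variant = welch)
          rows <- rbind(rows, data.frame(
            pathway = pw, measure = "burden", n_mut = mt$n1, n_wt = mt$n2,
            mean_mut = mt$mean1, sem_mut = mt$sem1,
            mean_wt = mt$mean2, sem_wt = mt$sem2,
            t = mt$t, p = mt$p, stars = p_stars(mt$p)))
          if (!is.null(loads)) {
            mt <- mean_test(loads[flag], loads[!flag], variant = welch)
            rows <- rbind(rows, data.frame(
              pathway = pw, measure = "neoantigen_load",
              n_mut = mt$n1, n_wt = mt$n2,
              mean_mut = mt$mean1, sem_mut = mt$sem1,
              mean_wt = mt$mean2, sem_wt = mt$sem2,
              t = mt$t, p = mt$p, stars = p_stars(mt$p)))
          }
        }
        if (!is.null(results$infiltration) && sum(flag) > 0 &&
            sum(!flag) > 0) {
          g <- setNames(ifelse(flag, "mut", "wt"), samples)
          fc <- infiltration_fold_change(results$infiltration$matrix, g,
                                         min_samples = 0L,
                                         numerator = "mut")
          fc$pathway <- pw
          inf_rows <- rbind(inf_rows, fc)
        }
      }
      if (!is.null(rows)) {
        write_tsv(rows, file.path(out_dir, "repair_comparisons.tsv"))
        out$repair_comparisons <- rows
      }
      if (!is.null(inf_rows)) {
        write_tsv(inf_rows, file.path(out_dir, "repair_infiltration.tsv"))
        out$repair_infiltration <- inf_rows
      }

      if (!is.null(loads)) {
        qs <- quartile_split(loads)
        if (!is.null(results$infiltration)) {
          fc <- infiltration_fold_change(results$infiltration$matrix, qs,
                                         min_samples = 0L,
                                         numerator = "top_quartile")
          write_tsv(fc, file.path(out_dir, "neoantigen_infiltration.tsv"))
          out$neoantigen_infiltration <- fc
        }
        # gene-expression correlations with load (Figure-5A-style panel)
        panel_genes <- intersect(config$panels$immunomodulatory,
                                 rownames(expr$values))
        cors <- lapply(panel_genes, function(g) {
          pc <- tryCatch(pearson_cor(loads, expr$values[g, samples]),
                         error = function(e) NULL)
          if (is.null(pc)) return(NULL)
          data.frame(gene = g, r = pc$r, p = pc$p, n = pc$n,
                     stars = p_stars(pc$p))
        })
        cors <- do.call(rbind, cors)
        if (!is.null(cors)) {
          write_tsv(cors, file.path(out_dir, "gene_correlations.tsv"))
          out$gene_correlations <- cors
        }
        # M1/M2 macrophage polarization and checkpoint genes, top quartile
        top <- names(qs)[qs == "top_quartile"]
        rest <- names(qs)[qs == "rest"]
        m1m2 <- NULL
        for (set in c("m1", "m2", "pd_l1", "pd_1")) {
          for (g in intersect(config$panels[[set]], rownames(expr$values))) {
            mt <- mean_test(expr$values[g, top], expr$values[g, rest],
                            variant = welch)
            m1m2 <- rbind(m1m2, data.frame(
              panel = set, gene = g,
              mean_high = mt$mean1, sem_high = mt$sem1,
              mean_low = mt$mean2, sem_low = mt$sem2,
              t = mt$t, p = mt$p, stars = p_stars(mt$p)))
          }
        }
        if (!is.null(m1m2)) {
          write_tsv(m1m2, file.path(out_dir, "expression_groups.tsv"))
          out$expression_groups <- m1m2
        }
        # survival: top quartile vs rest
        cl <- co$clinical
        if (!is.null(cl) && sum(cl$os_event) >= 1) {
          grp <- qs[cl$sample_id]
          if (length(unique(grp)) == 2) {
            km <- km_logrank(cl$os_months, cl$os_event, grp)
            surv_tab <- data.frame(comparison = "neoantigen_top_quartile",
                                   chisq = km$chisq, df = km$df, p = km$p,
                                   stars = p_stars(km$p))
            write_tsv(surv_tab, file.path(out_dir, "survival.tsv"))
            curves <- do.call(rbind, lapply(names(km$curves), function(g) {
              cbind(group = g, km$curves[[g]])
            }))
            write_tsv(curves, file.path(out_dir, "km_curves.tsv"))
            out$survival <- km
          }
        }
      }
      out
    })
  }
  results$manifest <- manifest
  invisible(results)
}
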