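#' Metagene-based immunophenotyping
#'
#' Calls per-sample infiltration by each immune cell type from single-
#' sample gene-set enrichment of the cell type's metagene set. Within each
#' sample, genes are ranked by their cohort z-score (descending; ties
#' broken by gene name for determinism), a weighted Kolmogorov-Smirnov
#' running-sum enrichment score is computed per cell type, a gene-label
#' permutation null gives the p-value, and Benjamini-Hochberg adjustment
#' across the cell types within the sample gives the q-value. A cell type
#' is called positively infiltrating when `q <= q_threshold` (default 10%)
#' and the enrichment score is positive.
#'
#' @name immunophenotype
NULL

#' Infiltration-calling configuration
#'
#' @param n_permutations Number of gene-label permutations (>= 100).
#' @param q_threshold FDR threshold for a positive call, in (0,1).
#' @param weight_exponent Exponent on |z| rank weights (0 = unweighted KS).
#' @param require_positive_es Require enrichment (not depletion) for a
#'   positive call.
#' @param seed RNG seed for the permutation null.
#' @return Object of class `calling_config`.
#' @export
calling_config <- function(n_permutations = 999L, q_threshold = 0.10,
                           weight_exponent = 1, require_positive_es = TRUE,
                           seed = 1L) {
  if (!is_count(n_permutations) || n_permutations < 100L) {
    config_error("n_permutations must be an integer >= 100")
  }
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold >= 1) {
    # q_threshold = 0 is allowed only as an explicit degenerate request
    if (!identical(as.numeric(q_threshold), 0)) {
      config_error("q_threshold must be in (0,1)")
    }
  }
  structure(list(n_permutations = as.integer(n_permutations),
                 q_threshold = q_threshold,
                 weight_exponent = weight_exponent,
                 require_positive_es = isTRUE(require_positive_es),
                 seed = as.integer(seed)),
            class = "calling_config")
}

# Core ES computation from hit positions in the ranked list. The running
# sum increments |w|^e / sum(|w|^e) at hits and decrements 1/(N - nh) at
# misses; ES is the deviation of maximal magnitude (ties between the
# positive and negative extreme resolve to the positive one).
es_from_hits <- function(hits, weights, N, exponent) {
  nh <- length(hits)
  if (nh == 0L) data_error("gene set has no genes in the ranked list")
  if (nh == N) return(1)
  w <- abs(weights[hits])^exponent
  sw <- sum(w)
  chit <- if (sw > 0) cumsum(w) / sw else seq_len(nh) / nh
  dec <- 1 / (N - nh)
  miss_before <- hits - seq_len(nh)
  peak <- chit - miss_before * dec                 # just after each hit
  trough <- c(0, chit[-nh]) - miss_before * dec    # just before each hit
  pos <- max(peak)
  neg <- min(trough, 0)
  # ties between the positive and negative extreme resolve to positive;
  # the tolerance absorbs floating-point noise in the two running sums
  if (pos >= -neg - 1e-9) pos else neg
}

#' Weighted KS enrichment score
#'
#' @param genes Character vector: genes ordered by a sample's expression
#'   z-score, descending (no duplicates).
#' @param weights Numeric rank weights aligned with `genes` (typically the
#'   z-scores themselves).
#' @param gene_set Character vector of set genes; must intersect `genes`.
#' @param exponent Weighting exponent (0 gives the classic unweighted KS
#'   statistic).
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(genes, weights, gene_set, exponent = 1) {
  if (anyDuplicated(genes)) data_error("ranked gene list contains duplicates")
  if (length(weights) != length(genes)) {
    data_error("weights must align with the ranked gene list")
  }
  hits <- which(genes %in% gene_set)
  es_from_hits(hits, weights, length(genes), exponent)
}

# Vectorised permutation null: |ES| for `n_perm` random hit sets of size
# nh against the fixed ranked weights. Uses the hit-position formulation,
# so cost is O(n_perm * nh), independent of list length.
null_abs_es <- function(weights, nh, n_perm, exponent) {
  N <- length(weights)
  if (nh >= N) return(rep(1, n_perm))
  H <- matrix(0L, nrow = nh, ncol = n_perm)
  for (j in seq_len(n_perm)) H[, j] <- sort.int(sample.int(N, nh))
  W <- matrix(abs(weights[H])^exponent, nrow = nh)
  CW <- if (nh == 1L) W else apply(W, 2L, cumsum)
  CW <- matrix(CW, nrow = nh)
  sw <- CW[nh, ]
  zero_w <- sw == 0
  chit <- sweep(CW, 2L, ifelse(zero_w, 1, sw), "/")
  if (any(zero_w)) chit[, zero_w] <- seq_len(nh) / nh
  dec <- 1 / (N - nh)
  MB <- H - seq_len(nh)
  peak <- chit - MB * dec
  trough <- rbind(0, chit[-nh, , drop = FALSE]) - MB * dec
  pos <- peak[cbind(max.col(t(peak), ties.method = "first"), seq_len(n_perm))]
  neg <- trough[cbind(max.col(t(-trough), ties.method = "first"),
                      seq_len(n_perm))]
  neg <- pmin(neg, 0)
  abs(ifelse(pos >= -neg, pos, neg))
}

#' Gene-label permutation p-value for an enrichment score
#'
#' Recomputes the score for `n_permutations` random gene sets of equal
#' size; `p = (1 + #{|es_perm| >= |es_obs|}) / (n_permutations + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_permutations Number of permutations.
#' @param seed RNG seed (identical seed gives identical p).
#' @return List with `es` and `p`.
#' @export
permutation_p <- function(genes, weights, gene_set, n_permutations = 999L,
                          seed = 1L, exponent = 1) {
  es <- enrichment_score(genes, weights, gene_set, exponent)
  nh <- sum(genes %in% gene_set)
  null <- with_seed(seed,
                    null_abs_es(weights, nh, n_permutations, exponent))
  p <- (1 + sum(null >= abs(es))) / (n_permutations + 1)
  list(es = es, p = p)
}

#' Call per-sample immune infiltration
#'
#' Per sample: rank all matrix genes by z-score (descending, gene-name
#' tie-break), score every panel cell type, compute gene-permutation
#' p-values (permutation draws are shared across cell types of equal set
#' size within a sample — the null law only depends on set size), adjust
#' across the cell types within the sample by Benjamini-Hochberg, and
#' threshold. Cell types with no genes in the matrix are excluded with a
#' warning; panel coverage is reported as an attribute.
#'
#' @param expr An `expr_matrix`.
#' @param panel A [metagene_panel()].
#' @param cfg A [calling_config()].
#' @return Object of class `infiltration_matrix`: list with `calls`
#'   (logical samples x cell-types matrix), `results` (tidy data frame:
#'   sample_id, cell_type, es, p, q, call), `panel`, `config`.
#' @export
call_infiltration <- function(expr, panel, cfg = calling_config()) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(panel, "metagene_panel"))
  z <- expr$zscores
  genes <- rownames(z)
  keep <- vapply(panel$sets, function(s) any(s %in% genes), TRUE)
  if (!all(keep)) {
    warning(sprintf("cell types with no panel genes in the matrix excluded: %s",
                    paste(panel$cell_types[!keep], collapse = ", ")),
            call. = FALSE)
  }
  cell_types <- panel$cell_types[keep]
  if (!length(cell_types)) data_error("no panel cell type overlaps the matrix")
  coverage <- vapply(panel$sets[cell_types],
                     function(s) mean(s %in% genes), 0)
  samples <- colnames(z)
  n_ct <- length(cell_types)
  res <- vector("list", length(samples))
  with_seed(cfg$seed, {
    for (i in seq_along(samples)) {
      zi <- z[, i]
      ord <- order(-zi, genes)     # z desc, gene-name lexicographic ties
      rg <- genes[ord]
      rw <- zi[ord]
      hitsets <- lapply(panel$sets[cell_types], function(s) which(rg %in% s))
      nhs <- lengths(hitsets)
      es <- vapply(seq_len(n_ct), function(j) {
        es_from_hits(hitsets[[j]], rw, length(rg), cfg$weight_exponent)
      }, 0)
      p <- numeric(n_ct)
      for (nh in unique(nhs)) {
        null <- null_abs_es(rw, nh, cfg$n_permutations, cfg$weight_exponent)
        sel <- which(nhs == nh)
        p[sel] <- vapply(es[sel], function(e) {
          (1 + sum(null >= abs(e))) / (cfg$n_permutations + 1)
        }, 0)
      }
      q <- bh_fdr(p)
      res[[i]] <- data.frame(sample_id = samples[i], cell_type = cell_types,
                             es = es, p = p, q = q,
                             stringsAsFactors = FALSE)
    }
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  results$call <- results$q <= cfg$q_threshold &
    (!cfg$require_positive_es | results$es > 0)
  calls <- matrix(FALSE, nrow = length(samples), ncol = n_ct,
                  dimnames = list(samples, cell_types))
  calls[cbind(match(results$sample_id, samples),
              match(results$cell_type, cell_types))] <- results$call
  structure(list(calls = calls, results = results, panel = panel,
                 config = cfg, coverage = coverage),
            class = "infiltration_matrix")
}

#' @export
print.infiltration_matrix <- function(x, ...) {
  cat(sprintf("infiltration_matrix: %d samples x %d cell types, %d positive calls\n",
              nrow(x$calls), ncol(x$calls), sum(x$calls)))
  invisible(x)
}

#' Infiltration prevalence
#'
#' Percent of samples positively infiltrated by each cell type, plus the
#' aggregates `any_tcell` (at least one positive T cell subtype) and
#' `any_immune` (at least one positive cell type overall).
#'
#' @param m An `infiltration_matrix` (or plain logical matrix).
#' @param panel Panel supplying `tcell_subtypes`; defaults to the matrix's
#'   own panel.
#' @return List with `per_cell_type` data frame (cell_type,
#'   percent_positive, n_positive, n) and scalars `any_tcell`,
#'   `any_immune` (percent).
#' @export
infiltration_prevalence <- function(m, panel = NULL) {
  calls <- if (inherits(m, "infiltration_matrix")) m$calls else m
  if (is.null(panel) && inherits(m, "infiltration_matrix")) panel <- m$panel
  if (!nrow(calls)) data_error("empty infiltration matrix")
  n <- nrow(calls)
  per <- data.frame(cell_type = colnames(calls),
                    n_positive = colSums(calls),
                    n = n,
                    percent_positive = 100 * colMeans(calls),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  tsub <- intersect(if (!is.null(panel)) panel$tcell_subtypes else character(0),
                    colnames(calls))
  any_tcell <- if (length(tsub)) {
    100 * mean(rowSums(calls[, tsub, drop = FALSE]) > 0)
  } else NA_real_
  any_immune <- 100 * mean(rowSums(calls) > 0)
  list(per_cell_type = per, any_tcell = any_tcell, any_immune = any_immune)
}

#' Pairwise infiltration co-occurrence
#'
#' For each unordered pair of cell types, a two-sided Fisher exact test
#' (hypergeometric point-probability rule) on the 2x2 contingency of
#' positive calls. Pairs are labelled `co-occur` (p < alpha, OR > 1),
#' `mutually exclusive` (p < alpha, OR < 1) or `ns`. Cell types with a
#' degenerate margin (all-true or all-false) yield `ns` with a warning.
#'
#' @param m An `infiltration_matrix` or logical samples x cell-types
#'   matrix.
#' @param alpha Significance level.
#' @return Data frame: cell_type_a, cell_type_b, n11/n10/n01/n00,
#'   odds_ratio, p, label.
#' @export
cooccurrence <- function(m, alpha = 0.05) {
  calls <- if (inherits(m, "infiltration_matrix")) m$calls else m
  ct <- colnames(calls)
  pos <- colSums(calls)
  if (sum(pos >= 1) < 2) data_error("need >= 2 cell types with positive calls")
  degen <- pos == 0 | pos == nrow(calls)
  if (any(degen)) {
    warning(sprintf("degenerate margin for: %s (pairs reported ns)",
                    paste(ct[degen], collapse = ", ")), call. = FALSE)
  }
  pairs <- utils::combn(seq_along(ct), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- sum(calls[, i] & calls[, j])
    b <- sum(calls[, i] & !calls[, j])
    cc <- sum(!calls[, i] & calls[, j])
    d <- sum(!calls[, i] & !calls[, j])
    if (degen[i] || degen[j]) {
      p <- NA_real_; or <- NA_real_; label <- "ns"
    } else {
      p <- fisher_exact_2x2(a, b, cc, d)
      or <- (a * d) / (b * cc)
      label <- if (!is.na(p) && p < alpha && is.finite(or) && or > 1) {
        "co-occur"
      } else if (!is.na(p) && p < alpha &&
                 ((is.finite(or) && or < 1) || (b * cc > 0 && a * d == 0))) {
        "mutually exclusive"
      } else if (!is.na(p) && p < alpha && is.infinite(or)) {
        "co-occur"
      } else "ns"
    }
    data.frame(cell_type_a = ct[i], cell_type_b = ct[j],
               n11 = a, n10 = b, n01 = cc, n00 = d,
               odds_ratio = or, p = p, label = label,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$stars <- p_stars(res$p)
  res
}
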