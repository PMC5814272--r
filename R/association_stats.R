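#' Association statistics
#'
#' The statistical layer of the pipeline: two-proportion z tests, unpaired
#' two-tailed Student/Welch t tests, Pearson correlation, Benjamini-
#' Hochberg FDR, Fisher's exact test on 2x2 tables (hypergeometric
#' point-probability rule), Kaplan-Meier estimation with the log-rank
#' test, and group fold-change tables for infiltration prevalence. All
#' tests are two-sided; Welch is the default for mean comparisons.
#'
#' @name association_stats
NULL

#' Two-proportion z test
#'
#' Pooled-proportion z statistic with a two-sided normal p-value. When the
#' pooled proportion is 0 or 1 the test degenerates: z = 0, p = 1, with a
#' warning.
#'
#' @param x1,n1 Successes and size of group 1.
#' @param x2,n2 Successes and size of group 2.
#' @return List: z, p, p1, p2.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    data_error("invalid counts for two-proportion z test")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    warning("degenerate pooled proportion; z = 0, p = 1", call. = FALSE)
    return(list(z = 0, p = 1, p1 = p1, p2 = p2))
  }
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Unpaired two-tailed t test (Student or Welch)
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param variant `"welch"` (default) or `"student"`.
#' @return List: test, n1, n2, mean1, mean2, sem1, sem2, t, df, p.
#' @export
mean_test <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) data_error("each group needs n >= 2")
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      return(list(test = variant, n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
                  sem1 = 0, sem2 = 0, t = 0, df = n1 + n2 - 2, p = 1))
    }
    return(list(test = variant, n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
                sem1 = 0, sem2 = 0, t = sign(m1 - m2) * Inf,
                df = n1 + n2 - 2, p = 0))
  }
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(test = variant, n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
       sem1 = sqrt(v1 / n1), sem2 = sqrt(v2 / n2),
       t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-constant.
#' @return List: r, p, n.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) data_error("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) data_error("Pearson correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    data_error("Pearson correlation undefined for constant input")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- max(-1, min(1, r))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (is.finite(t)) 2 * pt(-abs(t), n - 2) else 0
  list(r = r, p = p, n = n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment `q_i = min_{j >= i} p_(j) * m / j`, clipped at 1,
#' mapped back to the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    data_error("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(ord)]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with the point-probability rule: the
#' p-value sums P(X = k) over all k whose point probability does not
#' exceed that of the observed table (within a relative tolerance of
#' 1e-7, as is conventional).
#'
#' @param a,b,c,d Cell counts (`a` = both positive, margins `a+b`, `a+c`).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0) return(NA_real_)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate for one group.
#'
#' @param time Follow-up times.
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @return Data frame: time, n_risk, n_event, n_censor, survival.
#' @export
km_curve <- function(time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Standard (Mantel-Haenszel) log-rank chi-square with
#' `#groups - 1` degrees of freedom.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = death observed).
#' @param group Group labels (>= 2 levels; >= 1 event in total).
#' @return List: `curves` (named list of [km_curve()] frames),
#'   `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) < 2L) data_error("log-rank test needs >= 2 groups")
  if (sum(event) < 1) data_error("log-rank test undefined without events")
  curves <- lapply(lv, function(g) km_curve(time[group == g],
                                            event[group == g]))
  names(curves) <- lv
  ut <- sort(unique(time[event == 1]))
  G <- length(lv)
  O <- E <- numeric(G)
  V <- matrix(0, G, G)
  for (t in ut) {
    at_risk <- vapply(lv, function(g) sum(time >= t & group == g), 0)
    deaths <- vapply(lv, function(g) sum(time == t & event == 1 & group == g), 0)
    N <- sum(at_risk); D <- sum(deaths)
    if (N < 1 || D < 1) next
    O <- O + deaths
    E <- E + D * at_risk / N
    if (N > 1) {
      for (i in seq_len(G)) for (j in seq_len(G)) {
        V[i, j] <- V[i, j] + D * (N - D) / (N - 1) *
          (at_risk[i] * ((i == j) * N - at_risk[j]) / N^2)
      }
    }
  }
  d <- (O - E)[-G]
  Vsub <- V[-G, -G, drop = FALSE]
  chisq <- tryCatch(as.numeric(t(d) %*% solve(Vsub) %*% d),
                    error = function(e) {
                      as.numeric(t(d) %*% MASS_ginv(Vsub) %*% d)
                    })
  df <- G - 1
  list(curves = curves, chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE))
}

# Moore-Penrose fallback for a singular log-rank variance matrix.
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Infiltration prevalence fold change between two groups
#'
#' Per cell type: percent of positively infiltrated samples in each group,
#' the fold change `percent_group1 / percent_group2` (log2 reported
#' alongside), and the two-proportion z test. Cell types with fewer than
#' `min_samples` positive calls overall are excluded.
#'
#' @param m An `infiltration_matrix` or logical samples x cell-types
#'   matrix.
#' @param groups Named two-level character vector over the matrix samples;
#'   the first level encountered is the numerator group unless `numerator`
#'   says otherwise.
#' @param min_samples Exclusion threshold on total positive calls.
#' @param numerator Optional group level to use as the fold-change
#'   numerator.
#' @return Data frame: cell_type, per-group n/percent, fold_change,
#'   log2_fold_change, z, p, stars. Fold change over a zero denominator
#'   is `Inf`.
#' @export
infiltration_fold_change <- function(m, groups, min_samples = 10L,
                                     numerator = NULL) {
  calls <- if (inherits(m, "infiltration_matrix")) m$calls else m
  samples <- intersect(rownames(calls), names(groups))
  if (!length(samples)) data_error("groups do not cover the matrix samples")
  calls <- calls[samples, , drop = FALSE]
  groups <- as.character(groups[samples])
  lv <- unique(groups)
  if (length(lv) != 2L) config_error("groups must have exactly two levels")
  if (!is.null(numerator)) {
    if (!numerator %in% lv) config_error("numerator is not a group level")
    lv <- c(numerator, setdiff(lv, numerator))
  }
  if (!all(table(groups) > 0)) data_error("both groups must be nonempty")
  keep <- colSums(calls) >= min_samples
  out <- lapply(colnames(calls)[keep], function(ct) {
    x1 <- sum(calls[groups == lv[1], ct]); n1 <- sum(groups == lv[1])
    x2 <- sum(calls[groups == lv[2], ct]); n2 <- sum(groups == lv[2])
    zt <- suppressWarnings(two_proportion_z(x1, n1, x2, n2))
    pct1 <- 100 * x1 / n1; pct2 <- 100 * x2 / n2
    fold <- if (pct2 == 0) Inf else pct1 / pct2
    data.frame(cell_type = ct, group1 = lv[1], group2 = lv[2],
               n1 = n1, n2 = n2, percent1 = pct1, percent2 = pct2,
               fold_change = fold, log2_fold_change = log2(fold),
               z = zt$z, p = zt$p, stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_type = character(0))
  if (nrow(res)) res$stars <- p_stars(res$p)
  attr(res, "excluded") <- colnames(calls)[!keep]
  res
}
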