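test_that("enrichment_score handles extreme concentrations", {
  genes <- paste0("g", 1:10)
  w <- seq(2, -2, length.out = 10)
  # set occupying the top ranks, exponent 0: peak reaches exactly 1
  expect_equal(enrichment_score(genes, w, genes[1:3], exponent = 0), 1)
  # set at the very bottom: deepest deviation is -1 under exponent 0
  expect_equal(enrichment_score(genes, w, genes[8:10], exponent = 0),
               brute_es(genes, w, genes[8:10], exponent = 0))
  expect_equal(enrichment_score(genes, w, genes[8:10], exponent = 0), -1)
  # disjoint set is an error
  expect_error(enrichment_score(genes, w, c("zz1", "zz2")),
               class = "neoimmune_data_error")
})

test_that("enrichment_score agrees with the brute-force running sum", {
  set.seed(14)
  for (rep in 1:40) {
    N <- sample(5:60, 1)
    genes <- paste0("g", seq_len(N))
    w <- sort(rnorm(N), decreasing = TRUE)
    gs <- sample(genes, sample(1:(N - 1), 1))
    for (e in c(0, 1, 2)) {
      expect_equal(enrichment_score(genes, w, gs, exponent = e),
                   brute_es(genes, w, gs, exponent = e), tolerance = 1e-12)
    }
  }
})

test_that("permutation_p behaves at the null, the extreme, and is seeded", {
  genes <- paste0("g", 1:40)
  w <- seq(3, -3, length.out = 40)
  # maximally concentrated set: no permutation can beat it
  r <- permutation_p(genes, w, genes[1:5], n_permutations = 999, seed = 2)
  expect_equal(r$p, 1 / 1000)
  # determinism
  r2 <- permutation_p(genes, w, genes[1:5], n_permutations = 999, seed = 2)
  expect_identical(r, r2)
  # a scattered set on a symmetric list: p should be large
  set.seed(8)
  scattered <- genes[seq(4, 40, by = 8)]
  r3 <- permutation_p(genes, w, scattered, n_permutations = 499, seed = 5)
  expect_gt(r3$p, 0.2)
})

test_that("call_infiltration recovers a planted signal and respects q=0", {
  set.seed(31)
  n_genes <- 300; n_samples <- 12
  genes <- paste0("g", seq_len(n_genes))
  vals <- matrix(exp(rnorm(n_genes * n_samples, 2, 0.5)), n_genes,
                 dimnames = list(genes, paste0("s", seq_len(n_samples))))
  panel <- metagene_panel(list(planted = genes[1:25], decoy = genes[101:125]),
                          tcell_subtypes = "planted")
  # plant a 3-sigma shift on the planted set's genes in samples 1..6
  vals[1:25, 1:6] <- vals[1:25, 1:6] * exp(1.5)
  expr <- expression_matrix(vals)
  inf <- call_infiltration(expr, panel,
                           calling_config(n_permutations = 499, seed = 4))
  expect_true(all(inf$calls[1:6, "planted"]))
  expect_lt(mean(inf$calls[, "decoy"]), 0.5)
  expect_true(all(inf$results$q >= inf$results$p - 1e-12))

  # degenerate q threshold: no calls at all
  inf0 <- call_infiltration(expr, panel,
                            calling_config(n_permutations = 499, seed = 4,
                                           q_threshold = 0))
  expect_equal(sum(inf0$calls), 0)

  # cell type absent from the matrix is excluded with a warning
  panel2 <- metagene_panel(list(planted = genes[1:25], ghost = c("zz1", "zz2")))
  expect_warning(inf2 <- call_infiltration(expr, panel2,
                                           calling_config(n_permutations = 499,
                                                          seed = 4)),
                 "excluded")
  expect_false("ghost" %in% colnames(inf2$calls))
})

test_that("prevalence percentages and aggregates respect containment", {
  calls <- matrix(FALSE, 4, 3,
                  dimnames = list(paste0("s", 1:4), c("tc1", "tc2", "nk")))
  calls[1, "tc1"] <- TRUE
  panel <- metagene_panel(list(tc1 = "a", tc2 = "b", nk = "c"),
                          tcell_subtypes = c("tc1", "tc2"))
  prev <- infiltration_prevalence(calls, panel)
  expect_equal(prev$per_cell_type$percent_positive[1], 25)
  expect_equal(prev$any_tcell, 25)
  expect_equal(prev$any_immune, 25)
  calls[2, "nk"] <- TRUE; calls[3, "tc2"] <- TRUE
  prev <- infiltration_prevalence(calls, panel)
  max_t <- max(prev$per_cell_type$percent_positive[1:2])
  expect_gte(prev$any_tcell, max_t)
  expect_gte(prev$any_immune, prev$any_tcell)
  # all-false matrix
  prev0 <- infiltration_prevalence(calls & FALSE, panel)
  expect_equal(prev0$per_cell_type$percent_positive, c(0, 0, 0))
})

test_that("cooccurrence labels agreement, independence and disagreement", {
  mk <- function(a_pos, b_pos, n) {
    m <- matrix(FALSE, n, 2, dimnames = list(paste0("s", 1:n), c("A", "B")))
    m[a_pos, 1] <- TRUE; m[b_pos, 2] <- TRUE
    m
  }
  # perfect agreement on 20 samples: p = 2 / C(20,10)
  co <- cooccurrence(mk(1:10, 1:10, 20))
  expect_equal(co$label, "co-occur")
  expect_equal(co$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(co$p, 1.082509e-05, tolerance = 1e-6)
  # independence
  co <- cooccurrence(mk(1:10, c(1:5, 11:15), 20))
  expect_equal(co$p, 1)
  expect_equal(co$label, "ns")
  # perfect disagreement
  co <- cooccurrence(mk(1:10, 11:20, 20))
  expect_equal(co$label, "mutually exclusive")
  expect_equal(co$p, 2 / choose(20, 10), tolerance = 1e-9)
  # degenerate margin -> ns with warning
  m <- mk(1:10, 1:20, 20)
  expect_warning(co <- cooccurrence(m), "degenerate")
  expect_equal(co$label, "ns")
})
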