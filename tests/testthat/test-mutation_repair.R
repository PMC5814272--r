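test_that("mutation_burden applies the counting rule and roster zeros", {
  muts <- mut_df("S1", "G1", c("missense", "missense", "missense", "silent"))
  b <- mutation_burden(muts, samples = c("S1", "S2"))
  expect_equal(b$burden, c(3L, 0L))
  b2 <- mutation_burden(muts, counted_classes = c(neoimmune:::NONSYN_CLASSES,
                                                  "silent"),
                        samples = "S1")
  expect_equal(b2$burden, 4L)
  # additive over disjoint subsets and order-invariant
  m2 <- rbind(mut_df("S2", "G2", "nonsense"), muts)
  b3 <- mutation_burden(m2[sample(nrow(m2)), ], samples = c("S1", "S2"))
  expect_equal(b3$burden, c(3L, 1L))
})

test_that("classify_repair flags pathways by gene-list membership", {
  muts <- rbind(
    mut_df("S1", "BRCA2", "missense", "p.A10V"),
    mut_df("S2", "MSH2", "nonsense"),
    mut_df("S2", "PMS2", "nonsense"),
    mut_df("S3", "TP53", "missense", "p.R175H"))
  st <- classify_repair(muts)
  expect_equal(st$hr_mut, c(TRUE, FALSE, FALSE))
  expect_equal(st$n_hr_genes, c(1L, 0L, 0L))
  expect_equal(st$mmr_mut, c(FALSE, TRUE, FALSE))
  expect_equal(st$n_mmr_genes, c(0L, 2L, 0L))
  expect_false(any(st$pole_mut))
  # silent mutations in a pathway gene do not count
  st2 <- classify_repair(mut_df("S1", "BRCA1", "silent"))
  expect_false(st2$hr_mut)
})

test_that("substitution_spectrum collapses strands and flags undefined", {
  muts <- rbind(
    mut_df("S1", "G1", "missense", "p.A2V", ref = "C", alt = "A"),
    mut_df("S1", "G2", "missense", "p.A3V", ref = "G", alt = "T"),  # -> C>A
    mut_df("S1", "G3", "missense", "p.A4V", ref = "C", alt = "T"),
    mut_df("S1", "G4", "missense", "p.A5V", ref = "A", alt = "G"),  # -> T>C
    mut_df("S2", "G5", "missense", "p.A6V", ref = "C", alt = "T"),
    mut_df("S3", "G6", "frameshift", ref = "A", alt = "AT"))
  sp <- substitution_spectrum(muts)
  expect_equal(sp[sp$sample_id == "S1", "C>A"], 0.5)
  expect_equal(sp[sp$sample_id == "S1", "T>C"], 0.25)
  expect_equal(sp[sp$sample_id == "S2", "C>T"], 1.0)
  expect_false(sp$defined[sp$sample_id == "S3"])
  expect_equal(attr(sp, "n_non_snv"), 1L)
  ok <- sp$defined
  sums <- rowSums(sp[ok, neoimmune:::SUBST_CLASSES])
  expect_equal(sums, rep(1, sum(ok)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("median_split assigns ties to low; quartile_split uses P75", {
  b <- data.frame(sample_id = paste0("S", 1:4), burden = c(1, 2, 3, 4))
  s <- median_split(b)
  expect_equal(unname(s), c("low", "low", "high", "high"))
  b$burden <- c(1, 2, 2, 9)
  s <- median_split(b)
  expect_equal(sum(s == "high"), 1L)
  expect_equal(names(s)[s == "high"], "S4")
  expect_true(sum(s == "high") <= length(s) / 2)
  b$burden <- rep(3, 4)
  expect_warning(s <- median_split(b), "identical")
  expect_true(all(s == "low"))

  v <- setNames(1:8, paste0("S", 1:8))
  expect_equal(unname(quantile(v, 0.75)), 6.25)
  qs <- quartile_split(v)
  expect_equal(names(qs)[qs == "top_quartile"], c("S7", "S8"))
  expect_warning(qs <- quartile_split(setNames(rep(2, 5), paste0("S", 1:5))),
                 "identical")
  expect_false(any(qs == "top_quartile"))
  qs <- quartile_split(setNames(c(0, 0, 0, 10), paste0("S", 1:4)))
  expect_equal(sum(qs == "top_quartile"), 1L)
})

test_that("gene_panel_mutation_rates counts fractions per group", {
  muts <- rbind(
    mut_df(paste0("M", 1:4), "IFNB1", "missense", "p.A2V"),
    mut_df("M1", "IFNB1", "missense", "p.A3V"))   # same sample twice
  groups <- setNames(rep(c("mut", "wt"), each = 10),
                     c(paste0("M", 1:10), paste0("W", 1:10)))
  tab <- suppressWarnings(
    gene_panel_mutation_rates(muts, c("IFNB1", "IRF8"), groups))
  expect_equal(tab$frac1[tab$gene == "IFNB1"], 0.4)
  expect_equal(tab$frac2[tab$gene == "IFNB1"], 0.0)
  expect_equal(tab$frac1[tab$gene == "IRF8"], 0)
  expect_equal(tab$z[tab$gene == "IRF8"], 0)
  expect_equal(gene_panel_mutation_rates(muts, character(0), groups),
               data.frame(gene = character(0), stringsAsFactors = FALSE))
})

test_that("oncogene_positive applies glob and class rules", {
  rules <- data.frame(gene = "KRAS", match = "protein", value = "p.G12*",
                      stringsAsFactors = FALSE)
  muts <- rbind(mut_df("S1", "KRAS", "missense", "p.G12C"),
                mut_df("S2", "KRAS", "missense", "p.A59T"),
                mut_df("S3", "TP53", "missense", "p.G12C"))
  pos <- oncogene_positive(muts, rules)
  expect_equal(unname(pos), c(TRUE, FALSE, FALSE))
  expect_error(oncogene_positive(muts, rules[0, ]),
               class = "neoimmune_config_error")
  bad <- data.frame(gene = "KRAS", match = "regex", value = "x")
  expect_error(oncogene_positive(muts, bad),
               class = "neoimmune_config_error")
  # class-based rule
  rules2 <- data.frame(gene = "TP53", match = "class", value = "missense")
  expect_equal(unname(oncogene_positive(muts, rules2)),
               c(FALSE, FALSE, TRUE))
})
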