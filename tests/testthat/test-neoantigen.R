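test_that("apply_variant substitutes and validates the reference", {
  expect_equal(apply_variant("ACDEF", 3, "D", "N"), "ACNEF")
  expect_error(apply_variant("ACDEF", 3, "E", "N"),
               class = "neoimmune_variant_mismatch")
  # applying then reverting restores the input
  m <- apply_variant("ACDEF", 3, "D", "N")
  expect_equal(apply_variant(m, 3, "N", "D"), "ACDEF")
})

test_that("enumerate_peptides yields every window covering the site", {
  wt <- paste(rep("A", 20), collapse = "")
  mut <- wt; substr(mut, 10, 10) <- "V"
  pairs <- enumerate_peptides(wt, mut, 10, k = 9)
  expect_equal(nrow(pairs), 9L)
  expect_equal(pairs$window_start, 2:10)
  expect_true(all(nchar(pairs$mutant_peptide) == 9))
  # the two peptides differ exactly at offset
  for (i in seq_len(nrow(pairs))) {
    d <- which(strsplit(pairs$mutant_peptide[i], "")[[1]] !=
                 strsplit(pairs$wildtype_peptide[i], "")[[1]])
    expect_equal(d, pairs$offset[i])
    expect_equal(substr(pairs$mutant_peptide[i], d, d), "V")
  }
  # terminal residue
  mut1 <- wt; substr(mut1, 1, 1) <- "V"
  expect_equal(nrow(enumerate_peptides(wt, mut1, 1, k = 9)), 1L)
  # protein exactly k long
  wt9 <- "ACDEFGHIK"; mut9 <- "ACDEVGHIK"
  p9 <- enumerate_peptides(wt9, mut9, 5, k = 9)
  expect_equal(nrow(p9), 1L)
  expect_equal(p9$mutant_peptide, mut9)
  # shorter than k
  expect_warning(p0 <- enumerate_peptides("ACDEF", "ACNEF", 3, k = 9),
                 "shorter")
  expect_equal(nrow(p0), 0L)
})

test_that("toy predictor is deterministic and honors the shipped examples", {
  ic1 <- toy_binding_predictor("ACDEFGHIK", "HLA-A*02:01")
  ic2 <- toy_binding_predictor("ACDEFGHIK", "HLA-A*02:01")
  expect_identical(ic1, ic2)
  expect_gt(ic1, 0)
  expect_error(toy_binding_predictor("ACDEFGHI", "HLA-A*02:01"),
               class = "neoimmune_data_error")
  expect_error(toy_binding_predictor("ACDEFGHIK", "HLA-A*99:99"),
               class = "neoimmune_data_error")

  # recompute the mapping by hand from the shipped weight table
  pwm_path <- system.file("extdata", "toy_pwm.tsv", package = "neoimmune")
  pwm <- read.delim(pwm_path, check.names = FALSE)
  ex_path <- system.file("extdata", "toy_pwm_examples.tsv",
                         package = "neoimmune")
  ex <- read.delim(ex_path, check.names = FALSE)
  for (i in seq_len(nrow(ex))) {
    al <- ex$allele[i]
    w <- pwm[pwm$allele == al, ]
    w <- w[order(w$position), ]
    hand_ic50 <- function(pep) {
      aa <- strsplit(pep, "")[[1]]
      s <- sum(vapply(1:9, function(p) w[p, aa[p]], 0))
      50000^(1 - s / 9)
    }
    expect_equal(toy_binding_predictor(ex$strong_peptide[i], al),
                 hand_ic50(ex$strong_peptide[i]), tolerance = 1e-9)
    expect_lt(toy_binding_predictor(ex$strong_peptide[i], al), 500)
    expect_gt(toy_binding_predictor(ex$weak_peptide[i], al), 500)
  }
})

test_that("predict_pairs crosses pairs with distinct alleles", {
  wt <- paste(rep("A", 20), collapse = "")
  mut <- wt; substr(mut, 10, 10) <- "V"
  pairs <- enumerate_peptides(wt, mut, 10, k = 9)
  al6 <- toy_alleles()
  expect_equal(nrow(predict_pairs(pairs, al6)), 54L)
  # homozygosity collapses
  expect_equal(nrow(predict_pairs(pairs, c(al6[1], al6[1:5]))), 45L)
  # predictor failure on one allele skips it with a warning
  expect_warning(
    res <- predict_pairs(pairs, c(al6[1:5], "HLA-A*99:99")),
    "allele skipped")
  expect_equal(nrow(res), 45L)
})

test_that("call_neoantigens applies the three strict filters", {
  vars <- data.frame(variant_id = 1:2, sample_id = c("S1", "S1"),
                     gene = c("G1", "G2"), transcript_id = "",
                     position = 5L, ref_aa = "A", alt_aa = "V",
                     stringsAsFactors = FALSE)
  vals <- matrix(c(5.2, 7, 0, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("G1", "G2"), c("S1", "S2")))
  expr <- expression_matrix(vals)
  preds <- data.frame(variant_id = c(1L, 1L, 2L),
                      allele = "HLA-A*01:01",
                      mutant_ic50 = c(100, 100, 100),
                      wildtype_ic50 = c(300, 800, 800))
  out <- call_neoantigens(preds, vars, expr)
  # variant 1: one failing (WT binder) and one passing row -> neoantigen
  expect_true(out$calls$is_neoantigen[1])
  expect_equal(out$calls$n_passing_pairs[1], 1L)
  # variant 2 fails the expression filter (expression 0 is not positive)
  expect_false(out$calls$is_neoantigen[2])
  expect_equal(out$load$load[out$load$sample_id == "S1"], 1L)
  # monotonicity: relaxing thresholds never lowers the load
  out2 <- call_neoantigens(preds, vars, expr,
                           neoantigen_thresholds(mutant_ic50_max = 1000,
                                                 wt_ic50_min = 200))
  expect_gte(out2$load$load[1], out$load$load[1])
})

test_that("neoantigen load equals the planted ground truth and is order-invariant", {
  co <- generate_cohort(cohort_config(n_samples = 30,
                                      panel = synthetic_panel(4, 10),
                                      seed = 19))
  res <- suppressWarnings(neoantigen_pipeline(
    co$mutations, co$proteins, co$hla, co$expression,
    samples = co$samples))
  expect_equal(res$load$load, co$truth$load$load)
  # permuting mutation rows leaves the load unchanged
  set.seed(1)
  shuf <- co$mutations[sample(nrow(co$mutations)), ]
  res2 <- suppressWarnings(neoantigen_pipeline(
    shuf, co$proteins, co$hla, co$expression, samples = co$samples))
  expect_equal(res2$load$load, res$load$load)
})

test_that("parse_predictor_output reads dialects and joins to pairs", {
  p <- tempfile()
  writeLines(c("peptide\tallele\tic50",
               "ACDEFGHIK\tHLA-A*01:01\t42.5",
               "ACDEFGHIL\tHLA-A*01:01\t900",
               "ZZZZZZZZZ\tHLA-A*01:01\t10"), p)
  out <- parse_predictor_output(p)
  expect_equal(nrow(out), 3L)
  expect_equal(out$ic50[1], 42.5)
  pairs <- data.frame(mutant_peptide = c("ACDEFGHIK", "ACDEFGHIL"),
                      wildtype_peptide = c("ACDEFGHIA", "ACDEFGHIA"),
                      window_start = 1:2, offset = 9:8)
  expect_warning(joined <- parse_predictor_output(p, pairs = pairs),
                 "did not match")
  expect_equal(attr(joined, "unmatched"), 3L)
  expect_error(parse_predictor_output(p, dialect = "nope"),
               class = "neoimmune_config_error")
  writeLines(c("peptide\tallele\tic50", "ACDEFGHIK\tHLA-A*01:01\tNA"), p)
  expect_error(parse_predictor_output(p), class = "neoimmune_record_error")
})
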