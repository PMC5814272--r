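small_cfg <- function(...) {
  cohort_config(n_samples = 40, panel = synthetic_panel(4, 10), ...)
}

test_that("identical config and seed give byte-identical outputs", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  generate_cohort(small_cfg(seed = 23), out_dir = d1)
  generate_cohort(small_cfg(seed = 23), out_dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "coh3")
  generate_cohort(small_cfg(seed = 24), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "mutations.maf")),
                         readLines(file.path(d3, "mutations.maf"))))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(frac_hr_mut = 1.2),
               class = "neoimmune_config_error")
  expect_error(cohort_config(rho = 0.5), class = "neoimmune_config_error")
  expect_error(cohort_config(lambda0 = 0), class = "neoimmune_config_error")
  expect_error(small_cfg(coplant = c("NK cell", "nope")),
               class = "neoimmune_config_error")
})

test_that("rho = 1 leaves no burden difference between groups", {
  co <- generate_cohort(cohort_config(n_samples = 200,
                                      panel = synthetic_panel(3, 8),
                                      rho = 1, frac_hr_mut = 0.5,
                                      frac_mmr_mut = 0, frac_pole_mut = 0,
                                      seed = 101))
  b <- mutation_burden(co$mutations, samples = co$samples)
  mut <- co$truth$repair$hr_mut
  m1 <- mean(b$burden[mut]); m2 <- mean(b$burden[!mut])
  se <- sqrt(var(b$burden[mut]) / sum(mut) +
               var(b$burden[!mut]) / sum(!mut))
  expect_lt(abs(m1 - m2), 2 * se + 0.5)
})

test_that("parameter recovery: burden ratio estimates rho within 20%", {
  co <- generate_cohort(cohort_config(n_samples = 200,
                                      panel = synthetic_panel(3, 8),
                                      lambda0 = 5, rho = 3, seed = 7))
  b <- mutation_burden(co$mutations, samples = co$samples)
  tr <- co$truth$repair
  mut <- tr$hr_mut | tr$mmr_mut | tr$pole_mut
  ratio <- mean(b$burden[mut]) / mean(b$burden[!mut])
  expect_lt(abs(ratio - 3) / 3, 0.2)
})

test_that("classify_repair reproduces planted repair flags exactly", {
  co <- generate_cohort(small_cfg(seed = 3))
  expect_true(check_ground_truth(co))
  st <- classify_repair(co$mutations, samples = co$samples)
  expect_equal(st$hr_mut, co$truth$repair$hr_mut)
  expect_equal(st$mmr_mut, co$truth$repair$mmr_mut)
  expect_equal(st$pole_mut, co$truth$repair$pole_mut)
})

test_that("emitted files round-trip through the package readers", {
  d <- file.path(tempdir(), "coh_rt")
  co <- generate_cohort(small_cfg(seed = 5), out_dir = d)
  muts <- read_maf(file.path(d, "mutations.maf"))
  expect_equal(nrow(muts), nrow(co$mutations))
  expr <- read_expression(file.path(d, "expression.tsv"))
  expect_equal(dim(expr$values), dim(co$expression$values))
  prot <- read_fasta(file.path(d, "proteins.fasta"))
  expect_identical(prot, co$proteins)
  hla <- read_hla(file.path(d, "hla.tsv"))
  expect_equal(hla, co$hla)
  cl <- read_clinical(file.path(d, "clinical.tsv"))
  expect_equal(cl$os_months, co$clinical$os_months)
})

test_that("coplanted cell types share their infiltrated samples", {
  cfg <- cohort_config(n_samples = 50, panel = synthetic_panel(4, 10),
                       coplant = c("Activated CD4 T cell",
                                   "Activated CD8 T cell"),
                       seed = 13)
  co <- generate_cohort(cfg)
  inf <- co$truth$infiltration
  expect_identical(inf[, "Activated CD4 T cell"],
                   inf[, "Activated CD8 T cell"])
})
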