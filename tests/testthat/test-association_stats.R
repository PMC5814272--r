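test_that("two-proportion z matches the pooled formula and degenerates safely", {
  r <- two_proportion_z(50, 100, 50, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  # hand evaluation: (0.3 - 0.1) / sqrt(0.2 * 0.8 * (1/100 + 1/100))
  r <- two_proportion_z(30, 100, 10, 100)
  expect_equal(r$z, 0.2 / sqrt(0.2 * 0.8 * 0.02), tolerance = 1e-12)
  expect_equal(r$z, 3.5355339, tolerance = 1e-6)

  expect_warning(r <- two_proportion_z(0, 10, 0, 10), "degenerate")
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
})

test_that("z^2 equals the uncorrected chi-square and flips sign with labels", {
  set.seed(42)
  for (i in 1:50) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    if ((x1 + x2) %in% c(0, n1 + n2)) next
    z <- two_proportion_z(x1, n1, x2, n2)
    tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
    cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(z$z^2, unname(cs$statistic), tolerance = 1e-9)
    zr <- two_proportion_z(x2, n2, x1, n1)
    expect_equal(zr$z, -z$z)
    expect_equal(zr$p, z$p)
  }
})

test_that("mean_test agrees with t.test for both variants", {
  a <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  b <- c(2.0, 6.5, 7.7, 8.1)
  for (v in c("welch", "student")) {
    m <- mean_test(a, b, variant = v)
    ref <- t.test(a, b, var.equal = (v == "student"))
    expect_equal(m$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(m$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(m$p, ref$p.value, tolerance = 1e-12)
    expect_equal(m$sem1, sd(a) / sqrt(length(a)))
  }
  # identical groups
  m <- mean_test(a, a)
  expect_equal(m$t, 0)
  expect_equal(m$p, 1)
  # strong shift is significant under either variant
  expect_lt(mean_test(c(1, 2, 3), c(11, 12, 13), "welch")$p, 0.01)
  expect_lt(mean_test(c(1, 2, 3), c(11, 12, 13), "student")$p, 0.01)
  # Welch reduces to Student at equal n and variance
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(mean_test(x, y, "welch")$p, mean_test(x, y, "student")$p,
               tolerance = 1e-12)
  # zero variance, equal means
  expect_equal(mean_test(c(2, 2), c(2, 2))$p, 1)
})

test_that("pearson_cor matches cor.test and handles the null", {
  x <- c(1, 2, 4, 7, 11, 16)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  set.seed(9)
  y <- rnorm(30)
  x2 <- rnorm(30)
  r <- pearson_cor(x2, y)
  ref <- cor.test(x2, y)
  expect_equal(r$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 5), 1:5), class = "neoimmune_data_error")
  # null calibration: p roughly uniform over seeded replicates
  set.seed(10)
  ps <- replicate(200, pearson_cor(rnorm(100), rnorm(100))$p)
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  expect_lt(mean(ps < 0.05), 0.11)
})

test_that("bh_fdr reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-order
    expect_true(all(q <= 1))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "neoimmune_data_error")
})

test_that("fisher_exact_2x2 equals fisher.test on random tables", {
  set.seed(7)
  for (i in 1:60) {
    n1 <- sample(1:15, 1); n2 <- sample(1:15, 1)
    a <- sample(0:n1, 1); cc <- sample(0:n2, 1)
    p <- fisher_exact_2x2(a, n1 - a, cc, n2 - cc)
    ref <- fisher.test(rbind(c(a, n1 - a), c(cc, n2 - cc)))$p.value
    expect_equal(p, ref, tolerance = 1e-9)
  }
})

test_that("Kaplan-Meier without censoring equals the empirical survivor", {
  set.seed(5)
  t <- round(rexp(40, 0.05), 1)
  km <- km_curve(t, rep(1, 40))
  emp <- vapply(km$time, function(u) mean(t > u), 0)
  expect_equal(km$survival, emp, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 1e-12))
  # censoring never decreases the estimate
  ev <- rbinom(40, 1, 0.6)
  km2 <- km_curve(t, ev)
  s1 <- stats::stepfun(km$time, c(1, km$survival))
  s2 <- stats::stepfun(km2$time, c(1, km2$survival))
  grid <- sort(unique(t))
  expect_true(all(s2(grid) >= s1(grid) - 1e-12))
})

test_that("log-rank matches survival::survdiff and handles edge cases", {
  skip_if_not_installed("survival")
  set.seed(21)
  time <- c(rexp(50, 0.1), rexp(50, 0.02))
  event <- rbinom(100, 1, 0.8)
  group <- rep(c("a", "b"), each = 50)
  lr <- km_logrank(time, event, group)
  ref <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$chisq, unname(ref$chisq), tolerance = 1e-9)
  expect_lt(lr$p, 0.01)

  # two identical groups -> statistic 0
  t2 <- c(1, 2, 3, 4); e2 <- c(1, 1, 1, 1)
  lr0 <- km_logrank(c(t2, t2), c(e2, e2), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  expect_error(km_logrank(t2, c(0, 0, 0, 0), c("a", "a", "b", "b")),
               class = "neoimmune_data_error")
})

test_that("infiltration_fold_change computes folds and applies exclusions", {
  calls <- matrix(FALSE, 20, 3,
                  dimnames = list(sprintf("S%02d", 1:20), c("A", "B", "C")))
  g <- setNames(rep(c("high", "low"), each = 10), rownames(calls))
  calls[1:8, "A"] <- TRUE; calls[11:14, "A"] <- TRUE    # 80% vs 40%
  calls[1:5, "B"] <- TRUE; calls[11:15, "B"] <- TRUE    # equal
  calls[1:9, "C"] <- TRUE                               # only 9 positives
  fc <- infiltration_fold_change(calls, g, min_samples = 10L)
  expect_equal(fc$cell_type, c("A", "B"))
  expect_equal(fc$fold_change[fc$cell_type == "A"], 2.0)
  expect_equal(fc$fold_change[fc$cell_type == "B"], 1.0)
  expect_equal(fc$z[fc$cell_type == "B"], 0)
  expect_true("C" %in% attr(fc, "excluded"))
  # swapping the numerator group inverts folds, p unchanged
  fc2 <- infiltration_fold_change(calls, g, min_samples = 10L,
                                  numerator = "low")
  expect_equal(fc2$fold_change[fc2$cell_type == "A"], 0.5)
  expect_equal(fc2$p, fc$p)
})
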