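test_that("descriptives report n-1 SD and SEM = SD/sqrt(n)", {
  tab <- cohort_table(matrix(c(1, 2, 3,
                               5, 5, 5,
                               2, 4, 4), nrow = 3,
                             dimnames = list(NULL, c("A", "B", "C"))))
  d <- descriptives(tab)
  expect_equal(d$mean[d$timepoint == "A"], 2)
  expect_equal(d$sd[d$timepoint == "A"], 1)
  expect_equal(d$sem[d$timepoint == "A"], 1 / sqrt(3))
  expect_equal(d$sd[d$timepoint == "B"], 0)

  # hand-checked n-1 formula on (2, 4, 4, 6): SD = sqrt(8/3)
  d4 <- descriptives(cohort_table(matrix(c(2, 4, 4, 6), ncol = 1)))
  expect_equal(d4$sd, sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(d4$sd, 1.633, tolerance = 1e-3)

  # single observation: mean reported, spread missing
  d1 <- descriptives(cohort_table(matrix(c(7, NA), ncol = 2), subjects = "s1"))
  expect_equal(d1$mean[1], 7)
  expect_true(is.na(d1$sd[1]))
})

test_that("repeated-measures ANOVA matches the sum-of-squares oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:10, 1); k <- sample(3:6, 1)
    m <- matrix(rnorm(n * k, mean = rep(rnorm(k, sd = 2), each = n)), n, k)
    res <- rm_anova(cohort_table(m))
    or <- oracle_rm_anova(m)
    expect_equal(res$F, or$F, tolerance = 1e-10)
    expect_equal(res$p, or$p, tolerance = 1e-10)
    expect_equal(res$df_effect, or$df_effect)
    expect_equal(res$df_error, or$df_error)
  }
})

test_that("repeated-measures ANOVA handles degenerate tables as specified", {
  # identical values across timepoints, subjects differ: no time effect
  flat <- cohort_table(matrix(rep(c(1, 5, 9), 3), nrow = 3))
  res <- rm_anova(flat)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_false(res$degenerate)

  # constant within-subject difference: zero residual variance
  exact <- cohort_table(matrix(c(1, 2, 3, 2, 3, 4), nrow = 3))
  res2 <- rm_anova(exact)
  expect_true(res2$degenerate)
  expect_identical(res2$F, Inf)
  expect_equal(res2$p, 0)
})

test_that("repeated-measures F is invariant to subject and global shifts", {
  set.seed(3)
  m <- matrix(rnorm(24), 6, 4)
  base <- rm_anova(cohort_table(m))$F
  shifted <- m + rnorm(6, sd = 10)      # per-subject constants (recycled by row)
  expect_equal(rm_anova(cohort_table(shifted))$F, base, tolerance = 1e-8)
  expect_equal(rm_anova(cohort_table(m + 100))$F, base, tolerance = 1e-8)
})

test_that("missing subjects are excluded listwise and reported", {
  m <- matrix(rnorm(20), 5, 4)
  m[2, 3] <- NA
  res <- rm_anova(cohort_table(m))
  expect_equal(res$n, 4)
  expect_equal(res$n_excluded, 1)
  expect_equal(res$F, oracle_rm_anova(m[-2, ])$F, tolerance = 1e-10)
})

test_that("null type-I error of the repeated-measures test is nominal", {
  set.seed(104)
  n_rej <- 0L
  reps <- 2000
  for (i in seq_len(reps)) {
    m <- matrix(rnorm(16 * 4), 16, 4)
    if (rm_anova(cohort_table(m))$p <= 0.05) n_rej <- n_rej + 1L
  }
  rate <- n_rej / reps
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Holm-Sidak step-down follows the direct formula", {
  # single comparison reduces to the unadjusted test
  r1 <- holm_sidak(0.03, alpha = 0.05)
  expect_equal(r1$step_alpha, 0.05)
  expect_true(r1$significant)

  # worked two-comparison case
  r2 <- holm_sidak(c(0.01, 0.04), alpha = 0.05)
  expect_equal(r2$step_alpha, c(1 - 0.95^(1 / 2), 0.05), tolerance = 1e-12)
  expect_equal(r2$step_alpha[1], 0.02532, tolerance = 1e-4)
  expect_true(all(r2$significant))

  # all ones: nothing significant, adjusted p capped at 1
  r3 <- holm_sidak(rep(1, 5))
  expect_false(any(r3$significant))
  expect_equal(r3$adjusted_p, rep(1, 5))

  expect_equal(nrow(holm_sidak(numeric(0))), 0L)

  # step-down enumeration oracle on random inputs, original order preserved
  set.seed(8)
  for (i in 1:25) {
    m <- sample(1:8, 1)
    ps <- runif(m)^2
    res <- holm_sidak(ps, alpha = 0.05)
    expect_equal(res$raw_p, ps)
    o <- order(ps)
    reject <- logical(m)
    for (j in seq_len(m)) {
      thr <- 1 - 0.95^(1 / (m - j + 1))
      if (ps[o[j]] <= thr) reject[o[j]] <- TRUE else break
    }
    expect_identical(res$significant, reject)
    adj_sorted <- cummax(pmin(1, 1 - (1 - ps[o])^(m - seq_len(m) + 1)))
    expect_equal(res$adjusted_p[o], adj_sorted, tolerance = 1e-12)
  }
})

test_that("Holm-Sidak rejections sit between Bonferroni and unadjusted", {
  set.seed(12)
  for (i in 1:50) {
    m <- sample(2:10, 1)
    ps <- runif(m)^3
    hs <- holm_sidak(ps, alpha = 0.05)$significant
    bonf <- ps <= 0.05 / m
    unadj <- ps <= 0.05
    expect_true(all(hs[bonf]))      # superset of Bonferroni
    expect_true(all(unadj[hs]))     # subset of unadjusted
  }
})

test_that("reference-family pairwise comparisons label and adjust correctly", {
  set.seed(5)
  m <- matrix(rnorm(32), 8, 4,
              dimnames = list(NULL, c("BL", "VF10", "VF14", "VF16")))
  m[, "VF16"] <- m[, "VF16"] + 3
  res <- pairwise_vs_reference(cohort_table(m), "BL")
  expect_setequal(res$comparison,
                  c("VF10 vs BL", "VF14 vs BL", "VF16 vs BL"))
  expect_true(res$significant[res$comparison == "VF16 vs BL"])
  expect_error(pairwise_vs_reference(cohort_table(m), "XX"), "reference")
})

test_that("Pearson correlation matches the definitional formula", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)

  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  res <- pearson(x, y)
  expect_equal(res$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(res$n, 5)
  # two-sided t on n-2 df
  tstat <- res$r * sqrt((5 - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * pt(abs(tstat), 3, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), ">= 3")
})

test_that("Pearson r is invariant to positive affine transforms", {
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(x, 0.2 * y - 4)$r, r0, tolerance = 1e-12)
})

test_that("simple regression matches the normal-equations oracle", {
  x <- c(0, 1, 2, 3); y <- 3 * x - 1
  res <- simple_linregress(x, y)
  expect_equal(res$slope, 3)
  expect_equal(res$intercept, -1)
  expect_equal(res$r, 1)

  flat <- simple_linregress(1:5, rep(2, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)

  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5)
    res <- simple_linregress(x, y)
    or <- oracle_ols(x, y)
    expect_equal(res$slope, or$slope, tolerance = 1e-10)
    expect_equal(res$intercept, or$intercept, tolerance = 1e-10)
  }
  expect_error(simple_linregress(rep(1, 5), rnorm(5)), "constant")
})

test_that("anchor-minute variability correlations run per target row", {
  set.seed(2)
  offs <- exp(rnorm(16, 0, 0.25))
  m <- outer(offs, c(10, 7, 9, 12)) * matrix(rnorm(64, 1, 0.05), 16, 4)
  colnames(m) <- c("1", "8", "14", "17")
  res <- baseline_variability_correlations(cohort_table(m), "1",
                                           c("8", "14", "17"))
  expect_equal(res$target, c("8", "14", "17"))
  expect_true(all(res$r > 0.8))
  expect_true(all(is.na(res$error)))

  # constant anchor: per-row error records, no abort
  m2 <- m; m2[, "1"] <- 5
  res2 <- baseline_variability_correlations(cohort_table(m2), "1",
                                            c("8", "14"))
  expect_true(all(grepl("constant", res2$error)))
  expect_true(all(is.na(res2$r)))

  expect_error(
    baseline_variability_correlations(cohort_table(m), "1", "99"), "99")
})

test_that("tidy long tables pivot into cohort tables", {
  df <- data.frame(subject = rep(c("a", "b"), each = 3),
                   timepoint = rep(c("BL", "VF10", "VF16"), 2),
                   value = c(1, 2, 3, 4, 5, 6))
  tab <- as_cohort_table(df)
  expect_equal(dim(tab$values), c(2L, 3L))
  expect_equal(tab$values["b", "VF10"], 5)
  expect_equal(tab$timepoints, c("BL", "VF10", "VF16"))
})
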