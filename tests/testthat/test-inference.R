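test_that("mixed ANOVA reduces exactly to its t-test oracles on random cohorts", {
  for (seed in 1:100) {
    n1 <- sample(5:15, 1)
    n2 <- sample(5:15, 1)
    co <- random_cohort(n1, n2, seed = seed)
    res <- mixed_anova_2x2(co)
    i1 <- co$group == "PTSD"

    means <- (co$strength_pre + co$strength_post) / 2
    tg <- t.test(means[i1], means[!i1], var.equal = TRUE)
    expect_equal(res$group$F, unname(tg$statistic)^2, tolerance = 1e-10)

    d <- co$strength_post - co$strength_pre
    ti <- t.test(d[i1], d[!i1], var.equal = TRUE)
    expect_equal(res$interaction$F, unname(ti$statistic)^2, tolerance = 1e-10)

    # df2 = N - 2 for all three effects; p consistent with F
    for (eff in list(res$group, res$stress, res$interaction)) {
      expect_equal(eff$df2, n1 + n2 - 2L)
      expect_equal(eff$p, pf(eff$F, 1, eff$df2, lower.tail = FALSE))
      expect_gte(eff$p, 0)
      expect_lte(eff$p, 1)
    }
  }
})

test_that("mixed ANOVA matches aov() on balanced cohorts for all three effects", {
  for (seed in c(3, 14)) {
    co <- random_cohort(12, 12, seed = seed)
    res <- mixed_anova_2x2(co)
    long <- data.frame(y = c(co$strength_pre, co$strength_post),
                       subj = factor(rep(co$subject_id, 2)),
                       grp = factor(rep(co$group, 2)),
                       scan = factor(rep(c("pre", "post"), each = nrow(co))))
    av <- summary(aov(y ~ grp * scan + Error(subj / scan), data = long))
    expect_equal(res$group$F, av[[1]][[1]]["grp", "F value"], tolerance = 1e-8)
    expect_equal(res$stress$F, av[[2]][[1]]["scan", "F value"], tolerance = 1e-8)
    expect_equal(res$interaction$F,
                 av[[2]][[1]]["grp:scan", "F value"], tolerance = 1e-8)
  }
})

test_that("degenerate cohorts error; identical groups give F ~ 0", {
  co <- random_cohort(6, 6, seed = 2)
  co$strength_post <- co$strength_pre
  expect_error(mixed_anova_2x2(co), "zero variance")

  expect_error(mixed_anova_2x2(
    data.frame(subject_id = c("a", "b", "c"),
               group = c("PTSD", "MDD", "MDD"),
               strength_pre = rnorm(3), strength_post = rnorm(3))),
    ">= 2 subjects")
})

test_that("simple_effect reproduces the hand paired-t computation", {
  pre <- c(1, 1, 1, 1)
  post <- pre + c(1, 2, 3, 6)
  co <- cohort_table(paste0("s", 1:8), rep(c("PTSD", "MDD"), each = 4),
                     c(pre, 0, 1, 2, 4), c(post, 1, 2, 3, 5))
  eff <- simple_effect(co, "PTSD")
  expect_equal(eff$signed_difference, 3.0)
  expect_equal(eff$mean_difference, 3.0)
  expect_identical(eff$direction, "increase")
  expect_equal(eff$sem, 1.0801234, tolerance = 1e-6)
  expect_equal(eff$t, 2.7775, tolerance = 1e-4)
  expect_equal(eff$df, 3L)
  expect_equal(eff$p, 2 * pt(-abs(eff$t), 3), tolerance = 1e-10)

  # constant shift -> sem 0 -> degenerate-case error
  co$strength_post <- co$strength_pre + 0.5
  expect_error(simple_effect(co, "PTSD"), "degenerate")
})

test_that("simple_effect recovers a simulated post-stress decrement", {
  cfg <- sim_config(dmn_interaction_effect = 0.5, seed = 77)
  out <- simulate_strengths(cfg)
  eff <- simple_effect(out$cohort, "PTSD")
  # injected PTSD shift = -0.5 * diff_sd = -0.013
  expect_lt(abs(eff$signed_difference - (-0.5 * cfg$diff_sd)), 3 * eff$sem)
  expect_identical(eff$direction, "decrease")
})

test_that("group_contrast reproduces the hand two-sample pooled t", {
  co <- cohort_table(paste0("s", 1:6), rep(c("PTSD", "MDD"), each = 3),
                     c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  eff <- group_contrast(co, "pre")
  expect_equal(eff$signed_difference, -3.0)
  expect_equal(eff$mean_difference, 3.0)
  expect_equal(eff$sem, 0.8164966, tolerance = 1e-6)
  expect_equal(abs(eff$t), 3.674235, tolerance = 1e-6)
  expect_equal(eff$df, 4L)

  co2 <- cohort_table(paste0("s", 1:6), rep(c("PTSD", "MDD"), each = 3),
                      c(1, 2, 3, 1, 2, 3), c(5, 6, 9, 5, 6, 9))
  eq <- group_contrast(co2, "mean")
  expect_equal(eq$signed_difference, 0)
  expect_equal(eq$p, 1)
})

test_that("percent_difference preserves sign and checks the reference", {
  expect_equal(percent_difference(0, 5), 0)
  expect_equal(percent_difference(0.013, 0.13), 10)
  expect_equal(percent_difference(-0.5, 2), -25)
  expect_error(percent_difference(1, 0), "zero")
})

test_that("interaction-contrast identity holds algebraically on random cohorts", {
  for (seed in 1:100) {
    co <- random_cohort(sample(4:12, 1), sample(4:12, 1), seed = seed + 500)
    dP <- simple_effect(co, "PTSD")$signed_difference
    dM <- simple_effect(co, "MDD")$signed_difference
    gpost <- group_contrast(co, "post")$signed_difference
    gpre <- group_contrast(co, "pre")$signed_difference
    expect_equal(dP - dM, gpost - gpre, tolerance = 1e-12)
  }
})

test_that("covariate-adjusted interaction has df2 = N - 2 - k and ignores null covariates", {
  co <- random_cohort(28, 24, seed = 9)
  covs <- as.data.frame(matrix(rnorm(52 * 11), 52, 11))
  names(covs) <- paste0("c", 1:11)
  co2 <- cbind(co, covs)
  res <- ancova_interaction(co2, paste0("c", 1:11))
  expect_equal(res$df2, 39L)
  expect_equal(res$p, pf(res$F, 1, 39, lower.tail = FALSE))

  # all-zero covariate is dropped: F identical to covariate-free model
  co2$zero <- 0
  res0 <- ancova_interaction(co2, "zero")
  expect_identical(res0$dropped, "zero")
  expect_equal(res0$F, mixed_anova_2x2(co)$interaction$F, tolerance = 1e-10)

  co2$c12 <- 3 * co2$c1
  expect_error(ancova_interaction(co2, c("c1", "c12")), "collinear")
})

test_that("adding a pure-noise covariate keeps the interaction test calibrated", {
  reps <- 1500L
  rej <- 0L
  for (i in seq_len(reps)) {
    out <- simulate_strengths(sim_config(n_ptsd = 14, n_mdd = 12,
                                         seed = 40000L + i))
    co <- out$cohort
    co$noise <- withr::with_seed(80000L + i, rnorm(nrow(co)))
    rej <- rej + (ancova_interaction(co, "noise")$p < 0.05)
  }
  expect_gt(rej / reps, 0.04 - 2.6 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rej / reps, 0.06 + 2.6 * sqrt(0.05 * 0.95 / reps))
})

test_that("correlation p-values follow the t transform, with degeneracy flagged", {
  expect_equal(correlation_p(0, 28)$p, 1)
  r5 <- correlation_p(0.5, 20)
  expect_equal(r5$t, 0.5 * sqrt(18) / sqrt(0.75), tolerance = 1e-12)
  expect_equal(r5$p, 2 * pt(-abs(r5$t), 18), tolerance = 1e-14)
  deg <- correlation_p(1, 10)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  expect_error(correlation_p(0.5, 3), "n >= 4")
  # correlation_test agrees with cor.test
  set.seed(4)
  x <- rnorm(25); y <- 0.3 * x + rnorm(25)
  expect_equal(correlation_test(x, y)$p, cor.test(x, y)$p.value,
               tolerance = 1e-12)
})

test_that("2x2 chi-square is the uncorrected Pearson statistic", {
  res <- chi_square_2x2(19, 9, 16, 8)
  # closed form N(ad-bc)^2 / row/col products
  chk <- function(a, b, c, d) {
    N <- a + b + c + d
    N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  expect_equal(res$chi2, chk(19, 9, 16, 8), tolerance = 1e-12)
  expect_equal(res$df, 1L)
  ident <- chi_square_2x2(5, 5, 5, 5)
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p, 1)
  expect_error(chi_square_2x2(0, 0, 3, 4), "zero margin")
})

test_that("Mann-Whitney: exact enumeration for small untied samples, approx otherwise", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$method, "exact")
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  # p uniform under the null (KS over repeated large samples)
  ps <- vapply(1:2000, function(i) {
    withr::with_seed(120000L + i, mann_whitney(rnorm(30), rnorm(30))$p)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("FDR adjustment is BH step-up, monotone and capped", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"))
  expect_equal(fdr_adjust(p, "bonferroni"), pmin(1, p * 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("duration analysis is the 2x2 model on half strengths", {
  co <- random_cohort(8, 8, seed = 60)
  half <- data.frame(subject_id = co$subject_id, group = co$group,
                     strength_h1 = co$strength_pre,
                     strength_h2 = co$strength_post)
  res <- duration_analysis(half)
  ref <- mixed_anova_2x2(co)
  expect_equal(res$interaction$F, ref$interaction$F, tolerance = 1e-12)
  expect_equal(res$time$F, ref$stress$F, tolerance = 1e-12)

  # identical halves -> time and interaction F = 0
  half$strength_h2 <- half$strength_h1
  expect_error(duration_analysis(half), "zero variance")
})

test_that("within-run drift is detected with the analytically predicted power", {
  # PTSD-specific half-2 increase delta, expressed as standardized d on
  # half differences; two-sample t power prediction
  d <- 0.9
  n1 <- 14L; n2 <- 12L
  predicted <- power_of("between_on_differences", d, n1, n2)$power
  reps <- 2000L
  rej <- 0L
  for (i in seq_len(reps)) {
    out <- simulate_strengths(sim_config(n_ptsd = n1, n_mdd = n2,
                                         dmn_interaction_effect = d,
                                         seed = 200000L + i))
    half <- data.frame(subject_id = out$cohort$subject_id,
                       group = out$cohort$group,
                       strength_h1 = out$cohort$strength_pre,
                       strength_h2 = out$cohort$strength_post)
    rej <- rej + (duration_analysis(half)$interaction$p < 0.05)
  }
  expect_lt(abs(rej / reps - predicted), 0.04)
})
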