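# Paired and two-sample t statistics from summaries and raw data,
# Levene's test, change-score comparisons and the full study report.

test_that("paired t from summary reproduces published table rows", {
  r1 <- paired_t_from_summary(paired_summary(1.41, 1.75, 9))
  expect_equal(round(r1$t, 2), 2.42)
  expect_identical(r1$df, 8)
  expect_equal(round(r1$se, 2), 0.58)

  r2 <- paired_t_from_summary(paired_summary(-1.00, 2.74, 9))
  expect_equal(round(r2$t, 2), -1.09)

  r3 <- paired_t_from_summary(paired_summary(0.23167, 0.62, 12))
  expect_equal(round(r3$t, 2), 1.29)  # published as 1.30 from unrounded data
  expect_identical(r3$df, 11)

  r4 <- paired_t_from_summary(paired_summary(-0.25, 4.31, 12))
  expect_equal(round(r4$t, 2), -0.20)

  expect_identical(paired_t_from_summary(paired_summary(0, 2, 9))$t, 0)
  expect_error(paired_summary(1, 1, 1), "n")
})

test_that("raw and summary paired routes agree, and match stats::t.test", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    pre <- rnorm(n, 8, 2)
    post <- pre - rnorm(n, 0.5, 1)
    raw <- paired_t_from_raw(pre, post)
    d <- pre - post
    summ <- paired_t_from_summary(paired_summary(mean(d), sd(d), n))
    expect_identical(raw$t, summ$t)
    ref <- t.test(pre, post, paired = TRUE)
    expect_equal(raw$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(raw$p_two_tailed, ref$p.value, tolerance = 1e-12)
    expect_equal(c(raw$ci_low, raw$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-12)
  }
  # identical vectors: a well-defined null with t = 0 ...
  expect_identical(paired_t_from_raw(c(8, 9, 10), c(8, 9, 10))$t, 0)
  # ... but a constant nonzero shift has no variance to test against
  expect_error(paired_t_from_raw(c(8, 9, 10), c(7, 8, 9)), "zero variance")
  expect_error(paired_t_from_raw(1:3, 1:4), "equal length")
})

test_that("pooled t from summary reproduces the pre-exposure table", {
  eh <- pooled_t_from_summary(group_summary(25.83, 5.27, 12),
                              group_summary(23.33, 3.08, 9))
  expect_equal(round(eh$t, 2), 1.27)
  expect_equal(round(eh$se, 2), 1.98)
  expect_equal(round(eh$mean_difference, 2), 2.50)
  expect_identical(eh$df, 19)

  hb <- pooled_t_from_summary(group_summary(7.13, 1.49, 12),
                              group_summary(8.13, 2.83, 9))
  expect_equal(round(hb$t, 2), -1.05)
  expect_equal(round(hb$mean_difference, 2), -1.00)

  same <- pooled_t_from_summary(group_summary(5, 2, 10),
                                group_summary(5, 2, 10))
  expect_identical(same$t, 0)
})

test_that("Welch t handles unequal variances and degenerate groups", {
  w <- welch_t_from_summary(group_summary(8.13, 2.83, 9),
                            group_summary(7.13, 1.49, 12))
  expect_equal(round(abs(w$t), 2), 0.96)  # published |t| = 0.967 from raw data
  expect_lt(w$df, 19)  # Satterthwaite df shrink below pooled

  # equal n and SD: Welch equals pooled exactly (df included)
  a <- group_summary(5.2, 1.3, 11); b <- group_summary(4.1, 1.3, 11)
  p_ <- pooled_t_from_summary(a, b); w_ <- welch_t_from_summary(a, b)
  expect_equal(w_$t, p_$t, tolerance = 1e-12)
  expect_equal(w_$df, p_$df, tolerance = 1e-12)

  # one group with zero variance still yields a finite statistic
  z <- welch_t_from_summary(group_summary(5, 0, 10), group_summary(4, 1, 10))
  expect_true(is.finite(z$t))

  # against stats::t.test on raw data via the induced summaries
  set.seed(21)
  x <- rnorm(9, 8, 2.8); y <- rnorm(12, 7, 1.5)
  sx <- group_summary(mean(x), sd(x), 9)
  sy <- group_summary(mean(y), sd(y), 12)
  refw <- t.test(x, y)
  refp <- t.test(x, y, var.equal = TRUE)
  ww <- welch_t_from_summary(sx, sy)
  pp <- pooled_t_from_summary(sx, sy)
  expect_equal(ww$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(ww$df, unname(refw$parameter), tolerance = 1e-10)
  expect_equal(pp$t, unname(refp$statistic), tolerance = 1e-12)
  expect_equal(pp$p_two_tailed, refp$p.value, tolerance = 1e-12)
})

test_that("two-tailed p is twice the one-tailed p in the observed direction", {
  set.seed(5)
  for (i in 1:25) {
    r <- pooled_t_from_summary(
      group_summary(rnorm(1), runif(1, 0.5, 3), sample(3:30, 1)),
      group_summary(rnorm(1), runif(1, 0.5, 3), sample(3:30, 1)))
    expect_equal(r$p_two_tailed, 2 * r$p_one_tailed, tolerance = 1e-14)
    expect_lte(r$ci_low, r$ci_high)
  }
})

test_that("Levene's test equals ANOVA on absolute deviations", {
  expect_equal(levene_test(list(c(1, 2, 3), c(1, 2, 3)))$F, 0,
               tolerance = 1e-12)

  g <- list(c(1, 2, 3), c(10, 20, 30))
  got <- levene_test(g)
  z <- c(abs(g[[1]] - mean(g[[1]])), abs(g[[2]] - mean(g[[2]])))
  fac <- factor(rep(1:2, each = 3))
  want <- anova(lm(z ~ fac))[["F value"]][1]
  expect_equal(got$F, want, tolerance = 1e-10)

  skip_if_not_installed("car")
  set.seed(9)
  x <- list(rnorm(12, 0, 1), rnorm(9, 0, 3), rnorm(15, 1, 2))
  mine <- levene_test(x)
  df_long <- data.frame(v = unlist(x),
                        g = factor(rep(1:3, times = lengths(x))))
  ref <- car::leveneTest(v ~ g, data = df_long, center = mean)
  expect_equal(mine$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  ref_bf <- car::leveneTest(v ~ g, data = df_long, center = median)
  expect_equal(levene_test(x, center = "median")$F,
               ref_bf[["F value"]][1], tolerance = 1e-10)

  expect_error(levene_test(list(c(1, 2, 3))), "at least 2")
  expect_error(levene_test(list(1, c(1, 2))), "at least 2 observations")
})

test_that("change-score comparison reproduces the published differences", {
  hb <- mean_change_difference(paired_summary(1.41, 1.75, 9),
                               paired_summary(0.23167, 0.62, 12))
  expect_equal(round(hb$mean_difference, 2), 1.18)
  expect_equal(round(hb$pooled$se, 2), 0.54)
  expect_identical(hb$pooled$df, 19)
  expect_equal(round(hb$welch$t, 2), 1.93)  # published 1.94 from raw data

  eh <- mean_change_difference(paired_summary(-1.00, 2.74, 9),
                               paired_summary(-0.25, 4.31, 12))
  expect_equal(round(eh$pooled$t, 3), -0.456)
  expect_equal(round(eh$pooled$se, 2), 1.64)
  expect_equal(round(eh$mean_difference, 2), -0.75)

  s <- paired_summary(0.8, 1.1, 10)
  sym <- mean_change_difference(s, s)
  expect_identical(sym$mean_difference, 0)
  expect_identical(sym$pooled$t, 0)
})

test_that("a moment-matched study reproduces every summary-derivable table entry", {
  study <- published_moment_study(seed = 42)
  rep_ <- analyze_study(study)
  expect_identical(unname(rep_$n), c(9L, 12L))

  # descriptives carry the published moments
  d <- rep_$descriptives
  pre_h_iv <- d[d$group == "intervention" & d$measure == "pre_hba1c", ]
  expect_equal(pre_h_iv$mean, 8.13, tolerance = 1e-9)
  expect_equal(pre_h_iv$sd, 2.83, tolerance = 1e-9)

  # within-group paired tests
  expect_equal(round(rep_$within_tests$intervention$hba1c$t, 2), 2.42)
  expect_equal(round(rep_$within_tests$intervention$eh$t, 2), -1.09)
  expect_equal(round(rep_$within_tests$control$eh$t, 2), -0.20)
  expect_equal(round(rep_$within_tests$control$hba1c$t, 2), 1.29)

  # pre-exposure equivalence (control - intervention)
  expect_equal(round(rep_$pre_tests$eh$pooled$t, 2), 1.27)
  expect_equal(round(rep_$pre_tests$hba1c$pooled$t, 2), -1.05)

  # change differences (intervention - control)
  expect_equal(round(rep_$change_tests$hba1c$mean_difference, 2), 1.18)
  expect_equal(round(rep_$change_tests$eh$pooled$t, 3), -0.456)

  # confounder check
  expect_equal(round(rep_$nse_test$pooled$t, 2), 0.49)
  expect_equal(round(rep_$nse_test$pooled$mean_difference, 2), 0.58)
  expect_equal(round(rep_$nse_test$pooled$ci_low, 2), -1.89)
  expect_equal(round(rep_$nse_test$pooled$ci_high, 2), 3.05)
})

test_that("study validation rejects malformed datasets", {
  study <- published_moment_study()
  expect_error(analyze_study(study[, setdiff(names(study), "post_hba1c")]),
               "post_hba1c")
  dup <- study
  dup$subject_id[2] <- dup$subject_id[1]
  expect_error(analyze_study(dup), "duplicated subject_id")
  tiny <- study[study$group == "control" | study$subject_id == "S01", ]
  expect_error(analyze_study(tiny), "fewer than 2")
  bad <- study
  bad$group[1] <- "placebo"
  expect_error(analyze_study(bad), "placebo")
})

test_that("null within-group t statistics follow the t distribution", {
  set.seed(123)
  n <- 9
  reps <- 600
  tt <- replicate(reps, {
    pre <- rnorm(n, 8, 1)
    post <- 8 + 0.7 * (pre - 8) + sqrt(1 - 0.49) * rnorm(n)
    paired_t_from_raw(pre, post)$t
  })
  ks <- suppressWarnings(ks.test(tt, pt, df = n - 1))
  expect_gt(ks$p.value, 0.01)
})
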