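# Two-group pre/post study inference: paired and independent t statistics
# computable from printed summary moments (mean, SD, n) as well as from raw
# per-subject data, Levene's variance-homogeneity test, and report tables.

#' Group summary (mean, SD, n)
#'
#' @param mean Group mean, outcome units.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (integer >= 2).
#' @return A list of class `"group_summary"` with an `se` field
#'   (`sd/sqrt(n)`).
#' @export
group_summary <- function(mean, sd, n) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stop("'mean' must be a single finite number", call. = FALSE)
  }
  check_nonneg(sd, "sd")
  n <- check_count(n, "n", min = 2L)
  structure(list(mean = mean, sd = sd, n = n, se = sd / sqrt(n)),
            class = "group_summary")
}

#' Paired-difference summary
#'
#' Summary moments of within-subject change scores, oriented pre minus
#' post (a positive mean difference is a drop over the study).
#'
#' @param mean_diff Mean of pre - post differences.
#' @param sd_diff SD of the differences (>= 0).
#' @param n Number of pairs (integer >= 2).
#' @return A list of class `"paired_summary"`.
#' @export
paired_summary <- function(mean_diff, sd_diff, n) {
  if (!is.numeric(mean_diff) || length(mean_diff) != 1L ||
      !is.finite(mean_diff)) {
    stop("'mean_diff' must be a single finite number", call. = FALSE)
  }
  check_nonneg(sd_diff, "sd_diff")
  n <- check_count(n, "n", min = 2L)
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff, n = n,
                 se = sd_diff / sqrt(n)),
            class = "paired_summary")
}

# Assemble the common result record. p_one_tailed is for the observed
# direction; the t distribution is symmetric so p_two = 2 * p_one.
.t_result <- function(t, df, se, mean_difference, conf = 0.95,
                      method = "t") {
  p_one <- stats::pt(abs(t), df, lower.tail = FALSE)
  crit <- stats::qt(1 - (1 - conf) / 2, df)
  structure(list(t = t, df = df, se = se,
                 mean_difference = mean_difference,
                 p_one_tailed = p_one, p_two_tailed = 2 * p_one,
                 conf = conf,
                 ci_low = mean_difference - crit * se,
                 ci_high = mean_difference + crit * se,
                 method = method),
            class = "t_result")
}

#' @export
print.t_result <- function(x, digits = 3, ...) {
  cat(sprintf("<t_result> %s: t(%s) = %s, p(two) = %s, p(one) = %s\n",
              x$method, format(round(x$df, 2)),
              format(round(x$t, digits)),
              format.pval(x$p_two_tailed, digits = digits),
              format.pval(x$p_one_tailed, digits = digits)))
  cat(sprintf("  mean difference %s, SE %s, %d%% CI [%s, %s]\n",
              format(round(x$mean_difference, digits)),
              format(round(x$se, digits)), round(100 * x$conf),
              format(round(x$ci_low, digits)),
              format(round(x$ci_high, digits))))
  invisible(x)
}

#' Paired t test from summary moments
#'
#' `se = sd_diff / sqrt(n)`, `t = mean_diff / se`, `df = n - 1`. Works
#' directly from a published table row (mean, SD, n of the differences)
#' with no raw data.
#'
#' @param s A [paired_summary()].
#' @param conf Confidence level for the CI (default 0.95).
#' @return A `"t_result"`.
#' @export
#' @examples
#' paired_t_from_summary(paired_summary(1.41, 1.75, 9))  # t = 2.42, df 8
paired_t_from_summary <- function(s, conf = 0.95) {
  stopifnot(inherits(s, "paired_summary"))
  if (s$sd_diff == 0) {
    # no change at all is a well-defined null; constant nonzero change
    # has an undefined statistic
    if (s$mean_diff == 0) {
      return(.t_result(t = 0, df = s$n - 1, se = 0, mean_difference = 0,
                       conf = conf, method = "paired t (summary)"))
    }
    stop("zero variance of the differences: paired t is undefined",
         call. = FALSE)
  }
  .t_result(t = s$mean_diff / s$se, df = s$n - 1, se = s$se,
            mean_difference = s$mean_diff, conf = conf,
            method = "paired t (summary)")
}

#' Paired t test from raw pre/post vectors
#'
#' Reduces the pairs to their difference summary (pre minus post) and
#' delegates to [paired_t_from_summary()]; the two routes agree exactly
#' on the induced summary.
#'
#' @param pre,post Numeric vectors of equal length >= 2.
#' @param conf Confidence level.
#' @return A `"t_result"`.
#' @export
paired_t_from_raw <- function(pre, post, conf = 0.95) {
  if (length(pre) != length(post)) {
    stop("'pre' and 'post' must have equal length", call. = FALSE)
  }
  if (length(pre) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (any(!is.finite(pre)) || any(!is.finite(post))) {
    stop("'pre'/'post' must be finite", call. = FALSE)
  }
  d <- pre - post
  paired_t_from_summary(paired_summary(mean(d), stats::sd(d), length(d)),
                        conf = conf)
}

# Shared two-sample machinery on summary moments; difference is a - b.
.two_sample_summary <- function(a, b, var_equal, conf = 0.95) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  diff <- a$mean - b$mean
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "pooled two-sample t (summary)"
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 /
      (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "Welch two-sample t (summary)"
  }
  if (se == 0) {
    stop("zero standard error: both groups have zero variance",
         call. = FALSE)
  }
  .t_result(t = diff / se, df = df, se = se, mean_difference = diff,
            conf = conf, method = method)
}

#' Pooled-variance two-sample t test from summary moments
#'
#' Classical Student t assuming equal variances; `df = n_a + n_b - 2`,
#' mean difference is `a - b`.
#'
#' @param a,b [group_summary()] records.
#' @param conf Confidence level.
#' @return A `"t_result"`.
#' @export
#' @examples
#' pooled_t_from_summary(group_summary(25.83, 5.27, 12),
#'                       group_summary(23.33, 3.08, 9))  # t = 1.27
pooled_t_from_summary <- function(a, b, conf = 0.95) {
  .two_sample_summary(a, b, var_equal = TRUE, conf = conf)
}

#' Welch unequal-variance two-sample t test from summary moments
#'
#' Welch t with Satterthwaite degrees of freedom (fractional in general);
#' mean difference is `a - b`. A group with zero variance contributes a
#' zero term to the standard error and drops out of the df weighting.
#'
#' @inheritParams pooled_t_from_summary
#' @return A `"t_result"`.
#' @export
welch_t_from_summary <- function(a, b, conf = 0.95) {
  .two_sample_summary(a, b, var_equal = FALSE, conf = conf)
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group center: the classic mean-centered form by default, the
#' median-centered Brown-Forsythe variant via `center = "median"`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @param center `"mean"` or `"median"`.
#' @return List of class `"levene_result"`: `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of at least 2 numeric vectors",
         call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  cfun <- if (center == "mean") mean else stats::median
  z <- lapply(groups, function(x) abs(x - cfun(x)))
  k <- length(z)
  n_i <- lengths(z)
  N <- sum(n_i)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  ssb <- sum(n_i * (zbar_i - zbar)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2),
                    numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  # degenerate dispersion patterns (e.g. identical groups, or n = 2 per
  # group where within-group deviations are always equal)
  if (ssb <= .Machine$double.eps * max(1, ssw, zbar^2)) {
    f <- 0; p <- 1
  } else if (ssw <= .Machine$double.eps * max(1, ssb)) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = f, df1 = df1, df2 = as.integer(df2), p = p),
            class = "levene_result")
}

#' @export
print.levene_result <- function(x, digits = 3, ...) {
  cat(sprintf("<levene_result> F(%d, %d) = %s, p = %s\n", x$df1, x$df2,
              format(round(x$F, digits)),
              format.pval(x$p, digits = digits)))
  invisible(x)
}

#' Between-group difference of change scores
#'
#' Treats the two groups' within-subject change summaries (pre minus
#' post) as independent samples and tests their difference, reporting
#' both the pooled and the Welch statistic side by side. The mean
#' difference is `a - b` (conventionally intervention minus control).
#'
#' @param a,b [paired_summary()] records of the two groups' changes.
#' @param conf Confidence level.
#' @return List of class `"change_difference"`: `mean_difference`,
#'   `pooled` and `welch` (`"t_result"`s).
#' @export
#' @examples
#' mean_change_difference(paired_summary(1.41, 1.75, 9),
#'                        paired_summary(0.23167, 0.62, 12))
mean_change_difference <- function(a, b, conf = 0.95) {
  stopifnot(inherits(a, "paired_summary"), inherits(b, "paired_summary"))
  ga <- group_summary(a$mean_diff, a$sd_diff, a$n)
  gb <- group_summary(b$mean_diff, b$sd_diff, b$n)
  structure(list(mean_difference = a$mean_diff - b$mean_diff,
                 pooled = pooled_t_from_summary(ga, gb, conf),
                 welch = welch_t_from_summary(ga, gb, conf)),
            class = "change_difference")
}

#' @export
print.change_difference <- function(x, ...) {
  cat(sprintf("<change_difference> mean difference %s\n",
              format(round(x$mean_difference, 3))))
  print(x$pooled); print(x$welch)
  invisible(x)
}

# --- full-study analysis ---------------------------------------------------

.validate_study <- function(data) {
  data <- as.data.frame(data)
  need <- c("subject_id", "group", "pre_hba1c", "post_hba1c",
            "pre_eh", "post_eh", "nse")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("study data is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(data$group), c("intervention", "control"))
  if (length(bad)) {
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(data$subject_id)) {
    stop(sprintf("duplicated subject_id: %s",
                 data$subject_id[duplicated(data$subject_id)][1]),
         call. = FALSE)
  }
  num_cols <- setdiff(need, c("subject_id", "group"))
  for (cc in num_cols) {
    if (any(!is.finite(data[[cc]]))) {
      stop(sprintf("column '%s' contains missing or non-numeric values",
                   cc), call. = FALSE)
    }
  }
  n_by_group <- table(factor(data$group,
                             levels = c("intervention", "control")))
  small <- names(n_by_group)[n_by_group < 2]
  if (length(small)) {
    stop(sprintf("group(s) with fewer than 2 subjects: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  data
}

.summ <- function(x) group_summary(mean(x), stats::sd(x), length(x))
.psumm <- function(pre, post) {
  d <- pre - post
  paired_summary(mean(d), stats::sd(d), length(d))
}

#' Analyze a two-group pre/post study
#'
#' Runs the full quasi-experimental analysis on per-subject records:
#' descriptive statistics per group and timepoint; pre-exposure
#' between-group equivalence tests (control minus intervention); paired
#' within-group pre/post tests; between-group tests on the change scores
#' (intervention minus control); and the between-group test of the
#' nutrition self-efficacy confounder (control minus intervention).
#' Pooled and Welch statistics are reported side by side with Levene's F,
#' and one- and two-tailed p values are both computed; the headline tail
#' follows the configuration.
#'
#' @param data Data frame with columns `subject_id`, `group`
#'   (`"intervention"`/`"control"`), `pre_hba1c`, `post_hba1c`, `pre_eh`,
#'   `post_eh`, `nse`.
#' @param conf Confidence level.
#' @param config An [engine_config()] (Levene variant, report precision).
#' @return A list of class `"study_report"`; see Details.
#' @details The report contains `descriptives` (data frame), `pre_tests`
#'   and `change_tests` (per outcome: pooled/Welch `"t_result"`s plus
#'   `"levene_result"`), `within_tests` (per group and outcome, paired
#'   `"t_result"`s), `nse_test`, and the group sizes.
#' @export
analyze_study <- function(data, conf = 0.95, config = engine_config()) {
  data <- .validate_study(data)
  iv <- data[data$group == "intervention", ]
  cv <- data[data$group == "control", ]
  desc <- do.call(rbind, lapply(list(
    c("intervention", "pre_hba1c"), c("intervention", "post_hba1c"),
    c("intervention", "pre_eh"), c("intervention", "post_eh"),
    c("control", "pre_hba1c"), c("control", "post_hba1c"),
    c("control", "pre_eh"), c("control", "post_eh"),
    c("intervention", "nse"), c("control", "nse")
  ), function(row_key) {
    grp <- if (row_key[1] == "intervention") iv else cv
    s <- .summ(grp[[row_key[2]]])
    data.frame(group = row_key[1], measure = row_key[2], mean = s$mean,
               sd = s$sd, se = s$se, n = s$n, stringsAsFactors = FALSE)
  }))
  pre_test <- function(col) {
    list(pooled = pooled_t_from_summary(.summ(cv[[col]]), .summ(iv[[col]]),
                                        conf),
         welch = welch_t_from_summary(.summ(cv[[col]]), .summ(iv[[col]]),
                                      conf),
         levene = levene_test(list(cv[[col]], iv[[col]]),
                              config$levene_center))
  }
  change_test <- function(pre_col, post_col) {
    da <- iv[[pre_col]] - iv[[post_col]]
    db <- cv[[pre_col]] - cv[[post_col]]
    res <- mean_change_difference(.psumm(iv[[pre_col]], iv[[post_col]]),
                                  .psumm(cv[[pre_col]], cv[[post_col]]),
                                  conf)
    res$levene <- levene_test(list(da, db), config$levene_center)
    res
  }
  structure(list(
    n = c(intervention = nrow(iv), control = nrow(cv)),
    descriptives = desc,
    pre_tests = list(eh = pre_test("pre_eh"), hba1c = pre_test("pre_hba1c")),
    within_tests = list(
      intervention = list(
        hba1c = paired_t_from_raw(iv$pre_hba1c, iv$post_hba1c, conf),
        eh = paired_t_from_raw(iv$pre_eh, iv$post_eh, conf)),
      control = list(
        hba1c = paired_t_from_raw(cv$pre_hba1c, cv$post_hba1c, conf),
        eh = paired_t_from_raw(cv$pre_eh, cv$post_eh, conf))),
    change_tests = list(hba1c = change_test("pre_hba1c", "post_hba1c"),
                        eh = change_test("pre_eh", "post_eh")),
    nse_test = list(pooled = pooled_t_from_summary(.summ(cv$nse),
                                                   .summ(iv$nse), conf),
                    welch = welch_t_from_summary(.summ(cv$nse),
                                                 .summ(iv$nse), conf),
                    levene = levene_test(list(cv$nse, iv$nse),
                                         config$levene_center)),
    config = config
  ), class = "study_report")
}

#' Reproduce the study tables from printed summary statistics
#'
#' Runs every summary-derivable test of the report from published group
#' and paired summaries alone (no raw data, hence no Levene F).
#'
#' @param summaries A list as returned by [read_summaries()]: `groups`
#'   (per measure, `control` and `intervention` [group_summary()]s) and
#'   `paired` (per outcome, per group [paired_summary()]s).
#' @param conf Confidence level.
#' @return A list of class `"summary_report"` with `between_tests` (one
#'   entry per non-NSE group measure), `within_tests`, `change_tests`
#'   and `nse_test`.
#' @export
analyze_summaries <- function(summaries, conf = 0.95) {
  g <- summaries$groups
  p <- summaries$paired
  between <- lapply(g[setdiff(names(g), "nse")], function(m) {
    list(pooled = pooled_t_from_summary(m$control, m$intervention, conf),
         welch = welch_t_from_summary(m$control, m$intervention, conf))
  })
  within <- lapply(p, function(outcome) {
    lapply(outcome, paired_t_from_summary, conf = conf)
  })
  change <- lapply(p, function(outcome) {
    mean_change_difference(outcome$intervention, outcome$control, conf)
  })
  nse <- if (!is.null(g$nse)) {
    list(pooled = pooled_t_from_summary(g$nse$control, g$nse$intervention,
                                        conf),
         welch = welch_t_from_summary(g$nse$control, g$nse$intervention,
                                      conf))
  }
  structure(list(between_tests = between, within_tests = within,
                 change_tests = change, nse_test = nse),
            class = "summary_report")
}

# Report-layer rounding only: internal values stay at full precision.
.fmt_t <- function(tr, dt = 2L, dm = 2L) {
  sprintf("t(%s) = %s, p(two) = %.3f, diff = %s, SE = %s",
          format(round(tr$df, 1)), format(round(tr$t, dt)),
          tr$p_two_tailed, format(round(tr$mean_difference, dm)),
          format(round(tr$se, dm)))
}

#' @export
print.study_report <- function(x, ...) {
  dt <- x$config$digits_t; dm <- x$config$digits_mean
  cat(sprintf("<study_report> intervention n=%d, control n=%d\n",
              x$n[["intervention"]], x$n[["control"]]))
  cat("Descriptives (mean (SD), SE):\n")
  d <- x$descriptives
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-12s %-11s %s (%s)  SE %s\n", d$group[i], d$measure[i],
                format(round(d$mean[i], dm)), format(round(d$sd[i], dm)),
                format(round(d$se[i], dm))))
  }
  cat("Pre-exposure tests (control - intervention):\n")
  for (nm in names(x$pre_tests)) {
    pt_ <- x$pre_tests[[nm]]
    cat(sprintf("  %-6s pooled %s | Levene F = %s, p = %.3f\n", nm,
                .fmt_t(pt_$pooled, dt, dm), format(round(pt_$levene$F, dt)),
                pt_$levene$p))
  }
  cat("Within-group paired tests (pre - post):\n")
  for (grp in names(x$within_tests)) {
    for (nm in names(x$within_tests[[grp]])) {
      cat(sprintf("  %-12s %-6s %s\n", grp, nm,
                  .fmt_t(x$within_tests[[grp]][[nm]], dt, dm)))
    }
  }
  cat("Change-score tests (intervention - control):\n")
  for (nm in names(x$change_tests)) {
    ct <- x$change_tests[[nm]]
    cat(sprintf("  %-6s pooled %s\n         welch  %s | Levene F = %s\n",
                nm, .fmt_t(ct$pooled, dt, dm), .fmt_t(ct$welch, dt, dm),
                format(round(ct$levene$F, dt))))
  }
  cat("Nutrition self-efficacy (control - intervention):\n")
  cat(sprintf("  pooled %s\n", .fmt_t(x$nse_test$pooled, dt, dm)))
  invisible(x)
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  cat("Between-group tests (control - intervention):\n")
  for (nm in names(x$between_tests)) {
    cat(sprintf("  %-10s pooled %s\n", nm,
                .fmt_t(x$between_tests[[nm]]$pooled)))
  }
  cat("Within-group paired tests (pre - post):\n")
  for (oc in names(x$within_tests)) {
    for (grp in names(x$within_tests[[oc]])) {
      cat(sprintf("  %-6s %-12s %s\n", oc, grp,
                  .fmt_t(x$within_tests[[oc]][[grp]])))
    }
  }
  cat("Change-score tests (intervention - control):\n")
  for (nm in names(x$change_tests)) {
    ct <- x$change_tests[[nm]]
    cat(sprintf("  %-6s pooled %s\n         welch  %s\n", nm,
                .fmt_t(ct$pooled), .fmt_t(ct$welch)))
  }
  if (!is.null(x$nse_test)) {
    cat(sprintf("NSE (control - intervention): pooled %s\n",
                .fmt_t(x$nse_test$pooled)))
  }
  invisible(x)
}
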