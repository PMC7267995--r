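# Seeded synthetic data: recipe corpora spanning the rule boundaries and
# simulated two-group pre/post studies, plus Monte-Carlo power estimation.

# Run code under a given seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Recipe generator configuration
#'
#' Sampling ranges emulate a general web recipe corpus on a per-meal
#' basis; a configurable fraction of recipes is placed exactly on a
#' scoring-rule boundary so branch edges are exercised.
#'
#' @param n_recipes Number of recipes (>= 1).
#' @param seed Integer seed (or `NULL`).
#' @param calories_range,carbs_range_g,fat_range_g,protein_range_g,
#'   sodium_range_mg,fiber_range_g Uniform sampling ranges.
#' @param satfat_frac_max Saturated fat is a uniform fraction of fat in
#'   `[0, satfat_frac_max]`.
#' @param cuisines Cuisine label pool.
#' @param boundary_fraction Fraction of recipes forced onto a rule
#'   boundary (in `[0, 1]`).
#' @param reference_rrc Budget (kcal/meal) at which percentage-rule
#'   boundaries are computed for boundary placement.
#' @return A list of class `"recipe_gen_config"`.
#' @export
recipe_gen_config <- function(n_recipes = 100L, seed = NULL,
                              calories_range = c(150, 1200),
                              carbs_range_g = c(0, 150),
                              fat_range_g = c(0, 60),
                              protein_range_g = c(0, 60),
                              sodium_range_mg = c(0, 2000),
                              fiber_range_g = c(0, 15),
                              satfat_frac_max = 0.5,
                              cuisines = c("mediterranean", "mexican",
                                           "indian", "italian", "american",
                                           "middle-eastern"),
                              boundary_fraction = 0.15,
                              reference_rrc = 600) {
  n_recipes <- check_count(n_recipes, "n_recipes")
  for (nm in c("calories_range", "carbs_range_g", "fat_range_g",
               "protein_range_g", "sodium_range_mg", "fiber_range_g")) {
    r <- get(nm)
    if (length(r) != 2L || any(r < 0) || r[1] > r[2]) {
      stop(sprintf("'%s' must be a non-negative increasing pair", nm),
           call. = FALSE)
    }
  }
  if (boundary_fraction < 0 || boundary_fraction > 1) {
    stop("'boundary_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (satfat_frac_max < 0 || satfat_frac_max > 1) {
    stop("'satfat_frac_max' must lie in [0, 1]", call. = FALSE)
  }
  check_positive(reference_rrc, "reference_rrc")
  structure(as.list(environment()), class = "recipe_gen_config")
}

#' Generate a synthetic recipe corpus
#'
#' Samples nutrients uniformly within the configured ranges
#' (reproducibly under the seed) and snaps the configured fraction of
#' recipes onto a randomly chosen rule boundary: the sodium cutoff, a
#' fiber range edge, a macronutrient percentage edge at the reference
#' budget, or the budget itself.
#'
#' @param config A [recipe_gen_config()].
#' @return Data frame in the recipe schema (one row per recipe).
#' @export
generate_recipes <- function(config = recipe_gen_config()) {
  stopifnot(inherits(config, "recipe_gen_config"))
  n <- config$n_recipes
  .with_seed(config$seed, {
    runif2 <- function(r) stats::runif(n, r[1], r[2])
    fat <- runif2(config$fat_range_g)
    df <- data.frame(
      recipe_id = sprintf("recipe_%04d", seq_len(n)),
      name = sprintf("Synthetic recipe %d", seq_len(n)),
      cuisine = sample(config$cuisines, n, replace = TRUE),
      calories = runif2(config$calories_range),
      carbs_g = runif2(config$carbs_range_g),
      fat_g = fat,
      satfat_g = fat * stats::runif(n, 0, config$satfat_frac_max),
      protein_g = runif2(config$protein_range_g),
      sodium_mg = runif2(config$sodium_range_mg),
      fiber_g = runif2(config$fiber_range_g),
      stringsAsFactors = FALSE
    )
    n_b <- round(config$boundary_fraction * n)
    if (n_b > 0) {
      rrc <- config$reference_rrc
      cfg <- engine_config()
      which_b <- sample(n, n_b)
      kind <- sample(c("sodium", "fiber_lo", "fiber_hi", "carb_lo",
                       "carb_hi", "fat_lo", "fat_hi", "protein_lo",
                       "protein_hi", "calories"), n_b, replace = TRUE)
      for (j in seq_len(n_b)) {
        i <- which_b[j]
        switch(kind[j],
          sodium = { df$sodium_mg[i] <- cfg$sodium_cutoff_mg },
          fiber_lo = { df$fiber_g[i] <- cfg$fiber_range_g[1] },
          fiber_hi = { df$fiber_g[i] <- cfg$fiber_range_g[2] },
          carb_lo = { df$carbs_g[i] <- cfg$carb_range[1] * rrc / 4 },
          carb_hi = { df$carbs_g[i] <- cfg$carb_range[2] * rrc / 4 },
          fat_lo = {
            df$fat_g[i] <- cfg$fat_range[1] * rrc / 9
            df$satfat_g[i] <- min(df$satfat_g[i], df$fat_g[i])
          },
          fat_hi = {
            df$fat_g[i] <- cfg$fat_range[2] * rrc / 9
            df$satfat_g[i] <- min(df$satfat_g[i], df$fat_g[i])
          },
          protein_lo = { df$protein_g[i] <- cfg$protein_range[1] * rrc / 4 },
          protein_hi = { df$protein_g[i] <- cfg$protein_range[2] * rrc / 4 },
          calories = { df$calories[i] <- rrc }
        )
      }
      attr(df, "boundary_rows") <- sort(which_b)
    }
    df
  })
}

#' Study simulator configuration
#'
#' Defaults mirror the reference two-group pre/post quasi-experiment:
#' 9 intervention and 12 control completers; glycated-hemoglobin (HbA1c)
#' and eating-habits (EH) baselines and change effects set to the
#' observed group moments; outcomes bivariate normal with within-subject
#' correlation 0.7. Changes are oriented pre minus post, so a positive
#' HbA1c effect is an extra drop in the intervention group.
#'
#' @param n_per_group Named pair `c(intervention = , control = )`.
#' @param hba1c_baseline_mean,hba1c_baseline_sd Baseline HbA1c (%) for
#'   both groups.
#' @param hba1c_control_change Mean pre-minus-post HbA1c change in the
#'   control group.
#' @param hba1c_effect Additional intervention change (treatment effect).
#' @param eh_baseline_mean,eh_baseline_sd,eh_control_change,eh_effect
#'   Same structure for the eating-habits composite (10-40 scale).
#' @param nse_mean,nse_sd Nutrition self-efficacy composite moments
#'   (no group effect: it is a confounder check).
#' @param correlation Within-subject pre/post correlation (in \[-1, 1\]).
#' @param hba1c_floor Physiologic lower truncation for HbA1c, applied
#'   after effect injection (default 4.0; `-Inf` disables).
#' @param seed Integer seed (or `NULL`).
#' @return A list of class `"study_gen_config"`.
#' @export
study_gen_config <- function(n_per_group = c(intervention = 9L,
                                             control = 12L),
                             hba1c_baseline_mean = 7.6,
                             hba1c_baseline_sd = 2.2,
                             hba1c_control_change = 0.23,
                             hba1c_effect = 1.18,
                             eh_baseline_mean = 24.8,
                             eh_baseline_sd = 4.4,
                             eh_control_change = -0.25,
                             eh_effect = -0.75,
                             nse_mean = 15.0,
                             nse_sd = 2.7,
                             correlation = 0.7,
                             hba1c_floor = 4.0,
                             seed = NULL) {
  if (length(n_per_group) != 2L ||
      !all(c("intervention", "control") %in% names(n_per_group))) {
    stop("'n_per_group' must be c(intervention = , control = )",
         call. = FALSE)
  }
  check_count(n_per_group[["intervention"]], "n_per_group[intervention]",
              min = 2L)
  check_count(n_per_group[["control"]], "n_per_group[control]", min = 2L)
  for (nm in c("hba1c_baseline_sd", "eh_baseline_sd", "nse_sd")) {
    if (get(nm) < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  if (correlation < -1 || correlation > 1) {
    stop("'correlation' must lie in [-1, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "study_gen_config")
}

# Pre/post draws for one group across reps: pre ~ N(mu, sd); post has the
# same marginal SD, correlation rho with pre, and mean mu - change.
.sim_prepost <- function(n, mu, sd, change, rho, floor_at, reps = 1L) {
  pre <- matrix(stats::rnorm(n * reps, mu, sd), n, reps)
  eps <- matrix(stats::rnorm(n * reps, 0, 1), n, reps)
  post <- (mu - change) + rho * (pre - mu) + sd * sqrt(1 - rho^2) * eps
  if (is.finite(floor_at)) {
    pre <- pmax(pre, floor_at)
    post <- pmax(post, floor_at)
  }
  list(pre = pre, post = post)
}

#' Simulate a two-group pre/post study
#'
#' Draws per-subject bivariate-normal pre/post HbA1c and eating-habits
#' outcomes plus a nutrition self-efficacy composite under the
#' configured group effects; reproducible under the configuration seed.
#'
#' @param config A [study_gen_config()].
#' @return Data frame in the study schema (`subject_id`, `group`,
#'   `pre_hba1c`, `post_hba1c`, `pre_eh`, `post_eh`, `nse`).
#' @export
simulate_study <- function(config = study_gen_config()) {
  stopifnot(inherits(config, "study_gen_config"))
  .with_seed(config$seed, {
    one_group <- function(group, n) {
      chg_h <- config$hba1c_control_change +
        if (group == "intervention") config$hba1c_effect else 0
      chg_e <- config$eh_control_change +
        if (group == "intervention") config$eh_effect else 0
      h <- .sim_prepost(n, config$hba1c_baseline_mean,
                        config$hba1c_baseline_sd, chg_h,
                        config$correlation, config$hba1c_floor)
      e <- .sim_prepost(n, config$eh_baseline_mean, config$eh_baseline_sd,
                        chg_e, config$correlation, -Inf)
      data.frame(group = group,
                 pre_hba1c = h$pre[, 1], post_hba1c = h$post[, 1],
                 pre_eh = e$pre[, 1], post_eh = e$post[, 1],
                 nse = stats::rnorm(n, config$nse_mean, config$nse_sd),
                 stringsAsFactors = FALSE)
    }
    out <- rbind(one_group("intervention",
                           config$n_per_group[["intervention"]]),
                 one_group("control", config$n_per_group[["control"]]))
    out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out)
    out$subject_id <- as.character(out$subject_id)
    out
  })
}

#' Monte-Carlo power of the between-group change test
#'
#' Simulates the configured study repeatedly and reports the rejection
#' rate of the two-tailed pooled-variance t test comparing the two
#' groups' pre-minus-post HbA1c changes. With the effect set to zero
#' this estimates the type-I error rate.
#'
#' @param config A [study_gen_config()].
#' @param alpha Significance level (two-tailed).
#' @param reps Number of simulated studies (>= 100).
#' @param seed Integer seed (or `NULL`).
#' @return Rejection rate in \[0, 1\].
#' @export
estimate_power <- function(config = study_gen_config(), alpha = 0.05,
                           reps = 2000L, seed = NULL) {
  stopifnot(inherits(config, "study_gen_config"))
  reps <- check_count(reps, "reps", min = 100L)
  if (alpha < 0 || alpha > 1) {
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  }
  n1 <- config$n_per_group[["intervention"]]
  n2 <- config$n_per_group[["control"]]
  .with_seed(seed, {
    g1 <- .sim_prepost(n1, config$hba1c_baseline_mean,
                       config$hba1c_baseline_sd,
                       config$hba1c_control_change + config$hba1c_effect,
                       config$correlation, config$hba1c_floor, reps)
    g2 <- .sim_prepost(n2, config$hba1c_baseline_mean,
                       config$hba1c_baseline_sd,
                       config$hba1c_control_change,
                       config$correlation, config$hba1c_floor, reps)
    d1 <- g1$pre - g1$post
    d2 <- g2$pre - g2$post
    m1 <- colMeans(d1); m2 <- colMeans(d2)
    v1 <- (colSums(d1^2) - n1 * m1^2) / (n1 - 1)
    v2 <- (colSums(d2^2) - n2 * m2^2) / (n2 - 1)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- (m1 - m2) / se
    if (alpha == 0) return(0)
    crit <- stats::qt(1 - alpha / 2, df)
    mean(abs(tstat) > crit)
  })
}
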