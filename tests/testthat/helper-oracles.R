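# Independent oracles and fixture builders shared across tests.

# Straight-line transcription of the scoring rules as nested
# conditionals, written independently of the package's weight functions.
# Returns the total score only.
oracle_total <- function(calories, carbs_g, fat_g, satfat_g, protein_g,
                         sodium_mg, fiber_g, rrc, hypertension = FALSE) {
  crc_w <- if (calories <= rrc) 1 else -1

  C <- 4 * carbs_g
  c_w <- if (C < 0.45 * rrc) 0 else if (C <= 0.65 * rrc) 1 else -1

  F_ <- 9 * fat_g
  f_w <- if (F_ < 0.25 * rrc) 0 else if (F_ <= 0.35 * rrc) 1 else -1
  if (hypertension && 9 * satfat_g > 0.07 * rrc) f_w <- -1

  P <- 4 * protein_g
  pr_w <- if (P < 0.15 * rrc) 0 else if (P <= 0.20 * rrc) 2 else -2

  # hypertension tightens: stricter of the 450 mg general and 1500/3 mg
  # hypertension per-meal limits
  s_cut <- if (hypertension) min(450, 500) else 450
  s_w <- if (sodium_mg <= s_cut) 1 else -1

  df_w <- if (fiber_g > 10) 3 else if (fiber_g >= 6) 2 else 0

  crc_w + c_w + f_w + pr_w + s_w + df_w
}

# Vector with exactly the requested sample mean and SD (n >= 2).
moment_match <- function(mean, sd, n) {
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# A boundary-crossing nutrient grid at a fixed budget: values straddle
# every rule cutoff by +/- eps plus the cutoff itself.
boundary_grid <- function(rrc = 600, eps = 1e-6) {
  around <- function(x) c(x - eps, x, x + eps)
  g <- expand.grid(
    calories = c(0.5 * rrc, around(rrc)[c(1, 3)], rrc),
    carbs_g = c(0, around(0.45 * rrc / 4)[2], around(0.65 * rrc / 4)),
    fat_g = c(0, around(0.25 * rrc / 9)[c(1, 2)],
              around(0.35 * rrc / 9)[c(2, 3)]),
    protein_g = c(0, around(0.15 * rrc / 4)[2], around(0.20 * rrc / 4)),
    sodium_mg = around(450),
    fiber_g = c(around(6)[c(1, 2)], around(10)[c(2, 3)])
  )
  g$satfat_g <- pmin(g$fat_g, c(0, 2.8, 4.7, 14)[(seq_len(nrow(g)) %% 4) + 1])
  g
}

# Wrap a nutrient grid in the recipe schema for bulk scoring.
grid_to_recipes <- function(grid) {
  cbind(data.frame(recipe_id = sprintf("g%05d", seq_len(nrow(grid))),
                   name = "grid", cuisine = NA_character_,
                   stringsAsFactors = FALSE),
        grid[, c("calories", "carbs_g", "fat_g", "satfat_g", "protein_g",
                 "sodium_mg", "fiber_g")])
}

# The two worked recipes used throughout: a high-scoring and a
# low-scoring one at a 600 kcal/meal budget.
worked_recipes <- function() {
  rbind(
    nutrient_profile("r1", "good", 550, 75, 20, 2, 25, 400, 8,
                     cuisine = "mediterranean"),
    nutrient_profile("r2", "bad", 700, 120, 30, 10, 10, 900, 3,
                     cuisine = "mexican")
  )
}

# Moment-matched per-subject study reproducing the printed group and
# paired summaries exactly: pre outcomes and pre-minus-post changes both
# carry the published moments, so every summary-derivable statistic of
# the report tables is reproduced from raw data.
published_moment_study <- function(seed = 42) {
  set.seed(seed)
  build_group <- function(group, n, pre_h, sd_h, d_h, sd_dh,
                          pre_e, sd_e, d_e, sd_de, nse_m, nse_sd) {
    pre_hba1c <- moment_match(pre_h, sd_h, n)
    pre_eh <- moment_match(pre_e, sd_e, n)
    data.frame(
      group = group,
      pre_hba1c = pre_hba1c,
      post_hba1c = pre_hba1c - moment_match(d_h, sd_dh, n),
      pre_eh = pre_eh,
      post_eh = pre_eh - moment_match(d_e, sd_de, n),
      nse = moment_match(nse_m, nse_sd, n),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    build_group("intervention", 9, 8.13, 2.83, 1.41, 1.75,
                23.33, 3.08, -1.00, 2.74, 14.67, 1.66),
    build_group("control", 12, 7.13, 1.49, 0.23167, 0.62,
                25.83, 5.27, -0.25, 4.31, 15.25, 3.22)
  )
  cbind(subject_id = sprintf("S%02d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

# Closed-form power of the two-sided two-sample t test via the
# noncentral t distribution.
power_closed_form <- function(d, n1, n2, alpha = 0.05) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}
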