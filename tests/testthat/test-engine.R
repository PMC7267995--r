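# The scoring engine: component weight rules, breakdowns, traffic-light
# binning, ranking, meal plans, engagement tiers.

test_that("macronutrient calorie conversion uses Atwater factors", {
  expect_identical(macronutrient_calories(75, "carb"), 300)
  expect_identical(macronutrient_calories(20, "fat"), 180)
  expect_identical(macronutrient_calories(0, "protein"), 0)
  expect_error(macronutrient_calories(-1, "carb"), "non-negative")
})

test_that("component weights follow the range rules at and around cutoffs", {
  # calories: inclusive at the budget
  expect_identical(weight_calories(550, 600), 1L)
  expect_identical(weight_calories(700, 600), -1L)
  expect_identical(weight_calories(600, 600), 1L)

  # carbohydrate: 45-65% of budget, neutral below
  expect_identical(weight_carbohydrate(75, 600), 1L)    # 50%
  expect_identical(weight_carbohydrate(120, 600), -1L)  # 80%
  expect_identical(weight_carbohydrate(0, 600), 0L)

  # fat: 25-35% of budget, neutral-with-message below
  expect_identical(weight_fat(20, 2, 600)$weight, 1L)   # 30%
  lf <- weight_fat(10, 1, 600)                          # 15%
  expect_identical(lf$weight, 0L)
  expect_identical(lf$message, "Good job. This choice is low in fat.")
  expect_identical(weight_fat(30, 3, 600)$weight, -1L)  # 45%

  # protein: double weight, 15-20% of budget
  expect_identical(weight_protein(25, 600), 2L)   # ~16.7%
  expect_identical(weight_protein(10, 600), 0L)   # ~6.7%
  expect_identical(weight_protein(45, 600), -2L)  # 30%

  # sodium: 450 mg cutoff, inclusive
  expect_identical(weight_sodium(400), 1L)
  expect_identical(weight_sodium(900), -1L)
  expect_identical(weight_sodium(450), 1L)

  # fiber: bonus-only weight
  expect_identical(weight_fiber(8), 2L)
  expect_identical(weight_fiber(12), 3L)
  expect_identical(weight_fiber(3), 0L)
  expect_identical(weight_fiber(6), 2L)
  expect_identical(weight_fiber(10), 2L)

  expect_error(weight_fat(5, 6, 600), "satfat_g")
  expect_error(weight_sodium(-1), "non-negative")
})

test_that("hypertension variants tighten sodium and add a saturated-fat check", {
  # hypertension applies the stricter of the general and 1500/3 mg
  # limits; with the defaults (450 < 500) the general cutoff binds ...
  expect_identical(weight_sodium(480, hypertension = TRUE), -1L)
  expect_identical(weight_sodium(450, hypertension = TRUE), 1L)
  # ... and with a laxer general cutoff (2300/3) the 500 mg limit does
  cfg_na <- engine_config(sodium_cutoff_mg = 2300 / 3)
  expect_identical(weight_sodium(600, FALSE, cfg_na), 1L)
  expect_identical(weight_sodium(600, TRUE, cfg_na), -1L)

  # saturated fat: 54 kcal from 6 g > 7% of 600 kcal -> forced -1
  hf <- weight_fat(20, 6, 600, hypertension = TRUE)
  expect_identical(hf$weight, -1L)
  expect_match(hf$message, "Saturated fat")
  expect_identical(weight_fat(20, 6, 600, hypertension = FALSE)$weight, 1L)

  # alternative base: 7% of fat calories instead of the budget
  cfg_fat <- engine_config(satfat_base = "fat")
  # 3 g sat = 27 kcal; 7% of 360 fat kcal = 25.2 (hit), 7% of 600 = 42 (no hit)
  expect_identical(weight_fat(40, 3, 600, TRUE, cfg_fat)$weight, -1L)
  expect_identical(weight_fat(40, 3, 600, TRUE)$weight, -1L)  # 40 g is over-range anyway
  expect_identical(weight_fat(20, 3, 600, TRUE, cfg_fat)$weight, -1L)
  expect_identical(weight_fat(20, 3, 600, TRUE)$weight, 1L)
})

test_that("score breakdowns sum the six weights and bin them", {
  r <- worked_recipes()
  good <- score_recipe_at(r[1, ], 600)
  expect_identical(c(good$crc_w, good$c_w, good$f_w, good$pr_w, good$s_w,
                     good$df_w), c(1L, 1L, 1L, 2L, 1L, 2L))
  expect_identical(good$total, 8L)
  expect_identical(good$bin, 7L)

  bad <- score_recipe_at(r[2, ], 600)
  expect_identical(c(bad$crc_w, bad$c_w, bad$f_w, bad$pr_w, bad$s_w,
                     bad$df_w), c(-1L, -1L, -1L, 0L, -1L, 0L))
  expect_identical(bad$total, -4L)
  expect_identical(bad$bin, 1L)

  zero <- score_recipe_at(
    nutrient_profile("z", "empty", 0, 0, 0, 0, 0, 0, 0), 600)
  expect_identical(zero$total, 2L)
  expect_true("Good job. This choice is low in fat." %in% zero$messages)

  # profile-driven scoring agrees with the budget-driven path
  p <- user_profile(30, "male", 180, 80)
  rrc <- energy_requirement(p)$rrc
  expect_identical(score_recipe(p, r[1, ])$total,
                   score_recipe_at(r[1, ], rrc)$total)
})

test_that("traffic-light binning is linear over the achievable totals", {
  expect_identical(traffic_light_bin(9)$bin, 7L)
  expect_identical(traffic_light_bin(9)$color_label, "green")
  expect_identical(traffic_light_bin(-6)$bin, 0L)
  expect_identical(traffic_light_bin(-6)$color_label, "red")
  expect_identical(traffic_light_bin(1)$bin, 3L)
  # two consecutive totals per bin, monotone, clamped to 0..7
  bins <- traffic_light_bin(-6:9)$bin
  expect_identical(bins, rep(0:7, each = 2))
  expect_error(traffic_light_bin(10), "\\[-6, 9\\]")
  expect_error(traffic_light_bin(-7), "\\[-6, 9\\]")
})

test_that("scoring matches an independent nested-conditional oracle", {
  grid <- boundary_grid(rrc = 600)
  grid <- grid[seq(1, nrow(grid), by = 7), ]  # thinned here; full in acceptance
  for (htn in c(FALSE, TRUE)) {
    got <- vapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      score_recipe_at(nutrient_profile("x", "x", g$calories, g$carbs_g,
                                       g$fat_g, g$satfat_g, g$protein_g,
                                       g$sodium_mg, g$fiber_g),
                      600, htn)$total
    }, integer(1))
    want <- vapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      oracle_total(g$calories, g$carbs_g, g$fat_g, g$satfat_g,
                   g$protein_g, g$sodium_mg, g$fiber_g, 600, htn)
    }, numeric(1))
    expect_identical(got, as.integer(want))
  }
})

test_that("ranking is a deterministic permutation, best first", {
  p <- user_profile(30, "male", 180, 80, meals_per_day = 3)
  r <- worked_recipes()
  ranked <- rank_recipes(p, r)
  expect_identical(sort(ranked$recipe_id), sort(r$recipe_id))
  expect_true(all(diff(ranked$total) <= 0))
  expect_identical(ranked$recipe_id[1], "r1")

  # ties broken by recipe_id ascending
  twin <- r[c(1, 1), ]
  twin$recipe_id <- c("b", "a")
  twin$name <- c("b", "a")
  expect_identical(rank_recipes(p, twin)$recipe_id, c("a", "b"))

  single <- rank_recipes(p, r[1, ])
  expect_identical(nrow(single), 1L)
  expect_error(rank_recipes(p, r[0, ]), "at least one")
})

test_that("meal plans cover days without within-day repetition", {
  p <- user_profile(30, "male", 180, 80)
  set.seed(11)
  corpus <- generate_recipes(recipe_gen_config(n_recipes = 21, seed = 11))
  plan <- build_meal_plan(p, corpus, days = 7, per_day = 3)
  ids <- unlist(plan$days)
  expect_identical(length(ids), 21L)
  expect_identical(sort(unique(ids)), sort(corpus$recipe_id))  # exact cover
  for (d in plan$days) expect_false(anyDuplicated(d) > 0)

  # fewer recipes than slots: reuse across days, never within one
  plan2 <- build_meal_plan(p, corpus[1:5, ], days = 4, per_day = 3)
  for (d in plan2$days) expect_false(anyDuplicated(d) > 0)

  one <- build_meal_plan(p, corpus, days = 1, per_day = 1)
  expect_identical(one$days$day1, rank_recipes(p, corpus)$recipe_id[1])

  expect_error(build_meal_plan(p, corpus, cuisines = "martian"),
               "insufficient recipes")
})

test_that("engagement tiers honor the configured thresholds", {
  expect_identical(engagement_tier(0), "bronze")
  expect_identical(engagement_tier(4), "bronze")
  expect_identical(engagement_tier(5), "silver")
  expect_identical(engagement_tier(14), "silver")
  expect_identical(engagement_tier(15), "gold")
  cfg <- engine_config(trophy_thresholds = c(silver = 2, gold = 4))
  expect_identical(engagement_tier(3, cfg), "silver")
  expect_error(engagement_tier(-1), "n_saved")
})
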