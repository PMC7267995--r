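# The recipe-scoring engine: six weight rules against the per-meal calorie
# budget, an eight-value traffic-light rendering of the summed score,
# ranking, meal planning and engagement tiers.

KCAL_PER_G <- c(carb = 4, fat = 9, protein = 4)

.lowfat_message <- "Good job. This choice is low in fat."

#' Create a recipe nutrient profile
#'
#' The five scored nutrients plus saturated fat and calories for one
#' recipe. All quantities are per serving/meal.
#'
#' @param recipe_id Identifier (character or coercible).
#' @param name Display name.
#' @param calories kcal (>= 0); the "chosen recipe calories".
#' @param carbs_g,fat_g,protein_g,fiber_g Grams (>= 0).
#' @param satfat_g Saturated fat in grams (0 <= satfat_g <= fat_g).
#' @param sodium_mg Sodium in milligrams (>= 0).
#' @param cuisine Optional cuisine tag.
#' @return A one-row data frame with class `"nutrient_profile"` prepended.
#' @export
#' @examples
#' nutrient_profile("r1", "Falafel salad", 550, 75, 20, 2, 25, 400, 8)
nutrient_profile <- function(recipe_id, name = recipe_id, calories,
                             carbs_g, fat_g, satfat_g = 0, protein_g,
                             sodium_mg, fiber_g, cuisine = NA_character_) {
  check_nonneg(calories, "calories")
  check_nonneg(carbs_g, "carbs_g")
  check_nonneg(fat_g, "fat_g")
  check_nonneg(satfat_g, "satfat_g")
  check_nonneg(protein_g, "protein_g")
  check_nonneg(sodium_mg, "sodium_mg")
  check_nonneg(fiber_g, "fiber_g")
  if (satfat_g > fat_g) {
    stop("'satfat_g' cannot exceed 'fat_g'", call. = FALSE)
  }
  out <- data.frame(recipe_id = as.character(recipe_id),
                    name = as.character(name),
                    cuisine = as.character(cuisine),
                    calories = calories, carbs_g = carbs_g, fat_g = fat_g,
                    satfat_g = satfat_g, protein_g = protein_g,
                    sodium_mg = sodium_mg, fiber_g = fiber_g,
                    stringsAsFactors = FALSE)
  class(out) <- c("nutrient_profile", class(out))
  out
}

#' Calories supplied by a macronutrient mass
#'
#' Standard Atwater factors: 4 kcal/g for carbohydrate and protein,
#' 9 kcal/g for fat.
#'
#' @param grams Mass in grams (>= 0, vectorized).
#' @param kind `"carb"`, `"fat"` or `"protein"`.
#' @return kcal.
#' @export
#' @examples
#' macronutrient_calories(75, "carb")  # 300
macronutrient_calories <- function(grams, kind = c("carb", "fat", "protein")) {
  kind <- match.arg(kind)
  if (any(!is.finite(grams)) || any(grams < 0)) {
    stop("'grams' must be non-negative", call. = FALSE)
  }
  KCAL_PER_G[[kind]] * grams
}

#' Calorie weight
#'
#' +1 when the recipe's calories fit the per-meal budget (inclusive),
#' otherwise -1.
#'
#' @param crc Chosen recipe calories, kcal (>= 0, vectorized).
#' @param rrc Per-meal budget, kcal (> 0).
#' @return Integer weight(s) in \{-1, +1\}.
#' @export
weight_calories <- function(crc, rrc) {
  if (any(!is.finite(crc)) || any(crc < 0)) {
    stop("'crc' must be non-negative", call. = FALSE)
  }
  check_positive(rrc, "rrc")
  ifelse(crc <= rrc, 1L, -1L)
}

#' Carbohydrate weight
#'
#' Carbohydrate calories (4 kcal/g) are compared with 45-65% of the
#' per-meal budget: +1 in range (inclusive), 0 below, -1 above.
#'
#' @param carbs_g Grams of carbohydrate (vectorized).
#' @param rrc Per-meal budget, kcal (> 0).
#' @param config An [engine_config()] (range override).
#' @return Integer weight(s) in \{-1, 0, +1\}.
#' @export
weight_carbohydrate <- function(carbs_g, rrc, config = engine_config()) {
  check_positive(rrc, "rrc")
  kcal <- macronutrient_calories(carbs_g, "carb")
  r <- config$carb_range * rrc
  ifelse(kcal < r[1], 0L, ifelse(kcal > r[2], -1L, 1L))
}

# Vectorized fat rule; returns weight plus the flags the messages are
# built from. Hypertension forces -1 whenever saturated-fat calories
# exceed the configured 7% base.
.fat_weights <- function(fat_g, satfat_g, rrc, hypertension,
                         config = engine_config()) {
  fat_kcal <- macronutrient_calories(fat_g, "fat")
  r <- config$fat_range * rrc
  w <- ifelse(fat_kcal < r[1], 0L, ifelse(fat_kcal > r[2], -1L, 1L))
  lowfat <- fat_kcal < r[1]
  sat_kcal <- 9 * satfat_g
  sat_base <- if (config$satfat_base == "rrc") rrc else fat_kcal
  sat_hit <- hypertension & (sat_kcal > config$satfat_limit * sat_base)
  w[sat_hit] <- -1L
  lowfat[sat_hit] <- FALSE
  list(weight = w, lowfat = lowfat, satfat_hit = sat_hit)
}

#' Fat weight
#'
#' Fat calories (9 kcal/g) are compared with 25-35% of the per-meal
#' budget: +1 in range (inclusive), -1 above, 0 below with an
#' encouraging low-fat message. For hypertensive users a saturated-fat
#' check runs on top: if saturated-fat calories exceed 7% of the budget
#' (or of fat calories, per configuration) the weight is forced to -1.
#'
#' @param fat_g,satfat_g Grams (0 <= satfat_g <= fat_g).
#' @param rrc Per-meal budget, kcal (> 0).
#' @param hypertension Logical.
#' @param config An [engine_config()].
#' @return List with `weight` (integer) and `message` (character or `NULL`).
#' @export
weight_fat <- function(fat_g, satfat_g = 0, rrc, hypertension = FALSE,
                       config = engine_config()) {
  check_nonneg(fat_g, "fat_g")
  check_nonneg(satfat_g, "satfat_g")
  check_positive(rrc, "rrc")
  if (satfat_g > fat_g) {
    stop("'satfat_g' cannot exceed 'fat_g'", call. = FALSE)
  }
  fw <- .fat_weights(fat_g, satfat_g, rrc, hypertension, config)
  msg <- if (fw$satfat_hit) {
    "Saturated fat exceeds the 7% limit for hypertension."
  } else if (fw$lowfat) .lowfat_message
  list(weight = fw$weight, message = msg)
}

#' Protein weight
#'
#' Protein calories (4 kcal/g) are compared with 15-20% of the per-meal
#' budget: +2 in range (inclusive), 0 below, -2 above.
#'
#' @inheritParams weight_carbohydrate
#' @param protein_g Grams of protein (vectorized).
#' @return Integer weight(s) in \{-2, 0, +2\}.
#' @export
weight_protein <- function(protein_g, rrc, config = engine_config()) {
  check_positive(rrc, "rrc")
  kcal <- macronutrient_calories(protein_g, "protein")
  r <- config$protein_range * rrc
  ifelse(kcal < r[1], 0L, ifelse(kcal > r[2], -2L, 2L))
}

#' Sodium weight
#'
#' +1 at or below the cutoff, -1 above (inclusive boundary). The general
#' cutoff is 450 mg per meal. Hypertension carries its own per-meal
#' limit, 1500/3 = 500 mg (one third of the 1500 mg/day recommendation
#' for comorbid diabetes and hypertension); since hypertension calls for
#' a further sodium reduction, never a relaxation, the effective cutoff
#' under hypertension is the stricter of the two limits.
#'
#' @param sodium_mg Milligrams of sodium (vectorized).
#' @param hypertension Logical.
#' @param config An [engine_config()].
#' @return Integer weight(s) in \{-1, +1\}.
#' @export
weight_sodium <- function(sodium_mg, hypertension = FALSE,
                          config = engine_config()) {
  if (any(!is.finite(sodium_mg)) || any(sodium_mg < 0)) {
    stop("'sodium_mg' must be non-negative", call. = FALSE)
  }
  cutoff <- if (hypertension) {
    min(config$sodium_cutoff_mg, config$sodium_cutoff_htn_mg)
  } else {
    config$sodium_cutoff_mg
  }
  ifelse(sodium_mg <= cutoff, 1L, -1L)
}

#' Dietary-fiber weight
#'
#' +2 for 6-10 g (inclusive), +3 above 10 g, 0 below 6 g. Fiber can only
#' help a score; exceeding the range earns the larger bonus.
#'
#' @param fiber_g Grams of fiber (vectorized).
#' @param config An [engine_config()].
#' @return Integer weight(s) in \{0, 2, 3\}.
#' @export
weight_fiber <- function(fiber_g, config = engine_config()) {
  if (any(!is.finite(fiber_g)) || any(fiber_g < 0)) {
    stop("'fiber_g' must be non-negative", call. = FALSE)
  }
  r <- config$fiber_range_g
  ifelse(fiber_g > r[2], 3L, ifelse(fiber_g < r[1], 0L, 2L))
}

# Eight ordered labels, red (poor) to green (optimal).
.traffic_labels <- c("red", "red-orange", "orange", "amber",
                     "yellow", "yellow-green", "light-green", "green")

#' Map a total score to the eight-value traffic-light scale
#'
#' The 16 achievable integer totals (-6..9) are binned linearly, two per
#' bin: `bin = floor((total + 6) / 2)`, clamped to 0..7. Bin 0 is red
#' (poor), bin 7 green (optimal); a neutral score sits near the middle.
#'
#' @param total Integer total score in \[-6, 9\] (vectorized).
#' @return List with `bin` (integer 0-7) and `color_label`.
#' @export
#' @examples
#' traffic_light_bin(9)   # bin 7, green
#' traffic_light_bin(-6)  # bin 0, red
traffic_light_bin <- function(total) {
  if (any(!is.finite(total)) || any(total < -6) || any(total > 9)) {
    stop("'total' must lie in [-6, 9]", call. = FALSE)
  }
  bin <- pmax(0L, pmin(7L, as.integer(floor((total + 6) / 2))))
  list(bin = bin, color_label = .traffic_labels[bin + 1L])
}

#' Score a whole corpus at a fixed per-meal budget
#'
#' Vectorized scoring: applies the six weight rules to every recipe at
#' once. This is the bulk backend behind [rank_recipes()]; use it when
#' scoring thousands of recipes.
#'
#' @param recipes Data frame in the recipe schema.
#' @param rrc Per-meal budget, kcal (> 0).
#' @param hypertension Logical.
#' @param config An [engine_config()].
#' @return Data frame with one row per recipe: the six weights, `total`,
#'   `bin`, `color_label`, and the `lowfat`/`satfat_hit` message flags.
#' @export
score_table <- function(recipes, rrc, hypertension = FALSE,
                        config = engine_config()) {
  recipes <- as.data.frame(recipes)
  check_positive(rrc, "rrc")
  fw <- .fat_weights(recipes$fat_g, recipes$satfat_g, rrc, hypertension,
                     config)
  w <- data.frame(
    crc_w = weight_calories(recipes$calories, rrc),
    c_w = weight_carbohydrate(recipes$carbs_g, rrc, config),
    f_w = fw$weight,
    pr_w = weight_protein(recipes$protein_g, rrc, config),
    s_w = weight_sodium(recipes$sodium_mg, hypertension, config),
    df_w = weight_fiber(recipes$fiber_g, config)
  )
  total <- as.integer(rowSums(w))
  tl <- traffic_light_bin(total)
  cbind(data.frame(recipe_id = recipes$recipe_id,
                   name = recipes$name, stringsAsFactors = FALSE),
        w, total = total, bin = tl$bin, color_label = tl$color_label,
        lowfat = fw$lowfat, satfat_hit = fw$satfat_hit)
}

#' Score one recipe at an explicit per-meal budget
#'
#' The low-level scorer: applies the six weight rules at a given budget
#' and hypertension status and assembles the full breakdown. Use
#' [score_recipe()] to derive the budget from a user profile.
#'
#' @param recipe A [nutrient_profile()] or one-row data frame with the
#'   recipe schema columns.
#' @param rrc Per-meal calorie budget, kcal (> 0).
#' @param hypertension Logical.
#' @param config An [engine_config()].
#' @return A list of class `"score_breakdown"`: the six component weights
#'   (`crc_w`, `c_w`, `f_w`, `pr_w`, `s_w`, `df_w`), `total`, `bin`,
#'   `color_label` and `messages`.
#' @export
score_recipe_at <- function(recipe, rrc, hypertension = FALSE,
                            config = engine_config()) {
  recipe <- as.data.frame(recipe)
  if (nrow(recipe) != 1L) {
    stop("'recipe' must be a single recipe record", call. = FALSE)
  }
  if (recipe$satfat_g > recipe$fat_g) {
    stop("'satfat_g' cannot exceed 'fat_g'", call. = FALSE)
  }
  st <- score_table(recipe, rrc, hypertension, config)
  messages <- character(0)
  if (st$satfat_hit) {
    messages <- c(messages,
                  "Saturated fat exceeds the 7% limit for hypertension.")
  }
  if (st$lowfat) messages <- c(messages, .lowfat_message)
  neg <- c(
    if (st$crc_w < 0) "Calories exceed your per-meal budget.",
    if (st$c_w < 0) "Carbohydrates are above the recommended range.",
    if (st$f_w < 0 && !st$satfat_hit) "Fat is above the recommended range.",
    if (st$pr_w < 0) "Protein is above the recommended range.",
    if (st$s_w < 0) "Sodium is above the recommended amount."
  )
  structure(list(recipe_id = st$recipe_id, name = st$name, rrc = rrc,
                 crc_w = st$crc_w, c_w = st$c_w, f_w = st$f_w,
                 pr_w = st$pr_w, s_w = st$s_w, df_w = st$df_w,
                 total = st$total, bin = st$bin,
                 color_label = st$color_label,
                 messages = c(messages, neg)),
            class = "score_breakdown")
}

#' Score a recipe for a user
#'
#' Computes the user's per-meal budget (Harris-Benedict BMR divided by
#' meals per day), applies the six nutrient weight rules, sums them and
#' maps the total onto the eight-value traffic-light scale. Deterministic.
#'
#' @param profile A [user_profile()].
#' @param recipe A [nutrient_profile()] or equivalent one-row data frame.
#' @param config An [engine_config()].
#' @return A `"score_breakdown"`; see [score_recipe_at()].
#' @export
#' @examples
#' p <- user_profile(30, "male", 180, 80)
#' r <- nutrient_profile("r1", "Falafel salad", 550, 75, 20, 2, 25, 400, 8)
#' score_recipe(p, r)
score_recipe <- function(profile, recipe, config = engine_config()) {
  stopifnot(inherits(profile, "user_profile"))
  er <- energy_requirement(profile, config)
  score_recipe_at(recipe, er$rrc, profile$hypertension, config)
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("<score_breakdown> %s (budget %.1f kcal/meal)\n",
              x$name, x$rrc))
  cat(sprintf("  weights: calories %+d  carbs %+d  fat %+d  protein %+d  sodium %+d  fiber %+d\n",
              x$crc_w, x$c_w, x$f_w, x$pr_w, x$s_w, x$df_w))
  cat(sprintf("  total %d -> bin %d/7 (%s)\n", x$total, x$bin,
              x$color_label))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Rank a recipe corpus for a user
#'
#' Scores every recipe against the user's per-meal budget and sorts by
#' total score, best first; ties are broken by `recipe_id` ascending so
#' the order is deterministic.
#'
#' @param profile A [user_profile()].
#' @param recipes Data frame of recipes (the [read_recipes()] schema).
#' @param config An [engine_config()].
#' @return Data frame with one row per recipe: `recipe_id`, `name`, the
#'   six weights, `total`, `bin`, `color_label`, ordered by rank.
#' @export
rank_recipes <- function(profile, recipes, config = engine_config()) {
  stopifnot(inherits(profile, "user_profile"))
  recipes <- as.data.frame(recipes)
  if (nrow(recipes) == 0L) {
    stop("'recipes' must contain at least one recipe", call. = FALSE)
  }
  er <- energy_requirement(profile, config)
  st <- score_table(recipes, er$rrc, profile$hypertension, config)
  st <- st[order(-st$total, st$recipe_id), , drop = FALSE]
  rownames(st) <- NULL
  st[, c("recipe_id", "name", "crc_w", "c_w", "f_w", "pr_w", "s_w",
         "df_w", "total", "bin", "color_label")]
}

#' Build a meal plan from the top-ranked recipes
#'
#' Recipes are optionally filtered to the user's favorite cuisines,
#' ranked, and assigned greedily: best recipes first, cycling through the
#' ranked list so no recipe repeats within a day.
#'
#' @param profile A [user_profile()].
#' @param recipes Recipe corpus data frame.
#' @param days Number of days (>= 1).
#' @param per_day Meals per day (>= 1).
#' @param cuisines Optional cuisine filter; defaults to the profile's
#'   favorite cuisines, or no filter if the profile has none.
#' @param config An [engine_config()].
#' @return A list of class `"meal_plan"`: `days` (a list mapping
#'   `day1..dayN` to recipe-id vectors) and `profile`.
#' @export
build_meal_plan <- function(profile, recipes, days = 7L, per_day = 3L,
                            cuisines = profile$cuisines,
                            config = engine_config()) {
  days <- check_count(days, "days")
  per_day <- check_count(per_day, "per_day")
  recipes <- as.data.frame(recipes)
  if (!is.null(cuisines)) {
    recipes <- recipes[recipes$cuisine %in% cuisines, , drop = FALSE]
  }
  if (nrow(recipes) < per_day) {
    stop(sprintf(
      "insufficient recipes: %d available%s but %d needed per day",
      nrow(recipes),
      if (is.null(cuisines)) "" else " after cuisine filtering", per_day),
      call. = FALSE)
  }
  ranked <- rank_recipes(profile, recipes, config)
  ids <- ranked$recipe_id
  idx <- (seq_len(days * per_day) - 1L) %% length(ids) + 1L
  plan <- split(ids[idx], rep(seq_len(days), each = per_day))
  names(plan) <- paste0("day", seq_len(days))
  structure(list(days = plan, profile = profile), class = "meal_plan")
}

#' @export
print.meal_plan <- function(x, ...) {
  cat(sprintf("<meal_plan> %d day(s), %d meal(s)/day\n",
              length(x$days), length(x$days[[1]])))
  for (d in names(x$days)) {
    cat(sprintf("  %s: %s\n", d, paste(x$days[[d]], collapse = ", ")))
  }
  invisible(x)
}

#' Engagement trophy tier
#'
#' Users are binned by how many recipes they have saved to meal plans:
#' bronze below the silver threshold, gold at or above the gold threshold.
#'
#' @param n_saved Number of saved recipes (>= 0).
#' @param config An [engine_config()] (threshold overrides).
#' @return `"bronze"`, `"silver"` or `"gold"`.
#' @export
#' @examples
#' engagement_tier(0)   # bronze
#' engagement_tier(15)  # gold
engagement_tier <- function(n_saved, config = engine_config()) {
  check_nonneg(n_saved, "n_saved")
  th <- config$trophy_thresholds
  if (n_saved >= th[["gold"]]) "gold"
  else if (n_saved >= th[["silver"]]) "silver"
  else "bronze"
}
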