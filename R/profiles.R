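# User profiles and energy requirements: the Harris-Benedict basal
# metabolic rate and the per-meal calorie budget derived from it.

# Harris-Benedict coefficient sets (intercept, weight kg, height cm, age y).
# "original" is the 1919 publication; "revised" the 1984 re-estimation.
.hb_coef <- list(
  original = list(
    male   = c(66.4730, 13.7516, 5.0033, 6.7550),
    female = c(655.0955, 9.5634, 1.8496, 4.6756)
  ),
  revised = list(
    male   = c(88.362, 13.397, 4.799, 5.677),
    female = c(447.593, 9.247, 3.098, 4.330)
  )
)

#' Create a user profile
#'
#' Demographics plus the comorbidity flag that drives the rule variants:
#' hypertension tightens the sodium cutoff and adds a saturated-fat check.
#'
#' @param age Age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param height_cm Height in centimeters (> 0).
#' @param weight_kg Weight in kilograms (> 0).
#' @param hypertension Logical; comorbid hypertension (default `FALSE`).
#' @param meals_per_day Integer >= 1; divides the daily energy need into
#'   the per-meal budget (default 3).
#' @param cuisines Optional character vector of favorite cuisine tags used
#'   to filter meal plans.
#' @return A list of class `"user_profile"`.
#' @export
#' @examples
#' user_profile(30, "male", 180, 80)
user_profile <- function(age, sex, height_cm, weight_kg,
                         hypertension = FALSE, meals_per_day = 3L,
                         cuisines = NULL) {
  check_positive(age, "age")
  check_positive(height_cm, "height_cm")
  check_positive(weight_kg, "weight_kg")
  if (!is.character(sex) || length(sex) != 1L ||
      !sex %in% c("male", "female")) {
    stop("'sex' must be \"male\" or \"female\"", call. = FALSE)
  }
  if (!is.logical(hypertension) || length(hypertension) != 1L ||
      is.na(hypertension)) {
    stop("'hypertension' must be TRUE or FALSE", call. = FALSE)
  }
  meals_per_day <- check_count(meals_per_day, "meals_per_day")
  structure(list(age = age, sex = sex, height_cm = height_cm,
                 weight_kg = weight_kg, hypertension = hypertension,
                 meals_per_day = meals_per_day, cuisines = cuisines),
            class = "user_profile")
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("<user_profile> %s, %g y, %g cm, %g kg%s, %d meals/day\n",
              x$sex, x$age, x$height_cm, x$weight_kg,
              if (x$hypertension) ", hypertensive" else "",
              x$meals_per_day))
  invisible(x)
}

#' Read a user profile from a JSON file
#'
#' Expects a JSON object with fields `age`, `sex`, `height_cm`,
#' `weight_kg` and optionally `hypertension`, `meals_per_day`, `cuisines`.
#'
#' @param path Path to the JSON file.
#' @return A `"user_profile"`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("profile file not found: %s", path),
                               call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("age", "sex", "height_cm", "weight_kg")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop(sprintf("profile is missing field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  user_profile(age = p$age, sex = p$sex, height_cm = p$height_cm,
               weight_kg = p$weight_kg,
               hypertension = isTRUE(p$hypertension),
               meals_per_day = if (is.null(p$meals_per_day)) 3L
                               else p$meals_per_day,
               cuisines = p$cuisines)
}

#' Basal metabolic rate (Harris-Benedict)
#'
#' Estimates the daily resting energy expenditure in kcal/day from sex,
#' weight (kg), height (cm) and age (years):
#' male 66.4730 + 13.7516 W + 5.0033 H - 6.7550 A;
#' female 655.0955 + 9.5634 W + 1.8496 H - 4.6756 A (1919 coefficients;
#' the 1984 revision is available via `coefficients = "revised"`).
#' No activity multiplier is applied: the estimate is taken as the daily
#' calorie need anchoring all nutrient checks.
#'
#' @param profile A [user_profile()].
#' @param coefficients `"original"` (default) or `"revised"`.
#' @return BMR in kcal/day.
#' @export
#' @examples
#' compute_bmr(user_profile(30, "male", 180, 80))  # 1864.545
compute_bmr <- function(profile, coefficients = c("original", "revised")) {
  stopifnot(inherits(profile, "user_profile"))
  coefficients <- match.arg(coefficients)
  k <- .hb_coef[[coefficients]][[profile$sex]]
  k[1] + k[2] * profile$weight_kg + k[3] * profile$height_cm -
    k[4] * profile$age
}

#' Per-meal calorie budget (recommended recipe calories)
#'
#' Divides the daily energy need evenly over the day's meals. Every
#' nutrient-range check in the scoring engine is expressed relative to
#' this budget.
#'
#' @param bmr Daily energy need in kcal/day (> 0).
#' @param meals_per_day Integer >= 1 (default 3).
#' @return kcal per meal.
#' @export
#' @examples
#' compute_rrc(1800, 3)  # 600
compute_rrc <- function(bmr, meals_per_day = 3L) {
  check_positive(bmr, "bmr")
  meals_per_day <- check_count(meals_per_day, "meals_per_day")
  bmr / meals_per_day
}

#' Daily and per-meal energy requirement
#'
#' @param profile A [user_profile()].
#' @param config An [engine_config()] (selects the coefficient set).
#' @return List with `bmr` (kcal/day) and `rrc` (kcal/meal).
#' @export
energy_requirement <- function(profile, config = engine_config()) {
  bmr <- compute_bmr(profile, config$hb_coefficients)
  list(bmr = bmr, rrc = compute_rrc(bmr, profile$meals_per_day))
}
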