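# Central configuration: every threshold of the scoring rules and the
# statistical report conventions lives here, with validated defaults.

#' Engine configuration
#'
#' Collects every tunable parameter of the scoring engine and the
#' statistical report into one validated object. The defaults are the
#' package's reference behaviour; any component can be overridden.
#'
#' @param hb_coefficients Harris-Benedict coefficient set: `"original"`
#'   (the 1919 publication) or `"revised"` (the 1984 Roza-Shizgal
#'   re-estimation).
#' @param satfat_base Denominator of the 7% saturated-fat check applied to
#'   hypertensive users: `"rrc"` (saturated-fat calories vs 7% of the
#'   per-meal calorie budget, the American Diabetes Association "percent of
#'   calories" reading) or `"fat"` (vs 7% of the recipe's fat calories).
#' @param satfat_limit Saturated-fat fraction limit (default 0.07).
#' @param sodium_cutoff_mg Sodium cutoff in mg for non-hypertensive users
#'   (default 450).
#' @param sodium_cutoff_htn_mg Sodium cutoff in mg under hypertension
#'   (default 500 = 1500 mg/day over three meals).
#' @param carb_range,fat_range,protein_range Macronutrient calorie ranges
#'   as fractions of the per-meal budget (RRC).
#' @param fiber_range_g Dietary-fiber range in grams per meal earning the
#'   in-range bonus (default 6-10 g).
#' @param trophy_thresholds Named numeric `c(silver = , gold = )` minimum
#'   saved-recipe counts for the engagement tiers.
#' @param nse_items,nse_range Item count and response range of the
#'   nutrition self-efficacy instrument (defaults: 5 items scored 1-4).
#' @param levene_center `"mean"` (classic Levene) or `"median"`
#'   (Brown-Forsythe) centering for the variance-homogeneity test.
#' @param headline_tail `"two"` or `"one"`: which p value report tables
#'   put first (both are always computed).
#' @param digits_t,digits_mean Printed precision of the report layer.
#'   Rounding is applied only when formatting, never internally.
#' @return A list of class `"engine_config"`.
#' @export
#' @examples
#' cfg <- engine_config(satfat_base = "fat")
#' cfg$sodium_cutoff_mg
engine_config <- function(hb_coefficients = c("original", "revised"),
                          satfat_base = c("rrc", "fat"),
                          satfat_limit = 0.07,
                          sodium_cutoff_mg = 450,
                          sodium_cutoff_htn_mg = 1500 / 3,
                          carb_range = c(0.45, 0.65),
                          fat_range = c(0.25, 0.35),
                          protein_range = c(0.15, 0.20),
                          fiber_range_g = c(6, 10),
                          trophy_thresholds = c(silver = 5, gold = 15),
                          nse_items = 5L,
                          nse_range = c(1L, 4L),
                          levene_center = c("mean", "median"),
                          headline_tail = c("two", "one"),
                          digits_t = 2L,
                          digits_mean = 2L) {
  hb_coefficients <- match.arg(hb_coefficients)
  satfat_base <- match.arg(satfat_base)
  levene_center <- match.arg(levene_center)
  headline_tail <- match.arg(headline_tail)
  check_range <- function(r, name) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
        r[1] < 0 || r[1] > r[2]) {
      stop(sprintf("'%s' must be an increasing non-negative pair", name),
           call. = FALSE)
    }
  }
  check_range(carb_range, "carb_range")
  check_range(fat_range, "fat_range")
  check_range(protein_range, "protein_range")
  check_range(fiber_range_g, "fiber_range_g")
  check_positive(satfat_limit, "satfat_limit")
  check_positive(sodium_cutoff_mg, "sodium_cutoff_mg")
  check_positive(sodium_cutoff_htn_mg, "sodium_cutoff_htn_mg")
  if (!all(c("silver", "gold") %in% names(trophy_thresholds)) ||
      trophy_thresholds[["silver"]] > trophy_thresholds[["gold"]]) {
    stop("'trophy_thresholds' needs silver <= gold entries", call. = FALSE)
  }
  check_count(nse_items, "nse_items")
  if (length(nse_range) != 2L || nse_range[1] >= nse_range[2]) {
    stop("'nse_range' must be an increasing pair", call. = FALSE)
  }
  structure(list(
    hb_coefficients = hb_coefficients,
    satfat_base = satfat_base,
    satfat_limit = satfat_limit,
    sodium_cutoff_mg = sodium_cutoff_mg,
    sodium_cutoff_htn_mg = sodium_cutoff_htn_mg,
    carb_range = carb_range,
    fat_range = fat_range,
    protein_range = protein_range,
    fiber_range_g = fiber_range_g,
    trophy_thresholds = trophy_thresholds,
    nse_items = as.integer(nse_items),
    nse_range = as.integer(nse_range),
    levene_center = levene_center,
    headline_tail = headline_tail,
    digits_t = as.integer(digits_t),
    digits_mean = as.integer(digits_mean)
  ), class = "engine_config")
}

#' Read an engine configuration from a key=value text file
#'
#' Lines are `key = value` (comments start with `#`); keys are the
#' arguments of [engine_config()]. Pair-valued keys take two
#' comma-separated numbers. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return An `"engine_config"` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed config line: '%s'", ln),
                               call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(engine_config))) {
      stop(sprintf("unknown config key: '%s'", key), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    args[[key]] <- if (any(is.na(num))) val else num
  }
  if (!is.null(args$trophy_thresholds)) {
    args$trophy_thresholds <- stats::setNames(args$trophy_thresholds,
                                              c("silver", "gold"))
  }
  do.call(engine_config, args)
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

# --- internal validation helpers ------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
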