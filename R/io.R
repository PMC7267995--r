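# Readers and writers for the recipe, study and summary schemas.
# CSV dialect is fixed: UTF-8, comma separator, dot decimal, header row.

.recipe_cols <- c("recipe_id", "name", "cuisine", "calories", "carbs_g",
                  "fat_g", "satfat_g", "protein_g", "sodium_mg", "fiber_g")
.recipe_num_cols <- setdiff(.recipe_cols, c("recipe_id", "name", "cuisine"))

.validate_recipes <- function(df, where = "recipes") {
  miss <- setdiff(.recipe_cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (cc in .recipe_num_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      stop(sprintf("%s: column '%s' is not numeric", where, cc),
           call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      stop(sprintf("%s: row %d, column '%s': missing or negative value",
                   where, bad[1], cc), call. = FALSE)
    }
  }
  bad <- which(df$satfat_g > df$fat_g)
  if (length(bad)) {
    stop(sprintf("%s: row %d: satfat_g exceeds fat_g", where, bad[1]),
         call. = FALSE)
  }
  df$recipe_id <- as.character(df$recipe_id)
  df$name <- as.character(df$name)
  df$cuisine <- as.character(df$cuisine)
  df[, .recipe_cols]
}

#' Read a recipe corpus
#'
#' Reads and validates the recipe schema
#' `recipe_id,name,cuisine,calories,carbs_g,fat_g,satfat_g,protein_g,sodium_mg,fiber_g`
#' from CSV or an equivalent JSON array of records. Validation errors
#' name the offending row and column.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return Data frame of validated recipes.
#' @export
read_recipes <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("recipe file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  df <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  miss <- setdiff(.recipe_cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("recipe file contains a header but no rows", call. = FALSE)
    return(df[, .recipe_cols])
  }
  .validate_recipes(df, where = basename(path))
}

#' Write a recipe corpus
#'
#' @param recipes Recipe data frame.
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"json"`.
#' @export
write_recipes <- function(recipes, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  recipes <- .validate_recipes(as.data.frame(recipes))
  if (format == "json") {
    jsonlite::write_json(recipes, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(recipes, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a per-subject study table
#'
#' Reads and validates the study schema
#' `subject_id,group,pre_hba1c,post_hba1c,pre_eh,post_eh,nse`: group
#' labels must be `intervention`/`control`, subject ids unique, all
#' outcome cells finite numbers.
#'
#' @param path CSV path.
#' @return Validated study data frame.
#' @export
read_study <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("study file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  .validate_study(df)
}

#' Write a per-subject study table
#'
#' @param data Study data frame.
#' @param path Output CSV path.
#' @export
write_study <- function(data, path) {
  data <- .validate_study(as.data.frame(data))
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read printed summary statistics
#'
#' Reads a JSON file of published group and paired summaries, e.g.
#' \preformatted{
#' {"groups": {"pre_eh": {"control": {"mean": 25.83, "sd": 5.27, "n": 12},
#'                        "intervention": {"mean": 23.33, "sd": 3.08, "n": 9}}},
#'  "paired": {"hba1c": {"intervention": {"mean_diff": 1.41,
#'                                        "sd_diff": 1.75, "n": 9}}}}
#' }
#' Group entries become [group_summary()] records and paired entries
#' [paired_summary()] records, ready for [analyze_summaries()].
#'
#' @param path JSON path.
#' @return List with `groups` and `paired` components.
#' @export
read_summaries <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("summaries file not found: %s", path), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(raw$groups, function(measure) {
    lapply(measure, function(g) group_summary(g$mean, g$sd, g$n))
  })
  paired <- lapply(raw$paired, function(outcome) {
    lapply(outcome, function(p) {
      paired_summary(p$mean_diff, p$sd_diff, p$n)
    })
  })
  list(groups = groups, paired = paired)
}

#' Path to the bundled printed-summary fixture
#'
#' The published group and paired summary statistics of the reference
#' two-group pre/post study (group means, SDs and sizes for eating
#' habits, HbA1c and nutrition self-efficacy; paired pre-minus-post
#' change summaries), as shipped in `inst/extdata`.
#'
#' @return File path.
#' @export
published_summaries_path <- function() {
  system.file("extdata", "printed_study_summaries.json",
              package = "nutrilight", mustWork = TRUE)
}
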