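#' Recognised food-group tags
#'
#' The controlled vocabulary of food-group tags used by the Breakfast Quality
#' Index: `cereal`, `fruit_or_vegetable`, `dairy`, `olive_oil`,
#' `butter_margarine`, `sugar_rich`, and `other`.
#'
#' @return Character vector of valid tags.
#' @export
food_group_tags <- function() {
  c("cereal", "fruit_or_vegetable", "dairy", "olive_oil",
    "butter_margarine", "sugar_rich", "other")
}

# columns every food-composition library must carry; units fixed per 100 g
food_library_columns <- function() {
  c("food_id", "name", "energy_kcal_per_100g", "carb_g", "simple_sugar_g",
    "fat_g", "mufa_g", "sfa_g", "protein_g", "calcium_mg_per_100g",
    "groups", "is_beverage", "is_energy_beverage")
}

#' Load and validate a food-composition library
#'
#' Reads a comma-delimited food-composition table with one row per food and
#' nutrient values expressed per 100 g of food. The `groups` column holds
#' semicolon-separated tags from [food_group_tags()]. Every row is checked
#' against the schema invariants: nonnegative nutrients, simple sugars not
#' exceeding total carbohydrate, MUFA + SFA not exceeding total fat, and the
#' energy-beverage flag only set on beverages with positive energy.
#'
#' @param path Path to a CSV file with the columns listed in the details.
#' @return A tibble of validated food entries with an additional `group_tags`
#'   list-column holding the parsed tags.
#' @seealso [demo_food_library()] for the packaged fixture library.
#' @export
load_food_library <- function(path) {
  lib <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_food_library(lib)
}

#' Packaged demonstration food library
#'
#' Returns the breakfast food library shipped with the package: roughly 35
#' foods (breads, biscuits, pastries, milks, yogurt, juices, fruit, olive
#' oil, butter, plus generic lunch/dinner foods) with hand-entered plausible
#' per-100 g nutrient values. It is a test and simulation fixture, not a
#' nutrition reference.
#'
#' @return A validated food-library tibble.
#' @export
demo_food_library <- function() {
  path <- system.file("extdata", "breakfast_food_library.csv",
                      package = "breakfastcmr", mustWork = TRUE)
  load_food_library(path)
}

#' Validate an in-memory food library
#'
#' Checks a data frame against the food-library schema and invariants, and
#' parses the `groups` tag column. Called by [load_food_library()]; exported
#' so programmatically built libraries go through the same checks.
#'
#' @param lib A data frame with the food-library columns.
#' @return The validated library as a tibble with a `group_tags` list-column.
#' @export
validate_food_library <- function(lib) {
  lib <- tibble::as_tibble(lib)
  missing <- setdiff(food_library_columns(), names(lib))
  if (length(missing) > 0) {
    stop("food library is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(lib$food_id)) {
    dup <- unique(lib$food_id[duplicated(lib$food_id)])
    stop("duplicated food_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }

  num_cols <- c("energy_kcal_per_100g", "carb_g", "simple_sugar_g", "fat_g",
                "mufa_g", "sfa_g", "protein_g", "calcium_mg_per_100g")
  for (col in num_cols) {
    bad <- which(!is.finite(lib[[col]]) | lib[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("food library row %d: column '%s' must be a nonnegative number",
                   bad[1], col), call. = FALSE)
    }
  }
  for (col in c("is_beverage", "is_energy_beverage")) {
    if (!is.logical(lib[[col]]) || anyNA(lib[[col]])) {
      stop(sprintf("food library column '%s' must be TRUE/FALSE with no missing values",
                   col), call. = FALSE)
    }
  }

  # per-row composition invariants (small tolerance for decimal rounding)
  tol <- 1e-9
  bad <- which(lib$simple_sugar_g > lib$carb_g + tol)
  if (length(bad) > 0) {
    stop(sprintf("food library row %d (%s): simple_sugar_g exceeds carb_g",
                 bad[1], lib$food_id[bad[1]]), call. = FALSE)
  }
  bad <- which(lib$mufa_g + lib$sfa_g > lib$fat_g + tol)
  if (length(bad) > 0) {
    stop(sprintf("food library row %d (%s): mufa_g + sfa_g exceeds fat_g",
                 bad[1], lib$food_id[bad[1]]), call. = FALSE)
  }
  bad <- which(lib$is_energy_beverage &
                 (!lib$is_beverage | lib$energy_kcal_per_100g <= 0))
  if (length(bad) > 0) {
    stop(sprintf(paste0("food library row %d (%s): is_energy_beverage requires ",
                        "is_beverage and positive energy"),
                 bad[1], lib$food_id[bad[1]]), call. = FALSE)
  }

  tags <- strsplit(as.character(lib$groups), ";", fixed = TRUE)
  tags <- lapply(tags, function(x) trimws(x[nzchar(trimws(x))]))
  for (i in seq_along(tags)) {
    unknown <- setdiff(tags[[i]], food_group_tags())
    if (length(unknown) > 0) {
      stop(sprintf("food library row %d (%s): unknown group tag '%s'",
                   i, lib$food_id[i], unknown[1]), call. = FALSE)
    }
  }
  lib$group_tags <- tags
  lib
}
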