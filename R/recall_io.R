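#' Recognised meal labels
#' @return Character vector of valid meal labels for recall records.
#' @export
meal_labels <- function() {
  c("breakfast", "mid_morning", "lunch", "snack", "dinner", "other")
}

#' Load 24-hour recall records
#'
#' Reads long-format recall lines: one row per food consumed, with columns
#' `participant_id`, `day_index` (1 or 2; two nonconsecutive weekday recalls),
#' `meal` (one of [meal_labels()]), `food_id`, and `grams` consumed.
#'
#' @param path Path to a CSV recall file.
#' @param library Optional food library; when given, every `food_id` must
#'   resolve in it.
#' @return A tibble of validated recall lines.
#' @export
load_recalls <- function(path, library = NULL) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_recalls(rec, library = library)
}

#' Validate in-memory recall lines
#'
#' @param rec Data frame of recall lines.
#' @inheritParams load_recalls
#' @return Validated tibble of recall lines.
#' @export
validate_recalls <- function(rec, library = NULL) {
  rec <- tibble::as_tibble(rec)
  required <- c("participant_id", "day_index", "meal", "food_id", "grams")
  missing <- setdiff(required, names(rec))
  if (length(missing) > 0) {
    stop("recall file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(rec$day_index %in% c(1L, 2L))) {
    stop("day_index must be 1 or 2", call. = FALSE)
  }
  bad_meal <- setdiff(unique(rec$meal), meal_labels())
  if (length(bad_meal) > 0) {
    stop("unknown meal label(s): ", paste(bad_meal, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(rec$grams) | rec$grams <= 0)
  if (length(bad) > 0) {
    stop(sprintf("recall row %d: grams must be > 0", bad[1]), call. = FALSE)
  }
  if (!is.null(library)) {
    unknown <- setdiff(unique(rec$food_id), library$food_id)
    if (length(unknown) > 0) {
      stop("recall food_id not in library: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  rec$day_index <- as.integer(rec$day_index)
  rec
}

# join recall lines against the library and scale per-100 g values by grams
resolve_lines <- function(lines, library) {
  unknown <- setdiff(unique(lines$food_id), library$food_id)
  if (length(unknown) > 0) {
    stop("cannot resolve food_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::inner_join(lines, library, by = "food_id")
  scale <- out$grams / 100
  dplyr::mutate(
    out,
    energy_kcal    = .data$energy_kcal_per_100g * scale,
    carb_g_amt     = .data$carb_g * scale,
    sugar_g_amt    = .data$simple_sugar_g * scale,
    fat_g_amt      = .data$fat_g * scale,
    mufa_g_amt     = .data$mufa_g * scale,
    sfa_g_amt      = .data$sfa_g * scale,
    protein_g_amt  = .data$protein_g * scale,
    calcium_mg_amt = .data$calcium_mg_per_100g * scale
  )
}

#' Resolve one participant-day of recall lines to nutrient intakes
#'
#' Maps each recall line to its food-library entry, scales the per-100 g
#' nutrient values by the grams consumed, and aggregates to a day-level
#' intake record with the breakfast meal kept separately for downstream
#' breakfast scoring. Breakfast is identified by the explicit `meal ==
#' "breakfast"` label; when no line carries it the day has no breakfast.
#'
#' @param lines Recall lines for a single participant and day.
#' @param library A validated food library.
#' @return A `day_intake` list: `participant_id`, `day_index`,
#'   `total_energy_kcal`, `foods` (all resolved lines), and `breakfast`
#'   (resolved breakfast lines, or `NULL` when the day has no breakfast).
#' @export
resolve_day <- function(lines, library) {
  lines <- tibble::as_tibble(lines)
  if (nrow(lines) == 0) stop("no recall lines supplied", call. = FALSE)
  if (length(unique(lines$participant_id)) != 1 ||
      length(unique(lines$day_index)) != 1) {
    stop("resolve_day expects lines from a single participant and day",
         call. = FALSE)
  }
  foods <- resolve_lines(lines, library)
  bf <- foods[foods$meal == "breakfast", , drop = FALSE]
  out <- list(
    participant_id    = lines$participant_id[1],
    day_index         = lines$day_index[1],
    total_energy_kcal = sum(foods$energy_kcal),
    foods             = foods,
    breakfast         = if (nrow(bf) > 0) bf else NULL
  )
  class(out) <- "day_intake"
  out
}

#' Summarise a breakfast record
#'
#' Aggregates resolved breakfast food lines into the totals the Breakfast
#' Quality Index and the energy-density measures consume. Foods are
#' partitioned into solids (everything that is not a beverage) and
#' energy-containing beverages; non-energy beverages such as water belong to
#' neither energy partition.
#'
#' @param breakfast Resolved breakfast lines (the `breakfast` element of a
#'   `day_intake`), or `NULL` for an absent breakfast.
#' @return A list of totals: energy, mass, calcium, MUFA/SFA grams,
#'   sugar-rich energy, the solid and energy-beverage mass/energy partitions,
#'   and logical presence flags per food group.
#' @export
breakfast_totals <- function(breakfast) {
  if (is.null(breakfast) || nrow(breakfast) == 0) {
    return(list(
      present = FALSE, energy_kcal = 0, mass_g = 0, calcium_mg = 0,
      mufa_g = 0, sfa_g = 0, sugar_rich_energy_kcal = 0,
      solid_mass_g = 0, solid_energy_kcal = 0,
      energy_beverage_mass_g = 0, energy_beverage_energy_kcal = 0,
      has_cereal = FALSE, has_fruit_or_vegetable = FALSE, has_dairy = FALSE,
      has_olive_oil = FALSE, has_butter_margarine = FALSE
    ))
  }
  has_tag <- function(tag) {
    any(vapply(breakfast$group_tags, function(tt) tag %in% tt, logical(1)))
  }
  sugar_rich <- vapply(breakfast$group_tags,
                       function(tt) "sugar_rich" %in% tt, logical(1))
  solid <- !breakfast$is_beverage
  ebev <- breakfast$is_energy_beverage
  list(
    present = TRUE,
    energy_kcal = sum(breakfast$energy_kcal),
    mass_g = sum(breakfast$grams),
    calcium_mg = sum(breakfast$calcium_mg_amt),
    mufa_g = sum(breakfast$mufa_g_amt),
    sfa_g = sum(breakfast$sfa_g_amt),
    sugar_rich_energy_kcal = sum(breakfast$energy_kcal[sugar_rich]),
    solid_mass_g = sum(breakfast$grams[solid]),
    solid_energy_kcal = sum(breakfast$energy_kcal[solid]),
    energy_beverage_mass_g = sum(breakfast$grams[ebev]),
    energy_beverage_energy_kcal = sum(breakfast$energy_kcal[ebev]),
    has_cereal = has_tag("cereal"),
    has_fruit_or_vegetable = has_tag("fruit_or_vegetable"),
    has_dairy = has_tag("dairy"),
    has_olive_oil = has_tag("olive_oil"),
    has_butter_margarine = has_tag("butter_margarine")
  )
}

#' Average two recall days
#'
#' Combines the two nonconsecutive recall days of one participant. Total
#' daily energy is always the arithmetic mean of both days. Breakfast-level
#' totals are averaged over the days on which a breakfast was consumed; when
#' breakfast appears on only one day its totals are carried through and a
#' partial flag is set.
#'
#' @param d1,d2 `day_intake` records for the same participant.
#' @return An `averaged_intake` list with `total_energy_kcal`,
#'   `breakfast_totals` (numeric totals averaged across breakfast days, or
#'   `NULL` when neither day has breakfast), `n_breakfast_days`, and
#'   `breakfast_partial`.
#' @export
average_days <- function(d1, d2) {
  stopifnot(inherits(d1, "day_intake"), inherits(d2, "day_intake"))
  if (!identical(d1$participant_id, d2$participant_id)) {
    stop("average_days: days belong to different participants", call. = FALSE)
  }
  t1 <- breakfast_totals(d1$breakfast)
  t2 <- breakfast_totals(d2$breakfast)
  present <- c(t1$present, t2$present)
  numeric_fields <- c("energy_kcal", "mass_g", "calcium_mg", "mufa_g",
                      "sfa_g", "sugar_rich_energy_kcal", "solid_mass_g",
                      "solid_energy_kcal", "energy_beverage_mass_g",
                      "energy_beverage_energy_kcal")
  bt <- NULL
  if (any(present)) {
    days <- list(t1, t2)[present]
    bt <- lapply(stats::setNames(numeric_fields, numeric_fields), function(f) {
      mean(vapply(days, `[[`, numeric(1), f))
    })
  }
  out <- list(
    participant_id    = d1$participant_id,
    total_energy_kcal = mean(c(d1$total_energy_kcal, d2$total_energy_kcal)),
    breakfast_totals  = bt,
    n_breakfast_days  = sum(present),
    breakfast_partial = sum(present) == 1
  )
  class(out) <- "averaged_intake"
  out
}

#' Apply the recall-completeness exclusion rule
#'
#' Participants contribute to the analysis only with two complete, resolvable
#' recall days. Participants with a single recall day, no recall data at all,
#' or food codes that cannot be resolved in the library are excluded, and the
#' reason is logged per participant.
#'
#' @param recalls Recall lines for any number of participants.
#' @param library Optional food library used to check food-code resolvability.
#' @param participant_ids Optional roster; defaults to the participants seen
#'   in `recalls`. Roster members without any recall line are excluded with
#'   reason `"no recall data"`.
#' @return A list with `retained` (character vector of participant ids) and
#'   `log` (tibble of `participant_id`, `reason` for each exclusion).
#' @export
apply_exclusions <- function(recalls, library = NULL, participant_ids = NULL) {
  recalls <- tibble::as_tibble(recalls)
  if (is.null(participant_ids)) {
    participant_ids <- unique(recalls$participant_id)
  }
  resolvable <- if (is.null(library)) {
    rep(TRUE, nrow(recalls))
  } else {
    recalls$food_id %in% library$food_id
  }
  status <- vapply(participant_ids, function(pid) {
    rows <- recalls$participant_id == pid
    if (!any(rows)) return("no recall data")
    days <- unique(recalls$day_index[rows])
    ok_days <- vapply(days, function(d) {
      all(resolvable[rows & recalls$day_index == d])
    }, logical(1))
    if (any(!ok_days)) return("incomplete dietary data")
    if (sum(ok_days) < 2) return("single recall")
    "retained"
  }, character(1))
  list(
    retained = participant_ids[status == "retained"],
    log = tibble::tibble(
      participant_id = participant_ids[status != "retained"],
      reason = unname(status[status != "retained"])
    )
  )
}
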