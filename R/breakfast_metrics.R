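#' Score the 10-item Breakfast Quality Index
#'
#' Evaluates the ten Mediterranean-pattern breakfast criteria against one
#' breakfast record and the participant's total daily energy intake. One
#' point is scored per criterion met; the total ranges from 0 (poorest) to
#' 10 (optimal breakfast quality). The criteria are:
#'
#' i. any cereal or derivative consumed;
#' ii. any fruit or vegetable;
#' iii. any dairy product;
#' iv. energy from sugar-rich foods at breakfast below 5% of total daily
#'     energy;
#' v. olive oil consumed;
#' vi. MUFA/SFA ratio of at least 2 (met with zero SFA only when MUFA is
#'     positive);
#' vii. breakfast supplies 20--25% of total daily energy (inclusive band);
#' viii. cereal, fruit/vegetable and dairy all present in the same meal;
#' ix. breakfast calcium of at least `calcium_threshold_mg` (default 200 mg,
#'     the lower end of the recommended 200--300 mg range);
#' x. no butter or margarine consumed.
#'
#' An absent breakfast scores 0 with every item false.
#'
#' @param breakfast Resolved breakfast lines (the `breakfast` element of a
#'   [resolve_day()] result) or `NULL` for an absent breakfast.
#' @param daily_energy_kcal Total daily energy intake (kcal), > 0.
#' @param calcium_threshold_mg Calcium criterion threshold in mg.
#' @return A `bqi_result` list: `items` (named logical vector `i`..`x`),
#'   `score` (integer 0--10), and `inputs` (the breakfast totals used).
#' @export
score_bqi <- function(breakfast, daily_energy_kcal,
                      calcium_threshold_mg = 200) {
  if (!is.finite(daily_energy_kcal) || daily_energy_kcal <= 0) {
    stop("daily_energy_kcal must be positive", call. = FALSE)
  }
  bt <- breakfast_totals(breakfast)
  if (!bt$present) {
    items <- stats::setNames(rep(FALSE, 10), bqi_item_names())
  } else {
    frac <- bt$energy_kcal / daily_energy_kcal
    ratio_ok <- if (bt$sfa_g > 0) {
      bt$mufa_g / bt$sfa_g >= 2
    } else {
      bt$mufa_g > 0
    }
    items <- c(
      i    = bt$has_cereal,
      ii   = bt$has_fruit_or_vegetable,
      iii  = bt$has_dairy,
      iv   = bt$sugar_rich_energy_kcal < 0.05 * daily_energy_kcal,
      v    = bt$has_olive_oil,
      vi   = ratio_ok,
      vii  = frac >= 0.20 && frac <= 0.25,
      viii = bt$has_cereal && bt$has_fruit_or_vegetable && bt$has_dairy,
      ix   = bt$calcium_mg >= calcium_threshold_mg,
      x    = !bt$has_butter_margarine
    )
  }
  out <- list(items = items, score = as.integer(sum(items)), inputs = bt)
  class(out) <- "bqi_result"
  out
}

bqi_item_names <- function() {
  c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x")
}

#' @export
print.bqi_result <- function(x, ...) {
  cat("Breakfast Quality Index:", x$score, "/ 10\n")
  cat("items met:", paste(names(x$items)[x$items], collapse = " "), "\n")
  invisible(x)
}

#' Breakfast energy density from solids and from beverages
#'
#' Energy density is energy consumed (kcal) divided by mass consumed (g).
#' BEDs is computed over solid foods only, excluding all beverages; BEDb is
#' computed over energy-containing beverages only (soft drinks, milk,
#' smoothies, shakes, juices). Non-energy beverages such as water enter
#' neither denominator. A density is `NA` when its mass denominator is zero.
#'
#' @inheritParams score_bqi
#' @return A list with `beds_kcal_per_g` and `bedb_kcal_per_g`.
#' @export
compute_energy_density <- function(breakfast) {
  bt <- breakfast_totals(breakfast)
  list(
    beds_kcal_per_g = if (bt$solid_mass_g > 0) {
      bt$solid_energy_kcal / bt$solid_mass_g
    } else NA_real_,
    bedb_kcal_per_g = if (bt$energy_beverage_mass_g > 0) {
      bt$energy_beverage_energy_kcal / bt$energy_beverage_mass_g
    } else NA_real_
  )
}

#' Classify breakfast skipping
#'
#' Two definitions are carried side by side: a recall-based one — skipper
#' when no breakfast was recorded on either of the two recall days (a child
#' consuming breakfast on one recorded day may still be a habitual skipper,
#' so single-day absence is not counted) — and the breakfast-skipping item
#' of the KIDMED questionnaire, echoed as reported.
#'
#' @param d1,d2 `day_intake` records for the same participant.
#' @param kidmed_item `TRUE`/`FALSE`/`NA`: the questionnaire skipping item.
#' @return A list with `by_recall` (logical) and `by_kidmed` (logical, `NA`
#'   when the questionnaire item is absent).
#' @export
classify_skipping <- function(d1, d2, kidmed_item = NA) {
  stopifnot(inherits(d1, "day_intake"), inherits(d2, "day_intake"))
  list(
    by_recall = is.null(d1$breakfast) && is.null(d2$breakfast),
    by_kidmed = as.logical(kidmed_item)
  )
}

#' Score a whole cohort from recall data
#'
#' Runs the full breakfast-metrics pipeline: applies the two-complete-recall
#' exclusion rule, resolves each retained participant-day, scores the BQI and
#' energy densities per day, and averages the per-day metric values across
#' the days on which breakfast was consumed. Total daily energy is the mean
#' over both recall days. Participants who had no breakfast on either day
#' receive a BQI of 0 with all items unmet and missing energy densities.
#'
#' @param recalls Validated recall lines (see [load_recalls()]).
#' @param library A validated food library.
#' @param kidmed Optional tibble with columns `participant_id`,
#'   `kidmed_skip` supplying the questionnaire skipping item.
#' @param calcium_threshold_mg Passed to [score_bqi()].
#' @return A list with `scores` — a per-participant tibble of
#'   `bqi_score` (mean of per-day scores over breakfast days), per-item
#'   fractions `item_i`..`item_x`, `beds`, `bedb`, `breakfast_energy_kcal`,
#'   `energy_kcal_day`, `n_breakfast_days`, `breakfast_partial`,
#'   `skip_recall`, `skip_kidmed` — and `exclusions`, the exclusion log.
#' @export
score_cohort <- function(recalls, library, kidmed = NULL,
                         calcium_threshold_mg = 200) {
  recalls <- validate_recalls(recalls, library = library)
  excl <- apply_exclusions(recalls, library = library)
  keep <- recalls[recalls$participant_id %in% excl$retained, , drop = FALSE]

  # vectorized scoring over all participant-days at once; agrees with the
  # single-record path (resolve_day + score_bqi), which is property-tested
  lib <- library
  for (tag in food_group_tags()) {
    lib[[paste0("tag_", tag)]] <-
      vapply(lib$group_tags, function(tt) tag %in% tt, logical(1))
  }
  res <- dplyr::inner_join(keep, lib, by = "food_id")
  sc <- res$grams / 100
  energy  <- res$energy_kcal_per_100g * sc
  calcium <- res$calcium_mg_per_100g * sc
  mufa    <- res$mufa_g * sc
  sfa     <- res$sfa_g * sc

  key <- paste(res$participant_id, res$day_index, sep = "\r")
  day_energy <- rowsum(energy, key)
  day_keys <- rownames(day_energy)

  b <- res$meal == "breakfast"
  solid <- !res$is_beverage
  ebev <- res$is_energy_beverage
  bm <- rowsum(cbind(
    energy     = energy[b],
    calcium    = calcium[b],
    mufa       = mufa[b],
    sfa        = sfa[b],
    sugar_e    = energy[b] * res$tag_sugar_rich[b],
    solid_mass = res$grams[b] * solid[b],
    solid_e    = energy[b] * solid[b],
    ebev_mass  = res$grams[b] * ebev[b],
    ebev_e     = energy[b] * ebev[b],
    n_cereal   = as.numeric(res$tag_cereal[b]),
    n_fv       = as.numeric(res$tag_fruit_or_vegetable[b]),
    n_dairy    = as.numeric(res$tag_dairy[b]),
    n_oil      = as.numeric(res$tag_olive_oil[b]),
    n_bm       = as.numeric(res$tag_butter_margarine[b])
  ), key[b])
  idx <- match(day_keys, rownames(bm))
  present <- !is.na(idx)
  g <- function(col) ifelse(present, bm[idx, col], NA_real_)

  day_total <- day_energy[, 1]
  frac <- g("energy") / day_total
  items <- cbind(
    i    = g("n_cereal") > 0,
    ii   = g("n_fv") > 0,
    iii  = g("n_dairy") > 0,
    iv   = g("sugar_e") < 0.05 * day_total,
    v    = g("n_oil") > 0,
    vi   = ifelse(g("sfa") > 0, g("mufa") / g("sfa") >= 2, g("mufa") > 0),
    vii  = frac >= 0.20 & frac <= 0.25,
    viii = g("n_cereal") > 0 & g("n_fv") > 0 & g("n_dairy") > 0,
    ix   = g("calcium") >= calcium_threshold_mg,
    x    = !(g("n_bm") > 0)
  )
  day_score <- rowSums(items)
  beds_day <- ifelse(present & g("solid_mass") > 0,
                     g("solid_e") / g("solid_mass"), NA_real_)
  bedb_day <- ifelse(present & g("ebev_mass") > 0,
                     g("ebev_e") / g("ebev_mass"), NA_real_)

  # collapse the per-day rows to one row per participant: metric values are
  # averaged over the days on which breakfast was consumed
  day_pid <- sub("\r.*$", "", day_keys)
  n_days <- rowsum(rep(1, length(day_pid)), day_pid)[, 1]
  n_present <- rowsum(as.numeric(present), day_pid)[, 1]
  sum_present <- function(x) rowsum(ifelse(present & !is.na(x), x, 0), day_pid)[, 1]
  n_nonmiss <- function(x) rowsum(as.numeric(present & !is.na(x)), day_pid)[, 1]
  mean_present <- function(x) {
    k <- n_nonmiss(x)
    ifelse(k > 0, sum_present(x) / k, NA_real_)
  }
  items0 <- items * 1          # logical -> numeric; rows of absent days are NA
  items0[is.na(items0)] <- 0
  item_frac <- rowsum(items0, day_pid) / pmax(n_present, 1)

  scores <- tibble::tibble(
    participant_id = sort(unique(day_pid)),
    bqi_score = unname(ifelse(n_present > 0,
                              sum_present(day_score) / pmax(n_present, 1), 0)),
    beds = unname(mean_present(beds_day)),
    bedb = unname(mean_present(bedb_day)),
    breakfast_energy_kcal = unname(
      ifelse(n_present > 0, sum_present(g("energy")) / pmax(n_present, 1), 0)),
    energy_kcal_day = unname(rowsum(day_total, day_pid)[, 1] / n_days),
    n_breakfast_days = as.integer(unname(n_present)),
    breakfast_partial = unname(n_present == 1),
    skip_recall = unname(n_present == 0)
  )
  colnames(item_frac) <- paste0("item_", bqi_item_names())
  scores <- dplyr::bind_cols(scores, tibble::as_tibble(item_frac))

  if (!is.null(kidmed)) {
    scores <- dplyr::left_join(
      scores,
      dplyr::select(tibble::as_tibble(kidmed), "participant_id",
                    skip_kidmed = "kidmed_skip"),
      by = "participant_id"
    )
  } else {
    scores$skip_kidmed <- NA
  }
  list(scores = scores, exclusions = excl$log)
}
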