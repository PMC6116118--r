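lib <- mini_library()

bf_of <- function(lines) resolve_day(lines, lib)$breakfast

test_that("a breakfast meeting every criterion scores the maximum of 10", {
  res <- score_bqi(bf_of(perfect_breakfast_lines()), 2000)
  expect_equal(res$score, 10L)
  expect_true(all(res$items))
})

test_that("an absent breakfast scores 0 with every item unmet", {
  res <- score_bqi(NULL, 2000)
  expect_equal(res$score, 0L)
  expect_false(any(res$items))
  expect_error(score_bqi(bf_of(perfect_breakfast_lines()), 0),
               "daily_energy_kcal")
})

test_that("a panel of hand-scored breakfasts matches item by item", {
  panel <- list(
    # all ten criteria met
    list(lines = perfect_breakfast_lines(), daily = 2000,
         items = c(i = TRUE, ii = TRUE, iii = TRUE, iv = TRUE, v = TRUE,
                   vi = TRUE, vii = TRUE, viii = TRUE, ix = TRUE, x = TRUE)),
    # butter on sweet bread, 40% of daily energy: every criterion fails
    list(lines = worst_breakfast_lines(), daily = 2000,
         items = c(i = FALSE, ii = FALSE, iii = FALSE, iv = FALSE, v = FALSE,
                   vi = FALSE, vii = FALSE, viii = FALSE, ix = FALSE,
                   x = FALSE)),
    # sugary biscuits (60 g, 261.6 kcal) + whole milk (200 g, 110 kcal) +
    # butter (10 g, 80 kcal): 451.6 kcal of a 1505.3 kcal day = 30%;
    # sugar-rich 261.6 kcal = 17% of daily; MUFA 6.3, SFA 10.3 (ratio 0.61);
    # calcium 15 + 200 + 1.6 = 216.6 mg -> only cereal, dairy, calcium met
    list(lines = recall_lines("P3", 1, "breakfast",
                              c("biscuit", "milk", "butter"), c(60, 200, 10)),
         daily = 451.6 / 0.30,
         items = c(i = TRUE, ii = FALSE, iii = TRUE, iv = FALSE, v = FALSE,
                   vi = FALSE, vii = FALSE, viii = FALSE, ix = TRUE,
                   x = FALSE)),
    # olive-oil oat porridge and apple but no dairy: oat 100 g + apple 100 g
    # + oil 10 g = 280.4 kcal of a 1200 kcal day = 23.4%; calcium 50 mg;
    # MUFA 10.3 / SFA 2.46 = 4.2; no sugar-rich food
    list(lines = recall_lines("P4", 1, "breakfast",
                              c("oat", "apple", "oil"), c(100, 100, 10)),
         daily = 1200,
         items = c(i = TRUE, ii = TRUE, iii = FALSE, iv = TRUE, v = TRUE,
                   vi = TRUE, vii = TRUE, viii = FALSE, ix = FALSE,
                   x = TRUE)),
    # milk and yogurt only: 110 + 60 = 170 kcal of 2000 (8.5%), calcium
    # 200 + 120 = 320 mg, MUFA 2.4 / SFA 4 = 0.6
    list(lines = recall_lines("P5", 1, "breakfast",
                              c("milk", "yogurt"), c(200, 100)),
         daily = 2000,
         items = c(i = FALSE, ii = FALSE, iii = TRUE, iv = TRUE, v = FALSE,
                   vi = FALSE, vii = FALSE, viii = FALSE, ix = TRUE,
                   x = TRUE)),
    # wafer-only breakfast exactly on the 5% sugar boundary fails item iv
    # (strict <): 30 g wafer = 60 kcal of a 1200 kcal day; MUFA/SFA = 1;
    # only the no-butter criterion is met
    list(lines = recall_lines("P6", 1, "breakfast", "wafer", 30),
         daily = 1200,
         items = c(i = FALSE, ii = FALSE, iii = FALSE, iv = FALSE, v = FALSE,
                   vi = FALSE, vii = FALSE, viii = FALSE, ix = FALSE,
                   x = TRUE))
  )
  for (k in seq_along(panel)) {
    res <- score_bqi(bf_of(panel[[k]]$lines), panel[[k]]$daily)
    expect_equal(res$items, panel[[k]]$items, info = paste("fixture", k))
    expect_equal(res$score, sum(panel[[k]]$items), info = paste("fixture", k))
  }
})

test_that("the score is an integer in [0, 10] and item viii implies i-iii", {
  set.seed(202)
  for (rep in 1:50) {
    bf <- bf_of(random_breakfast(lib))
    res <- score_bqi(bf, runif(1, 1200, 2800))
    expect_true(res$score %in% 0:10)
    expect_equal(res$score, sum(res$items))
    if (res$items[["viii"]]) {
      expect_true(all(res$items[c("i", "ii", "iii")]))
    }
  }
})

test_that("adding butter can only lower the score; adding dairy only raise it", {
  # zero-energy tagged tokens isolate the group-membership criteria from
  # the energy-fraction ones
  token <- function(id, tags) tibble::tibble(
    food_id = id, name = id, energy_kcal_per_100g = 0, carb_g = 0,
    simple_sugar_g = 0, fat_g = 0, mufa_g = 0, sfa_g = 0, protein_g = 0,
    calcium_mg_per_100g = 0, groups = tags, is_beverage = FALSE,
    is_energy_beverage = FALSE)
  lib2 <- validate_food_library(dplyr::bind_rows(
    dplyr::select(lib, -"group_tags"),
    token("butter_token", "butter_margarine"),
    token("dairy_token", "dairy")))
  set.seed(203)
  for (rep in 1:20) {
    lines <- random_breakfast(lib)
    daily <- runif(1, 1200, 2800)
    base <- score_bqi(resolve_day(lines, lib2)$breakfast, daily)$score
    plus_butter <- dplyr::bind_rows(
      lines, recall_lines("R1", 1, "breakfast", "butter_token", 10))
    plus_dairy <- dplyr::bind_rows(
      lines, recall_lines("R1", 1, "breakfast", "dairy_token", 10))
    expect_lte(score_bqi(resolve_day(plus_butter, lib2)$breakfast, daily)$score,
               base)
    expect_gte(score_bqi(resolve_day(plus_dairy, lib2)$breakfast, daily)$score,
               base)
  }
})

test_that("energy densities follow their printed definitions", {
  # 80 g of wafer solids at 200 kcal/100 g: 160 kcal -> 2 kcal/g
  ed <- compute_energy_density(bf_of(
    recall_lines("P1", 1, "breakfast", "wafer", 80)))
  expect_equal(ed$beds_kcal_per_g, 2)
  expect_true(is.na(ed$bedb_kcal_per_g))

  # 250 g milk (137.5 kcal) plus 100 g water: water is excluded from the
  # beverage denominator -> 0.55 kcal/g
  ed <- compute_energy_density(bf_of(
    recall_lines("P1", 1, "breakfast", c("milk", "water"), c(250, 100))))
  expect_equal(ed$bedb_kcal_per_g, 0.55)
  expect_true(is.na(ed$beds_kcal_per_g))

  # recording oiled toast as two solid lines or one combined line gives the
  # same solids density
  two <- compute_energy_density(bf_of(
    recall_lines("P1", 1, "breakfast", c("oat", "oil"), c(90, 10))))
  one_lib <- validate_food_library(dplyr::bind_rows(
    dplyr::select(lib, -"group_tags"),
    tibble::tibble(food_id = "oat_oil", name = "Oat with oil",
                   energy_kcal_per_100g = (140 * 0.9 + 884 * 0.1),
                   carb_g = 18, simple_sugar_g = 0.9, fat_g = 14.5,
                   mufa_g = 10, sfa_g = 2.36, protein_g = 4.5,
                   calcium_mg_per_100g = 36, groups = "cereal;olive_oil",
                   is_beverage = FALSE, is_energy_beverage = FALSE)))
  one <- compute_energy_density(
    resolve_day(recall_lines("P1", 1, "breakfast", "oat_oil", 100),
                one_lib)$breakfast)
  expect_equal(two$beds_kcal_per_g, one$beds_kcal_per_g)
})

test_that("densities are invariant to mass scaling and to the other partition", {
  set.seed(204)
  for (rep in 1:10) {
    lines <- random_breakfast(lib)
    base <- compute_energy_density(bf_of(lines))
    # multiplying all masses by k changes neither density
    k <- runif(1, 0.3, 4)
    scaled <- lines; scaled$grams <- scaled$grams * k
    sc <- compute_energy_density(bf_of(scaled))
    expect_equal(sc$beds_kcal_per_g, base$beds_kcal_per_g)
    expect_equal(sc$bedb_kcal_per_g, base$bedb_kcal_per_g)
    # adding a beverage leaves BEDs unchanged; adding a solid or water
    # leaves BEDb unchanged
    plus_bev <- dplyr::bind_rows(lines,
                                 recall_lines("R1", 1, "breakfast", "milk", 150))
    expect_equal(compute_energy_density(bf_of(plus_bev))$beds_kcal_per_g,
                 base$beds_kcal_per_g)
    plus_solid <- dplyr::bind_rows(
      lines, recall_lines("R1", 1, "breakfast", c("rice", "water"), c(50, 100)))
    expect_equal(compute_energy_density(bf_of(plus_solid))$bedb_kcal_per_g,
                 base$bedb_kcal_per_g)
  }
})

test_that("recall-based skipping requires breakfast absent on both days", {
  with_bf <- resolve_day(dplyr::bind_rows(
    perfect_breakfast_lines(),
    recall_lines("P1", 1, "lunch", "rice", 100)), lib)
  no_bf_1 <- resolve_day(recall_lines("P1", 1, "lunch", "rice", 100), lib)
  no_bf_2 <- resolve_day(recall_lines("P1", 2, "lunch", "rice", 100), lib)

  expect_true(classify_skipping(no_bf_1, no_bf_2)$by_recall)
  expect_false(classify_skipping(with_bf, no_bf_2)$by_recall)
  s <- classify_skipping(with_bf, no_bf_2, kidmed_item = NA)
  expect_true(is.na(s$by_kidmed))
  expect_false(s$by_recall)
  expect_true(classify_skipping(no_bf_1, no_bf_2, kidmed_item = TRUE)$by_kidmed)
})

test_that("cohort scoring agrees with the single-record operations", {
  sim <- generate_cohort(cohort_config(n_children = 40, seed = 99,
                                       p_single_recall = 0.1))
  dlib <- sim$library
  for (pid in sim$scores$participant_id[seq(1, nrow(sim$scores), by = 3)]) {
    p <- sim$recalls[sim$recalls$participant_id == pid, ]
    d1 <- resolve_day(p[p$day_index == 1, ], dlib)
    d2 <- resolve_day(p[p$day_index == 2, ], dlib)
    s1 <- score_bqi(d1$breakfast, d1$total_energy_kcal)
    s2 <- score_bqi(d2$breakfast, d2$total_energy_kcal)
    e1 <- compute_energy_density(d1$breakfast)
    e2 <- compute_energy_density(d2$breakfast)
    pres <- c(!is.null(d1$breakfast), !is.null(d2$breakfast))
    row <- sim$scores[sim$scores$participant_id == pid, ]
    exp_score <- if (any(pres)) mean(c(s1$score, s2$score)[pres]) else 0
    expect_equal(row$bqi_score, exp_score)
    expect_equal(row$energy_kcal_day,
                 mean(c(d1$total_energy_kcal, d2$total_energy_kcal)))
    bedb_vals <- c(e1$bedb_kcal_per_g, e2$bedb_kcal_per_g)[pres]
    exp_bedb <- if (length(bedb_vals) == 0 || all(is.na(bedb_vals))) {
      NA_real_
    } else mean(bedb_vals, na.rm = TRUE)
    expect_equal(row$bedb, exp_bedb)
    expect_equal(row$skip_recall, !any(pres))
  }
})
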