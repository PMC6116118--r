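# Hand-entered mini food library with round per-100 g values, so every
# expected aggregate below can be verified with pencil-and-paper arithmetic.
mini_library <- function() {
  validate_food_library(tibble::tribble(
    ~food_id, ~name, ~energy_kcal_per_100g, ~carb_g, ~simple_sugar_g,
    ~fat_g, ~mufa_g, ~sfa_g, ~protein_g, ~calcium_mg_per_100g,
    ~groups, ~is_beverage, ~is_energy_beverage,
    "oat",    "Oat porridge",   140, 20, 1,  5,   3,    1,   5, 40,
    "cereal", FALSE, FALSE,
    "milk",   "Milk",            55,  5, 5,  3,   0.8,  1,   3, 100,
    "dairy", TRUE, TRUE,
    "apple",  "Apple",           52, 14, 10, 0,   0,    0,   0, 10,
    "fruit_or_vegetable", FALSE, FALSE,
    "oil",    "Olive oil",      884,  0, 0,  100, 73,   14.6, 0, 0,
    "olive_oil", FALSE, FALSE,
    "wafer",  "Sugar wafer",    200, 30, 20, 5,   1.6,  1.6, 2, 0,
    "sugar_rich", FALSE, FALSE,
    "sweetbread", "Sweet white bread", 400, 60, 30, 8, 0.667, 1, 8, 4,
    "sugar_rich", FALSE, FALSE,
    "butter", "Butter",         800,  0, 0,  90,  20,   50,  1, 16,
    "butter_margarine", FALSE, FALSE,
    "biscuit", "Sugary biscuit", 436, 75, 22, 12, 4.5,  5.5, 7, 25,
    "cereal;sugar_rich", FALSE, FALSE,
    "water",  "Water",            0,  0, 0,  0,   0,    0,   0, 0,
    "other", TRUE, FALSE,
    "yogurt", "Plain yogurt",    60,  5, 5,  3,   0.8,  2,   4, 120,
    "dairy", FALSE, FALSE,
    "rice",   "Cooked rice",    130, 28, 0,  0.3, 0.1,  0.1, 2.7, 10,
    "other", FALSE, FALSE
  ))
}

recall_lines <- function(pid, day, meal, food_id, grams) {
  tibble::tibble(participant_id = pid, day_index = as.integer(day),
                 meal = meal, food_id = food_id, grams = grams)
}

# breakfast meeting all ten index criteria, eaten within a 2000 kcal day:
# oat 100 g (140 kcal) + milk 200 g (110) + apple 100 g (52) + oil 10 g
# (88.4) + wafer 30 g (60) = 450.4 kcal = 22.5% of 2000; sugar-rich energy
# 60 kcal = 3%; calcium 40 + 200 + 10 = 250 mg; MUFA 3 + 1.6 + 7.3 + 0.48
# = 12.38 g, SFA 1 + 2 + 1.46 + 0.48 = 4.94 g, ratio 2.51
perfect_breakfast_lines <- function(pid = "P1", day = 1) {
  recall_lines(pid, day, "breakfast",
               c("oat", "milk", "apple", "oil", "wafer"),
               c(100, 200, 100, 10, 30))
}

# breakfast failing all ten criteria: butter on sweet white bread, 800 kcal
# of a 2000 kcal day (40%), sugar-rich energy 600 kcal (30%), calcium 10 mg,
# MUFA/SFA = (1 + 5)/(1.5 + 12.5) = 0.43
worst_breakfast_lines <- function(pid = "P1", day = 1) {
  recall_lines(pid, day, "breakfast",
               c("sweetbread", "butter"), c(150, 25))
}

# random but syntactically valid breakfast baskets for property tests
random_breakfast <- function(lib, n_foods = NULL) {
  ids <- setdiff(lib$food_id, "water")
  if (is.null(n_foods)) n_foods <- sample(1:5, 1)
  pick <- sample(ids, n_foods)
  recall_lines("R1", 1, "breakfast", pick,
               round(stats::runif(n_foods, 5, 300), 1))
}

# minimal regression-ready table built directly (no generator) for
# association unit tests
toy_analysis_table <- function(n = 60, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    participant_id = sprintf("T%03d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    center = sample(c("vitoria", "granada"), n, replace = TRUE),
    age_year = runif(n, 8, 12),
    maternal_ed_high = runif(n) < 0.3,
    puberty_high = runif(n) < 0.25,
    energy_kcal_day = rnorm(n, 1850, 200),
    fmi = rnorm(n, 10.7, 2.5),
    total_pa_enmo = rnorm(n, 63, 15),
    bqi_score = runif(n, 0, 10),
    uric_acid = rnorm(n, 4.7, 0.9)
  )
}
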