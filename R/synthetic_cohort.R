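#' Synthetic pediatric metabolic-syndrome reference (toy)
#'
#' A synthetic stand-in for the external pediatric reference tables needed
#' by [compute_mets_z()] and [classify_mets()]: sex- and age-specific means
#' and SDs of the five syndrome components with mild age trends, and
#' sex/age 90th-percentile waist cutoffs. Values are plausible for Spanish
#' schoolchildren of all BMI categories but are fabricated; they support
#' simulation and testing, not clinical use.
#'
#' @return A [mets_reference()] covering both sexes, ages 8--12.
#' @export
synthetic_mets_reference <- function() {
  grid <- expand.grid(sex = c("male", "female"), age_year = 8:12,
                      stringsAsFactors = FALSE)
  comp <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    sex <- grid$sex[i]; age <- grid$age_year[i]
    boy <- as.numeric(sex == "male")
    tibble::tibble(
      sex = sex, age_year = age,
      component = mets_components(),
      mean = c(85 + 2.0 * (age - 10),            # triglycerides mg/dL
               51.5 - 0.3 * (age - 10) + 1.5 * boy,  # hdl mg/dL
               85 + 0.4 * (age - 10) + 0.8 * boy,    # glucose mg/dL
               103 + 1.5 * (age - 10) + 2 * boy,     # sbp mmHg
               64 + 0.8 * (age - 10) + 1 * boy),     # dbp mmHg
      sd = c(40, 11.5, 6, 11, 9)
    )
  }))
  waist <- dplyr::mutate(
    tibble::as_tibble(grid),
    waist_p90 = ifelse(.data$sex == "male",
                       70 + 3.0 * (.data$age_year - 8),
                       68 + 2.8 * (.data$age_year - 8))
  )
  mets_reference(comp, waist)
}

# which simulated channels an effect may target, and their marginal scales
outcome_channels <- function() {
  tibble::tribble(
    ~channel,             ~scale,      ~par1,   ~par2,
    "uric_acid",          "normal",    4.7,     0.9,
    "total_chol",         "normal",    170.3,   30.6,
    "hdl",                "normal",    51.1,    11.6,
    "ldl",                "normal",    102.8,   24.9,
    "sbp",                "normal",    105.2,   15.0,
    "dbp",                "normal",    65.4,    9.8,
    "log_triglycerides",  "lognormal", 4.364,   0.519,
    "log_homa",           "lognormal", 2.377,   0.600,
    "log_ggt",            "lognormal", 2.770,   0.339
  )
}

#' Default confounder strengths of the outcome generator
#'
#' Standardized per-outcome effects of age, sex, fat mass index and total
#' physical activity used when simulating biomarkers; modest values chosen
#' to mimic the confounding structure a pediatric overweight/obesity cohort
#' exhibits.
#'
#' @return Named list of named numeric vectors.
#' @export
default_confounder_strengths <- function() {
  list(
    uric_acid         = c(sex = -0.15, fmi = 0.30, pa = -0.15, age = 0.10),
    total_chol        = c(fmi = 0.10),
    hdl               = c(fmi = -0.20, pa = 0.15),
    ldl               = c(fmi = 0.10),
    sbp               = c(age = 0.20, fmi = 0.25),
    dbp               = c(age = 0.15, fmi = 0.15),
    log_triglycerides = c(fmi = 0.20, pa = -0.10),
    log_homa          = c(fmi = 0.35, pa = -0.20, age = 0.10),
    log_ggt           = c(fmi = 0.20)
  )
}

#' Default breakfast composition profile of the generator
#'
#' Per-day inclusion probability and gram range for each breakfast food,
#' weighted towards the milk-with-cocoa / biscuit / sugary-cereal pattern
#' typical of Spanish schoolchildren, with olive-oil toast and fruit in a
#' minority.
#'
#' @return Tibble with columns `food_id`, `prob`, `gmin`, `gmax`.
#' @export
default_breakfast_profile <- function() {
  tibble::tribble(
    ~food_id,             ~prob, ~gmin, ~gmax,
    "milk_with_cocoa",     0.40,   150,   250,
    "whole_milk",          0.25,   150,   250,
    "semiskimmed_milk",    0.10,   150,   250,
    "maria_biscuits",      0.35,    20,    60,
    "sugary_breakfast_cereal", 0.22, 20,   50,
    "white_bread",         0.25,    30,    80,
    "wholegrain_bread",    0.08,    30,    80,
    "olive_oil",           0.15,     5,    15,
    "butter",              0.07,     5,    15,
    "strawberry_jam",      0.08,    10,    25,
    "croissant",           0.10,    40,    80,
    "packaged_juice",      0.15,   100,   200,
    "orange_juice_fresh",  0.08,   100,   200,
    "apple",               0.07,    80,   150,
    "banana",              0.07,    80,   140,
    "plain_yogurt",        0.08,   100,   125,
    "fresh_cheese",        0.05,    30,    60,
    "honey",               0.04,     5,    15,
    "serrano_ham",         0.05,    20,    40,
    "water",               0.10,   100,   250
  )
}

#' Configure the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated two-center cohort of
#' 8--12-year-old children with overweight/obesity: two weekday 24 h-recalls
#' per child, breakfast composition drawn from the packaged food library,
#' and cardiometabolic outcomes generated as linear (or log-linear, for the
#' skewed biomarkers) functions of the child's computed breakfast metrics
#' and confounders plus noise.
#'
#' @param n_children Cohort size.
#' @param center_split Proportion of children in the `vitoria` center.
#' @param seed Integer seed; a fixed seed gives bit-identical output.
#' @param effects Named numeric vector of standardized effects, names of the
#'   form `"exposure:outcome"` with exposure in
#'   `bqi_score`/`beds`/`bedb` and outcome one of the simulated channels
#'   (`uric_acid`, `total_chol`, `hdl`, `ldl`, `sbp`, `dbp`,
#'   `log_triglycerides`, `log_homa`, `log_ggt`). Effects on `log_homa` act
#'   through fasting insulin. Defaults emulate the association pattern the
#'   pipeline is designed to detect.
#' @param confounders Per-outcome named vectors of standardized confounder
#'   strengths (`age`, `sex`, `fmi`, `pa`).
#' @param skip_prob Probability a child skips breakfast on both recall days.
#' @param miss_one_prob Probability a non-skipper has breakfast on only one
#'   of the two recall days.
#' @param p_single_recall Probability a child contributes only one recall
#'   day (exercises the exclusion rule; 0 by default).
#' @param p_girl Proportion of girls.
#' @param age_mean,age_sd Age distribution (years), truncated to 8--12.
#' @param fmi_mean,fmi_sd Fat mass index distribution (kg/m^2).
#' @param energy_mean,energy_sd Target total daily energy intake (kcal).
#' @param mvpa_mean_boy,mvpa_mean_girl,mvpa_sd Daily MVPA (min/day).
#' @param pa_mediation Optional `list(exposure=, strength=)`: total physical
#'   activity generated partly from the named breakfast exposure, making PA
#'   a mediator on the exposure-outcome paths that include a PA term.
#' @param stratum_effects Optional `list(exposure=, outcome=, active=,
#'   inactive=)` overriding one effect separately by activity stratum.
#' @param sex_interaction Optional `list(exposure=, outcome=, diff=)`:
#'   the effect differs between boys and girls by `diff` (boys
#'   `+diff/2`, girls `-diff/2` around the base effect).
#' @param breakfast_profile Tibble `food_id`, `prob`, `gmin`, `gmax` of
#'   per-day breakfast inclusion probabilities and gram ranges.
#' @param kidmed_missing_prob Probability the questionnaire skipping item is
#'   missing.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_children = 203,
                          center_split = 0.55,
                          seed = 1L,
                          effects = c("bqi_score:uric_acid" = -0.17,
                                      "beds:hdl" = 0.19,
                                      "beds:total_chol" = 0.16,
                                      "beds:sbp" = 0.10,
                                      "bedb:log_homa" = 0.20),
                          confounders = default_confounder_strengths(),
                          skip_prob = 0.05,
                          miss_one_prob = 0.05,
                          p_single_recall = 0,
                          p_girl = 0.473,
                          age_mean = 10.3, age_sd = 1.1,
                          fmi_mean = 10.7, fmi_sd = 2.5,
                          energy_mean = 1850, energy_sd = 250,
                          mvpa_mean_boy = 59.9, mvpa_mean_girl = 48.4,
                          mvpa_sd = 20,
                          pa_mediation = NULL,
                          stratum_effects = NULL,
                          sex_interaction = NULL,
                          breakfast_profile = default_breakfast_profile(),
                          kidmed_missing_prob = 0.15) {
  cfg <- list(
    n_children = as.integer(n_children), center_split = center_split,
    seed = as.integer(seed), effects = effects, confounders = confounders,
    skip_prob = skip_prob, miss_one_prob = miss_one_prob,
    p_single_recall = p_single_recall, p_girl = p_girl,
    age_mean = age_mean, age_sd = age_sd,
    fmi_mean = fmi_mean, fmi_sd = fmi_sd,
    energy_mean = energy_mean, energy_sd = energy_sd,
    mvpa_mean_boy = mvpa_mean_boy, mvpa_mean_girl = mvpa_mean_girl,
    mvpa_sd = mvpa_sd,
    pa_mediation = pa_mediation, stratum_effects = stratum_effects,
    sex_interaction = sex_interaction,
    breakfast_profile = tibble::as_tibble(breakfast_profile),
    kidmed_missing_prob = kidmed_missing_prob
  )
  probs <- c(center_split, skip_prob, miss_one_prob, p_single_recall,
             p_girl, kidmed_missing_prob, cfg$breakfast_profile$prob)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_children < 2) stop("cohort_config: n_children must be >= 2",
                           call. = FALSE)
  if (length(cfg$effects) > 0) {
    parts <- strsplit(names(cfg$effects), ":", fixed = TRUE)
    ok <- vapply(parts, function(p) {
      length(p) == 2 && p[1] %in% default_exposures() &&
        p[2] %in% outcome_channels()$channel
    }, logical(1))
    if (any(!ok)) {
      stop("cohort_config: malformed effect key(s): ",
           paste(names(cfg$effects)[!ok], collapse = ", "), call. = FALSE)
    }
    if (skip_prob >= 1) {
      stop("cohort_config: skip_prob = 1 leaves breakfast exposures undefined, ",
           "so breakfast effects cannot be generated", call. = FALSE)
    }
  }
  class(cfg) <- "cohort_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

# z-score with NA treated as at-the-mean (children without the exposure
# contribute no exposure signal to their simulated outcomes)
safe_z <- function(x) {
  mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  z <- (x - mu) / s
  z[is.na(z)] <- 0
  z
}

#' Generate a synthetic two-center cohort
#'
#' Simulates participants, two weekday 24 h-recalls each, and fasting
#' biomarkers. Breakfast baskets are drawn from the configured food profile;
#' the generator then scores each child's actual BQI, BEDs and BEDb with the
#' same code the analysis uses, and simulates outcomes conditional on those
#' computed metrics — so every configured effect refers to the real scoring
#' path, not to a latent intended value.
#'
#' @param config A [cohort_config()].
#' @param dir Optional directory: when given, `food_library.csv`,
#'   `recalls.csv`, `participants.csv` and `truth.csv` are written there in
#'   the formats the loaders consume.
#' @return A list: `library`, `participants`, `recalls`, `scores` (the
#'   per-participant breakfast metrics), `exclusions`, `analysis` (the
#'   regression-ready table from [build_analysis_table()]), `truth` (every
#'   generating coefficient), and `paths` when files were written.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_children
  library <- demo_food_library()

  ## participants -----------------------------------------------------------
  pid <- sprintf("C%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$p_girl, "female", "male")
  boy <- as.numeric(sex == "male")
  center <- ifelse(stats::runif(n) < config$center_split,
                   "vitoria", "granada")
  age <- rtrunc_norm(n, config$age_mean, config$age_sd, 8, 12)
  maternal_ed_high <- stats::runif(n) < 0.262
  puberty_high <- stats::runif(n) <
    stats::plogis(-2.2 + 1.75 * (1 - boy) + 0.8 * (age - config$age_mean))
  fmi <- rtrunc_norm(n, config$fmi_mean, config$fmi_sd, 4, 22)
  fmi_z <- safe_z(fmi)
  abdominal_fat_kg <- pmax(1.7 + 0.6 * (0.8 * fmi_z +
                                          0.6 * stats::rnorm(n)), 0.3)
  waist_cm <- pmax(84.1 + 10.5 * (0.7 * fmi_z + 0.714 * stats::rnorm(n)), 55)
  pa_latent <- stats::rnorm(n)
  mvpa <- pmax(ifelse(boy == 1, config$mvpa_mean_boy,
                      config$mvpa_mean_girl) +
                 config$mvpa_sd * (0.6 * pa_latent + 0.8 * stats::rnorm(n)), 0)

  ## recalls ----------------------------------------------------------------
  single_recall <- stats::runif(n) < config$p_single_recall
  skip_both <- stats::runif(n) < config$skip_prob
  miss_one <- !skip_both & stats::runif(n) < config$miss_one_prob
  missed_day <- sample(1:2, n, replace = TRUE)

  prof <- config$breakfast_profile
  k <- nrow(prof)
  target_energy <- rtrunc_norm(n, config$energy_mean, config$energy_sd,
                               1200, 3200)

  lib_e <- stats::setNames(library$energy_kcal_per_100g, library$food_id)
  make_breakfast <- function(day) {
    inc <- matrix(stats::runif(n * k) < rep(prof$prob, each = n), n, k)
    grams <- matrix(stats::runif(n * k, rep(prof$gmin, each = n),
                                 rep(prof$gmax, each = n)), n, k)
    # guarantee at least one food for children who should have breakfast
    none <- rowSums(inc) == 0
    inc[none, which(prof$food_id == "milk_with_cocoa")] <- TRUE
    has_bf <- !skip_both & !(miss_one & missed_day == day) & (day == 1 | !single_recall)
    idx <- which(inc & has_bf, arr.ind = TRUE)
    tibble::tibble(
      participant_id = pid[idx[, 1]],
      day_index = day,
      meal = "breakfast",
      food_id = prof$food_id[idx[, 2]],
      grams = round(grams[idx], 1)
    )
  }
  bf1 <- make_breakfast(1); bf2 <- make_breakfast(2)

  # remaining meals: a fixed lunch/snack/dinner template scaled per child so
  # total daily energy lands on the child's target
  template <- tibble::tribble(
    ~meal,    ~food_id,         ~grams,
    "lunch",  "cooked_rice",     180,
    "lunch",  "chicken_breast",  120,
    "lunch",  "mixed_salad",      80,
    "lunch",  "olive_oil",        10,
    "lunch",  "orange",          150,
    "snack",  "plain_yogurt",    125,
    "dinner", "cooked_pasta",    150,
    "dinner", "white_fish",      120,
    "dinner", "fried_potato",     80,
    "dinner", "apple",           120
  )
  template_energy <- sum(template$grams * lib_e[template$food_id] / 100)
  other_meals <- function(bf, day) {
    bfe <- stats::setNames(rep(0, n), pid)
    if (nrow(bf) > 0) {
      agg <- stats::aggregate(bf$grams * lib_e[bf$food_id] / 100,
                              by = list(pid = bf$participant_id), FUN = sum)
      bfe[agg$pid] <- agg$x
    }
    present <- day == 1 | !single_recall
    scale_fac <- pmax(target_energy - bfe, 500) / template_energy
    ids <- rep(pid[present], each = nrow(template))
    tibble::tibble(
      participant_id = ids,
      day_index = day,
      meal = rep(template$meal, sum(present)),
      food_id = rep(template$food_id, sum(present)),
      grams = round(rep(template$grams, sum(present)) *
                      rep(scale_fac[present], each = nrow(template)), 1)
    )
  }
  recalls <- dplyr::bind_rows(bf1, other_meals(bf1, 1),
                              bf2, other_meals(bf2, 2))
  recalls <- dplyr::arrange(recalls, .data$participant_id, .data$day_index,
                            .data$meal, .data$food_id)

  kidmed_skip <- ifelse(stats::runif(n) < config$kidmed_missing_prob, NA,
                        skip_both | (stats::runif(n) < 0.08))

  ## score breakfast metrics through the real pipeline ----------------------
  scored <- score_cohort(recalls, library,
                         kidmed = tibble::tibble(participant_id = pid,
                                                 kidmed_skip = kidmed_skip))
  scores <- scored$scores
  ord <- match(pid, scores$participant_id)
  xz <- sapply(default_exposures(),
               function(e) safe_z(scores[[e]][ord]))
  xz[is.na(xz)] <- 0   # excluded (single-recall) children: no exposure signal

  ## physical activity, possibly mediated by an exposure --------------------
  med <- config$pa_mediation
  if (!is.null(med)) {
    stopifnot(med$exposure %in% default_exposures(),
              abs(med$strength) <= 1)
    pa_z <- med$strength * xz[, med$exposure] +
      sqrt(1 - med$strength^2) * pa_latent
  } else {
    pa_z <- pa_latent
  }
  total_pa_enmo <- pmax(63 + 15.4 * pa_z, 5)
  is_active <- classify_activity(mvpa)

  ## outcomes ---------------------------------------------------------------
  age_z <- safe_z(age)
  sex_z <- safe_z(boy)
  conf_z <- cbind(age = age_z, sex = sex_z, fmi = fmi_z, pa = safe_z(total_pa_enmo))

  channels <- outcome_channels()
  glucose <- rtrunc_norm(n, 85.9, 6.2, 60, 130)
  out_vals <- list(glucose = glucose)
  truth_rows <- list()

  for (i in seq_len(nrow(channels))) {
    ch <- channels$channel[i]
    eff <- rep(0, n)
    eff_sq <- 0
    for (e in default_exposures()) {
      key <- paste0(e, ":", ch)
      b <- unname(config$effects[key])
      b <- if (is.null(b) || is.na(b)) 0 else b
      b_i <- rep(b, n)
      se <- config$stratum_effects
      if (!is.null(se) && se$exposure == e && se$outcome == ch) {
        b_i <- ifelse(is_active, se$active, se$inactive)
      }
      si <- config$sex_interaction
      if (!is.null(si) && si$exposure == e && si$outcome == ch) {
        b_i <- b_i + si$diff * (boy - 0.5)
      }
      if (any(b_i != 0)) {
        eff <- eff + b_i * xz[, e]
        eff_sq <- eff_sq + mean(b_i)^2
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          kind = "effect", exposure = e, outcome = ch, term = "standardized",
          value = mean(b_i))
      }
    }
    gamma <- config$confounders[[ch]]
    conf_term <- rep(0, n); conf_sq <- 0
    if (!is.null(gamma) && length(gamma) > 0) {
      for (g in names(gamma)) {
        conf_term <- conf_term + gamma[[g]] * conf_z[, g]
        conf_sq <- conf_sq + gamma[[g]]^2
        truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
          kind = "confounder", exposure = g, outcome = ch, term = "standardized",
          value = gamma[[g]])
      }
    }
    resid_sd <- sqrt(max(0.1, 1 - eff_sq - conf_sq))
    y_std <- eff + conf_term + resid_sd * stats::rnorm(n)
    truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
      kind = "noise", exposure = NA, outcome = ch, term = "residual_sd",
      value = resid_sd)
    if (channels$scale[i] == "normal") {
      out_vals[[ch]] <- channels$par1[i] + channels$par2[i] * y_std
    } else {
      out_vals[[ch]] <- exp(channels$par1[i] + channels$par2[i] * y_std)
    }
  }

  participants <- tibble::tibble(
    participant_id = pid, sex = sex, center = center,
    age_year = round(age, 2), maternal_ed_high = maternal_ed_high,
    puberty_high = puberty_high,
    fmi = round(fmi, 2), abdominal_fat_kg = round(abdominal_fat_kg, 3),
    waist_cm = round(waist_cm, 1),
    sbp = round(out_vals$sbp, 1), dbp = round(out_vals$dbp, 1),
    glucose = round(out_vals$glucose, 1),
    insulin = round(out_vals$log_homa, 2),      # channel is fasting insulin
    triglycerides = round(out_vals$log_triglycerides, 1),
    total_chol = round(out_vals$total_chol, 1),
    hdl = round(out_vals$hdl, 1), ldl = round(out_vals$ldl, 1),
    uric_acid = round(out_vals$uric_acid, 2),
    ggt = round(out_vals$log_ggt, 1),
    total_pa_enmo = round(total_pa_enmo, 1),
    mvpa_min_day = round(mvpa, 1),
    kidmed_skip = kidmed_skip
  )
  # biomarkers are strictly positive by construction of the scales above,
  # but rounding guards
  for (col in c("sbp", "dbp", "hdl", "ldl", "uric_acid", "total_chol",
                "insulin", "triglycerides", "ggt")) {
    participants[[col]] <- pmax(participants[[col]], 0.1)
  }

  truth <- dplyr::bind_rows(truth_rows)
  analysis <- build_analysis_table(participants, scores,
                                   ref = synthetic_mets_reference())

  out <- list(config = config, library = library,
              participants = participants, recalls = recalls,
              scores = scores, exclusions = scored$exclusions,
              analysis = analysis, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      food_library = file.path(dir, "food_library.csv"),
      recalls = file.path(dir, "recalls.csv"),
      participants = file.path(dir, "participants.csv"),
      truth = file.path(dir, "truth.csv")
    )
    readr::write_csv(dplyr::select(library, -"group_tags"),
                     paths$food_library, progress = FALSE)
    readr::write_csv(recalls, paths$recalls, progress = FALSE)
    readr::write_csv(participants, paths$participants, progress = FALSE)
    readr::write_csv(truth, paths$truth, progress = FALSE)
    out$paths <- paths
  }
  out
}
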