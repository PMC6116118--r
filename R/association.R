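#' Default exposure and outcome sets for the association ladder
#'
#' Exposures are the three breakfast dimensions (`bqi_score`, `beds`,
#' `bedb`). Outcomes are the twelve cardiometabolic variables analysed:
#' center-standardized fat mass index and abdominal fat, blood pressures,
#' uric acid, the three cholesterol fractions, log triglycerides, log HOMA,
#' log GGT, and the continuous MetS z-score.
#'
#' @return Character vector of column names.
#' @export
default_exposures <- function() c("bqi_score", "beds", "bedb")

#' @rdname default_exposures
#' @export
default_outcomes <- function() {
  c("fmi_z", "abdominal_fat_z", "sbp", "dbp", "uric_acid",
    "total_chol", "hdl", "ldl", "log_triglycerides", "log_homa",
    "log_ggt", "mets_z")
}

#' Covariate sets of the three-model adjustment ladder
#'
#' Model 1 adjusts for sex, age, study center, maternal educational level
#' and total daily energy intake; Model 2 additionally for fat mass index;
#' Model 3 further for total physical activity. In the puberty sensitivity
#' analysis the age term is replaced by the high-puberty indicator
#' (Tanner stage III or above).
#'
#' @param tier Model tier, 1, 2 or 3.
#' @param puberty Replace age with the puberty indicator?
#' @return Character vector of covariate column names.
#' @export
ladder_covariates <- function(tier, puberty = FALSE) {
  stopifnot(tier %in% 1:3)
  base <- c("sex", if (puberty) "puberty_high" else "age_year",
            "center", "maternal_ed_high", "energy_kcal_day")
  if (tier >= 2) base <- c(base, "fmi")
  if (tier >= 3) base <- c(base, "total_pa_enmo")
  base
}

# categorical covariates entered as indicator terms
factor_covariates <- function() c("sex", "center", "maternal_ed_high",
                                  "puberty_high")

# single standardized-beta OLS fit on complete cases
fit_assoc <- function(data, exposure, outcome, covariates,
                      extra_terms = NULL) {
  cols <- c(exposure, outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("analysis table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < length(covariates) + 3) {
    stop(sprintf("too few complete cases (%d) for %s ~ %s", n, outcome,
                 exposure), call. = FALSE)
  }
  for (fc in intersect(factor_covariates(), covariates)) {
    d[[fc]] <- factor(d[[fc]])
    if (nlevels(d[[fc]]) < 2) {
      # constant factors carry no information; drop rather than fail the fit
      covariates <- setdiff(covariates, fc)
      d[[fc]] <- NULL
    }
  }
  # standardized beta: z-score exposure and outcome on the analysis sample
  d$.x <- as.numeric(scale(d[[exposure]]))
  d$.y <- as.numeric(scale(d[[outcome]]))
  if (anyNA(d$.x) || anyNA(d$.y)) {
    stop(sprintf("exposure or outcome constant in sample for %s ~ %s",
                 outcome, exposure), call. = FALSE)
  }
  rhs <- paste(c(".x", covariates, extra_terms), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  cf <- summary(fit)$coefficients
  if (anyNA(stats::coef(fit))) {
    stop(sprintf("rank-deficient fit for %s ~ %s (tier covariates: %s)",
                 outcome, exposure, paste(covariates, collapse = ", ")),
         call. = FALSE)
  }
  list(fit = fit, coefs = cf, n = n)
}

#' Fit the three-model covariate ladder for one exposure-outcome pair
#'
#' Ordinary least squares on complete cases, with the exposure and the
#' continuous outcome z-standardized on the analysis sample so the reported
#' coefficient is a standardized beta. Categorical covariates (sex, center,
#' maternal education) enter as indicator terms. The fat-mass-index outcome
#' is never adjusted for itself, so only Model 1 is fitted for `fmi_z`.
#'
#' @param data Analysis table (see [build_analysis_table()]).
#' @param exposure,outcome Column names.
#' @param tiers Which model tiers to fit (subset of 1:3).
#' @param puberty Use the puberty indicator instead of age (sensitivity
#'   analysis).
#' @return Tibble with one row per tier: `exposure`, `outcome`, `model`,
#'   `beta` (standardized), `se`, `p`, `n`.
#' @export
fit_ladder <- function(data, exposure, outcome, tiers = 1:3,
                       puberty = FALSE) {
  stopifnot(all(tiers %in% 1:3))
  if (outcome == "fmi_z") tiers <- intersect(tiers, 1L)
  rows <- lapply(tiers, function(tier) {
    covs <- ladder_covariates(tier, puberty = puberty)
    res <- fit_assoc(data, exposure, outcome, covs)
    tibble::tibble(
      exposure = exposure, outcome = outcome, model = as.integer(tier),
      beta = unname(res$coefs[".x", "Estimate"]),
      se   = unname(res$coefs[".x", "Std. Error"]),
      p    = unname(res$coefs[".x", "Pr(>|t|)"]),
      n    = res$n
    )
  })
  dplyr::bind_rows(rows)
}

#' Fit every exposure-outcome-model cell
#'
#' Convenience wrapper producing the long results table whose rows mirror
#' the exposure x outcome x model grid of the main analysis.
#'
#' @inheritParams fit_ladder
#' @param exposures,outcomes Column-name vectors.
#' @return Long tibble of [fit_ladder()] rows.
#' @export
fit_all_ladders <- function(data, exposures = default_exposures(),
                            outcomes = default_outcomes(), tiers = 1:3,
                            puberty = FALSE) {
  grid <- expand.grid(exposure = exposures, outcome = outcomes,
                      stringsAsFactors = FALSE)
  dplyr::bind_rows(purrr::pmap(grid, function(exposure, outcome) {
    fit_ladder(data, exposure, outcome, tiers = tiers, puberty = puberty)
  }))
}

#' Association within activity strata
#'
#' Refits one exposure-outcome association separately in active and
#' inactive children (MVPA at least / below 60 min per day). The Model 2
#' covariate set is used within each stratum: total physical activity is the
#' stratifying variable, so it is not re-entered as a covariate, while fat
#' mass index is retained.
#'
#' @inheritParams fit_ladder
#' @param strata_var Logical column defining the strata (default
#'   `is_active`).
#' @return Tibble with one row per stratum: `stratum`, `beta`, `se`, `p`,
#'   `n`.
#' @export
fit_stratified <- function(data, exposure, outcome,
                           strata_var = "is_active", puberty = FALSE) {
  stopifnot(strata_var %in% names(data))
  covs <- ladder_covariates(2, puberty = puberty)
  rows <- lapply(c(TRUE, FALSE), function(level) {
    d <- data[!is.na(data[[strata_var]]) & data[[strata_var]] == level, ,
              drop = FALSE]
    res <- fit_assoc(d, exposure, outcome, covs)
    tibble::tibble(
      exposure = exposure, outcome = outcome,
      stratum = if (level) "active" else "inactive",
      beta = unname(res$coefs[".x", "Estimate"]),
      se   = unname(res$coefs[".x", "Std. Error"]),
      p    = unname(res$coefs[".x", "Pr(>|t|)"]),
      n    = res$n
    )
  })
  dplyr::bind_rows(rows)
}

#' Test an exposure-by-sex interaction
#'
#' Adds an exposure x sex product term to the Model 1 fit and returns the
#' two-sided p-value of that term, used to decide whether boys and girls can
#' be pooled.
#'
#' @inheritParams fit_ladder
#' @return A one-row tibble: `exposure`, `outcome`, `interaction_beta`,
#'   `interaction_p`, `n`.
#' @export
test_sex_interaction <- function(data, exposure, outcome) {
  d <- data
  if (length(unique(stats::na.omit(d$sex))) < 2) {
    stop("sex is constant in the sample; interaction term inestimable",
         call. = FALSE)
  }
  covs <- ladder_covariates(1)
  res <- fit_assoc(d, exposure, outcome, covs, extra_terms = ".x:sex")
  term <- grep("^\\.x:sex", rownames(res$coefs), value = TRUE)
  stopifnot(length(term) == 1)
  tibble::tibble(
    exposure = exposure, outcome = outcome,
    interaction_beta = unname(res$coefs[term, "Estimate"]),
    interaction_p    = unname(res$coefs[term, "Pr(>|t|)"]),
    n = res$n
  )
}

#' Puberty sensitivity analysis
#'
#' Repeats the full adjustment ladder with the high-puberty indicator
#' (Tanner stage III or above) in place of age.
#'
#' @inheritParams fit_ladder
#' @return As [fit_ladder()].
#' @export
sensitivity_puberty <- function(data, exposure, outcome, tiers = 1:3) {
  fit_ladder(data, exposure, outcome, tiers = tiers, puberty = TRUE)
}
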