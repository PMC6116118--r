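#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' HOMA = fasting insulin (uU/mL) x fasting glucose (mmol/L) / 22.5.
#' Glucose supplied in mg/dL is converted to mmol/L by dividing by 18.016
#' (the molar mass of glucose per deciliter-to-liter scaling).
#'
#' @param insulin_uU_ml Fasting insulin, uU/mL (nonnegative; vectorized).
#' @param glucose_mg_dl Fasting glucose, mg/dL (nonnegative; vectorized).
#' @return Numeric vector of HOMA values; `NA` propagates.
#' @export
compute_homa <- function(insulin_uU_ml, glucose_mg_dl) {
  if (any(insulin_uU_ml < 0, na.rm = TRUE) ||
      any(glucose_mg_dl < 0, na.rm = TRUE)) {
    stop("insulin and glucose must be nonnegative", call. = FALSE)
  }
  insulin_uU_ml * (glucose_mg_dl / 18.016) / 22.5
}

mets_components <- function() {
  c("triglycerides", "hdl", "glucose", "sbp", "dbp")
}

#' Build a metabolic-syndrome reference from tables
#'
#' The continuous MetS z-score and the central-obesity criterion both need
#' external pediatric reference data: sex- and age-specific means and SDs of
#' the five syndrome components, and sex/age 90th-percentile waist cutoffs.
#'
#' @param components Tibble with columns `sex`, `age_year`, `component`
#'   (one of `triglycerides`, `hdl`, `glucose`, `sbp`, `dbp`), `mean`, `sd`.
#' @param waist Tibble with columns `sex`, `age_year`, `waist_p90` (cm).
#' @return A `mets_reference` object.
#' @seealso [synthetic_mets_reference()] for the packaged toy reference.
#' @export
mets_reference <- function(components, waist) {
  components <- tibble::as_tibble(components)
  waist <- tibble::as_tibble(waist)
  stopifnot(all(c("sex", "age_year", "component", "mean", "sd") %in%
                  names(components)),
            all(c("sex", "age_year", "waist_p90") %in% names(waist)))
  if (any(components$sd <= 0)) {
    stop("mets reference: every component SD must be > 0", call. = FALSE)
  }
  bad <- setdiff(unique(components$component), mets_components())
  if (length(bad) > 0) {
    stop("mets reference: unknown component ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(components = components, waist = waist),
            class = "mets_reference")
}

#' Load a metabolic-syndrome reference from delimited files
#'
#' @param components_path CSV with columns `sex`, `age_year`, `component`,
#'   `mean`, `sd`.
#' @param waist_path CSV with columns `sex`, `age_year`, `waist_p90`.
#' @return A `mets_reference` object.
#' @export
load_mets_reference <- function(components_path, waist_path) {
  mets_reference(
    readr::read_csv(components_path, show_col_types = FALSE, progress = FALSE),
    readr::read_csv(waist_path, show_col_types = FALSE, progress = FALSE)
  )
}

# wide per-stratum lookup table: one row per sex x age, columns mean_/sd_
ref_wide <- function(ref) {
  tidyr::pivot_wider(ref$components,
                     names_from = "component",
                     values_from = c("mean", "sd"))
}

check_strata <- function(found, sex, age_year, what) {
  if (any(!found)) {
    i <- which(!found)[1]
    stop(sprintf("no %s reference stratum for sex '%s', age %s",
                 what, sex[i], age_year[i]), call. = FALSE)
  }
}

#' Classify pediatric metabolic syndrome (IDF-style factor count)
#'
#' Flags five risk factors at the conventional pediatric cutoffs: central
#' obesity (waist at or above the sex/age 90th percentile), elevated blood
#' pressure (SBP >= 130 or DBP >= 85 mmHg), elevated triglycerides
#' (>= 150 mg/dL), low HDL cholesterol (< 40 mg/dL), and impaired fasting
#' glucose (>= 100 mg/dL). Metabolic syndrome is present with three or more
#' factors. Rows with any missing component are marked incomplete and their
#' `has_mets` is `NA`.
#'
#' @param data Tibble with columns `sex`, `age_year`, `waist_cm`, `sbp`,
#'   `dbp`, `triglycerides`, `hdl`, `glucose`.
#' @param ref A [mets_reference()] supplying waist cutoffs.
#' @return `data` with added columns `central_obesity`, `elevated_bp`,
#'   `elevated_tg`, `low_hdl`, `impaired_glucose`, `factor_count`,
#'   `has_mets`, `mets_complete`.
#' @export
classify_mets <- function(data, ref) {
  stopifnot(inherits(ref, "mets_reference"))
  data <- tibble::as_tibble(data)
  age <- as.integer(floor(data$age_year))
  idx <- match(paste(data$sex, age), paste(ref$waist$sex, ref$waist$age_year))
  check_strata(!is.na(idx), data$sex, age, "waist")
  p90 <- ref$waist$waist_p90[idx]

  flags <- tibble::tibble(
    central_obesity  = data$waist_cm >= p90,
    elevated_bp      = data$sbp >= 130 | data$dbp >= 85,
    elevated_tg      = data$triglycerides >= 150,
    low_hdl          = data$hdl < 40,
    impaired_glucose = data$glucose >= 100
  )
  complete <- !is.na(rowSums(!flags))
  count <- rowSums(flags)
  dplyr::bind_cols(data, flags,
                   tibble::tibble(
                     factor_count = as.integer(count),
                     has_mets = count >= 3,
                     mets_complete = complete
                   ))
}

#' Continuous metabolic-syndrome z-score
#'
#' The composite is the sum of the sex- and age-specific z-scores of the
#' five syndrome components: triglycerides, HDL cholesterol, glucose, and
#' systolic and diastolic blood pressure. By default the HDL term is negated
#' so that a higher composite always indicates a worse risk profile.
#'
#' @inheritParams classify_mets
#' @param hdl_direction `"negate"` (default) to flip the HDL z-score so that
#'   low HDL raises the composite, `"raw"` to sum it as-is.
#' @return Numeric vector of MetS z-scores (`NA` when any component or its
#'   stratum value is missing).
#' @export
compute_mets_z <- function(data, ref, hdl_direction = c("negate", "raw")) {
  stopifnot(inherits(ref, "mets_reference"))
  hdl_direction <- match.arg(hdl_direction)
  data <- tibble::as_tibble(data)
  age <- as.integer(floor(data$age_year))
  w <- ref_wide(ref)
  idx <- match(paste(data$sex, age), paste(w$sex, w$age_year))
  check_strata(!is.na(idx), data$sex, age, "component")

  z_of <- function(col) {
    (data[[col]] - w[[paste0("mean_", col)]][idx]) /
      w[[paste0("sd_", col)]][idx]
  }
  hdl_sign <- if (hdl_direction == "negate") -1 else 1
  z_of("triglycerides") + hdl_sign * z_of("hdl") + z_of("glucose") +
    z_of("sbp") + z_of("dbp")
}

#' Center-wise z-standardization
#'
#' Standardizes a measure within each study center: (x - center mean) /
#' center SD over the non-missing values of that center. Used for the
#' DXA-derived adiposity measures, where the two centers used similar but
#' not identical densitometers, to remove any systematic between-device
#' shift before pooling.
#'
#' @param x Numeric vector.
#' @param center Center label per element of `x`.
#' @return Numeric vector of within-center z-scores; missing values
#'   propagate.
#' @export
center_zscore <- function(x, center) {
  stopifnot(length(x) == length(center))
  out <- rep(NA_real_, length(x))
  for (ct in unique(center)) {
    sel <- which(center == ct & !is.na(x))
    if (length(sel) < 2) {
      stop(sprintf("center '%s' has fewer than 2 non-missing values", ct),
           call. = FALSE)
    }
    s <- stats::sd(x[sel])
    if (s == 0) {
      stop(sprintf("center '%s' has zero variance", ct), call. = FALSE)
    }
    out[sel] <- (x[sel] - mean(x[sel])) / s
  }
  out
}

#' Apply the outcome transformation policy
#'
#' Triglycerides, GGT, insulin and HOMA are right-skewed in children and are
#' natural-log transformed before regression; every other outcome passes
#' through unchanged. A manifest recording the transform applied to each
#' column is attached as the `"transform_manifest"` attribute.
#'
#' @param data Outcome tibble; must contain a `participant_id` column used
#'   to identify offending rows in error messages.
#' @param log_cols Columns to log-transform (only those present are used).
#' @return `data` with added `log_<col>` columns and the manifest attribute.
#' @export
transform_outcomes <- function(data,
                               log_cols = c("triglycerides", "ggt",
                                            "insulin", "homa")) {
  data <- tibble::as_tibble(data)
  log_cols <- intersect(log_cols, names(data))
  for (col in log_cols) {
    bad <- which(!is.na(data[[col]]) & data[[col]] <= 0)
    if (length(bad) > 0) {
      stop(sprintf("cannot log-transform '%s': nonpositive value for participant %s",
                   col, data$participant_id[bad[1]]), call. = FALSE)
    }
    data[[paste0("log_", col)]] <- log(data[[col]])
  }
  manifest <- tibble::tibble(
    column = names(data),
    transform = ifelse(names(data) %in% paste0("log_", log_cols),
                       "natural_log", "identity")
  )
  attr(data, "transform_manifest") <- manifest
  data
}
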