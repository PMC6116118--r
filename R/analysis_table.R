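#' Assemble the regression-ready analysis table
#'
#' Joins the participant table to the per-participant breakfast metrics and
#' derives every outcome the association ladder consumes: HOMA from fasting
#' insulin and glucose, the IDF-style metabolic-syndrome flags and the
#' continuous MetS z-score against a pediatric reference, center-wise
#' z-scores of the DXA adiposity measures (fat mass index and abdominal
#' fat), natural logs of the skewed biomarkers, and the active/inactive
#' physical-activity classification.
#'
#' @param participants Participant tibble: `participant_id`, `sex`,
#'   `center`, `age_year`, `maternal_ed_high`, `puberty_high`, `fmi`,
#'   `abdominal_fat_kg`, `waist_cm`, `sbp`, `dbp`, `glucose`, `insulin`,
#'   `triglycerides`, `total_chol`, `hdl`, `ldl`, `uric_acid`, `ggt`,
#'   `total_pa_enmo`, `mvpa_min_day`.
#' @param scores Per-participant breakfast metrics from [score_cohort()].
#' @param ref A [mets_reference()]; defaults to the packaged synthetic toy
#'   reference.
#' @return A tibble with one row per scored participant holding exposures,
#'   covariates, and the twelve outcome columns of [default_outcomes()].
#' @export
build_analysis_table <- function(participants, scores,
                                 ref = synthetic_mets_reference()) {
  d <- dplyr::inner_join(tibble::as_tibble(participants),
                         tibble::as_tibble(scores),
                         by = "participant_id")
  d$homa <- compute_homa(d$insulin, d$glucose)
  d$mets_z <- compute_mets_z(d, ref)
  mets <- classify_mets(d, ref)
  d$has_mets <- mets$has_mets
  d$mets_factor_count <- mets$factor_count
  d$fmi_z <- center_zscore(d$fmi, d$center)
  d$abdominal_fat_z <- center_zscore(d$abdominal_fat_kg, d$center)
  d <- transform_outcomes(d)
  d$is_active <- classify_activity(d$mvpa_min_day)
  d
}

#' Run the full pipeline: simulate, score, associate
#'
#' Generates a synthetic cohort, writes its input files, re-reads them
#' through the loaders, scores the breakfast metrics, assembles the
#' analysis table, and fits the full exposure x outcome x model grid.
#' Results (`scores.csv`, `associations.csv`) are written next to the
#' simulated inputs.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the generator.
#' @param n_children Cohort size.
#' @param config Optional [cohort_config()] overriding `seed`/`n_children`.
#' @return Invisibly, a list with `scores`, `associations`, `analysis`, and
#'   the file `paths`.
#' @export
run_breakfast_pipeline <- function(out_dir, seed = 1L, n_children = 203,
                                   config = NULL) {
  if (is.null(config)) {
    config <- cohort_config(n_children = n_children, seed = seed)
  }
  sim <- generate_cohort(config, dir = out_dir)

  # read the written files back through the loaders so the file interfaces
  # are exercised end to end
  library <- load_food_library(sim$paths$food_library)
  recalls <- load_recalls(sim$paths$recalls, library = library)
  participants <- readr::read_csv(sim$paths$participants,
                                  show_col_types = FALSE, progress = FALSE)
  scored <- score_cohort(recalls, library,
                         kidmed = participants[, c("participant_id",
                                                   "kidmed_skip")])
  analysis <- build_analysis_table(participants, scored$scores)
  associations <- fit_all_ladders(analysis)

  paths <- c(sim$paths,
             scores = file.path(out_dir, "scores.csv"),
             associations = file.path(out_dir, "associations.csv"))
  readr::write_csv(scored$scores, paths$scores, progress = FALSE)
  readr::write_csv(associations, paths$associations, progress = FALSE)
  invisible(list(scores = scored$scores, associations = associations,
                 analysis = analysis, paths = paths))
}
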