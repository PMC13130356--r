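#' Analysis configuration
#'
#' Declares the analytic choices of the population study: the KDM biomarker
#' panel, the two covariate sets (Model 1: sociodemographics + lifestyle;
#' Model 2: Model 1 plus the inflammatory markers CRP and WBC), the age
#' restriction (> 45 years), the exposure and outcomes, the number of
#' pooled survey cycles for weight combination, and whether median splits
#' use survey weights.
#'
#' @param biomarkers KDM biomarker columns.
#' @param covariates_model1 adjustment set for Model 1.
#' @param covariates_model2 adjustment set for Model 2 (must contain
#'   Model 1).
#' @param age_floor analytic sample restricted to ages strictly above this.
#' @param exposure binary exposure column, nonusers as reference.
#' @param n_cycles cycles pooled; weights are divided by this.
#' @param weighted_medians survey-weighted medians for index splits.
#' @param accel_threshold residual cutoff (years) defining KDM acceleration.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(biomarkers = kdm_biomarkers(),
                            covariates_model1 = c("chronological_age", "sex",
                                                  "race", "marital_status",
                                                  "income_poverty_ratio",
                                                  "smoking", "alcohol",
                                                  "energy_intake", "bmi"),
                            covariates_model2 = c(covariates_model1, "crp", "wbc"),
                            age_floor = 45,
                            exposure = "antibiotic_use",
                            n_cycles = 1,
                            weighted_medians = TRUE,
                            accel_threshold = 0) {
  if (!all(covariates_model1 %in% covariates_model2)) {
    stop("Model 1 covariates must be a subset of Model 2 covariates")
  }
  structure(list(biomarkers = biomarkers,
                 covariates_model1 = covariates_model1,
                 covariates_model2 = covariates_model2,
                 age_floor = age_floor, exposure = exposure,
                 n_cycles = n_cycles, weighted_medians = weighted_medians,
                 accel_threshold = accel_threshold),
            class = "analysis_config")
}

#' Sequential exclusions with a telescoping report
#'
#' Applies, in order: the age floor (strictly greater), completeness of
#' exposure and the diarrhea outcome, completeness of all model covariates,
#' completeness of the dietary components needed for DI-GM and CDAI, and —
#' for the KDM analyses only — completeness of every KDM biomarker.  The
#' report records `n_before, n_removed, n_after` per step and telescopes
#' exactly.
#'
#' @param cohort cohort table.
#' @param config [analysis_config()].
#' @return list: `analytic` (all steps except the biomarker step, used for
#'   the diarrhea models), `kdm` (additionally complete on all KDM
#'   biomarkers, used for the KDM models), `report`.
#' @export
apply_exclusions <- function(cohort, config = analysis_config()) {
  diet_cols <- c(digm_config()$name[digm_config()$scorable &
                                      digm_config()$rule != "fat_share_lt"],
                 "fat_energy_share", cdai_nutrients())
  required <- unique(c("participant_id", "chronological_age", config$exposure,
                       "diarrhea", config$covariates_model2, diet_cols,
                       config$biomarkers, "stratum_id", "psu_id", "weight"))
  stop_if_missing_cols(cohort, required)

  steps <- list(
    age_floor = function(d) d[!is.na(d$chronological_age) &
                                d$chronological_age > config$age_floor, ],
    complete_exposure_outcome = function(d)
      d[stats::complete.cases(d[, c(config$exposure, "diarrhea")]), ],
    complete_covariates = function(d)
      d[stats::complete.cases(d[, config$covariates_model2]), ],
    complete_diet_components = function(d)
      d[stats::complete.cases(d[, diet_cols]), ]
  )
  report <- data.frame(step = character(), n_before = integer(),
                       n_removed = integer(), n_after = integer())
  current <- cohort
  for (nm in names(steps)) {
    before <- nrow(current)
    current <- steps[[nm]](current)
    report <- rbind(report, data.frame(step = nm, n_before = before,
                                       n_removed = before - nrow(current),
                                       n_after = nrow(current)))
  }
  analytic <- current
  kdm_keep <- stats::complete.cases(analytic[, config$biomarkers])
  kdm <- analytic[kdm_keep, ]
  report <- rbind(report, data.frame(step = "complete_kdm_biomarkers",
                                     n_before = nrow(analytic),
                                     n_removed = sum(!kdm_keep),
                                     n_after = nrow(kdm)))
  rownames(report) <- NULL
  list(analytic = analytic, kdm = kdm, report = report)
}

# score a cohort: KDM age + acceleration on the KDM sample, DI-GM and CDAI
# on the analytic sample; everything computed once and reused downstream
score_cohort <- function(excl, config) {
  kdm_fit <- fit_kdm(excl$kdm, config$biomarkers)
  scores <- compute_kdm(kdm_fit, excl$kdm)
  scores <- compute_age_acceleration(scores, excl$kdm, config$accel_threshold)

  analytic <- excl$analytic
  meds <- compute_sex_medians(analytic, weighted = config$weighted_medians)
  digm <- compute_digm(analytic, sex_medians = meds)
  refs <- compute_sex_references(analytic)
  cdai <- compute_cdai(analytic, refs)

  analytic$digm <- digm$digm[match(analytic$participant_id, digm$participant_id)]
  analytic$cdai <- cdai$cdai[match(analytic$participant_id, cdai$participant_id)]
  w <- if (config$weighted_medians) analytic$weight
  analytic$digm_group <- median_split(analytic$digm, w)
  analytic$cdai_group <- median_split(analytic$cdai, w)
  analytic$kdm_age <- scores$kdm_age[match(analytic$participant_id, scores$participant_id)]
  analytic$acceleration <- scores$acceleration[match(analytic$participant_id, scores$participant_id)]
  analytic$accelerated <- scores$accelerated[match(analytic$participant_id, scores$participant_id)]
  analytic$joint_group <- joint_diet_group(analytic$digm_group, analytic$cdai_group)
  list(analytic = analytic, kdm_model = kdm_fit,
       sex_medians = meds, cdai_references = refs)
}

# double-low / single-low / double-high joint grouping
joint_diet_group <- function(digm_group, cdai_group) {
  low_d <- digm_group == "low"
  low_c <- cdai_group == "low"
  out <- ifelse(low_d & low_c, "double_low",
                ifelse(!low_d & !low_c, "double_high", "single_low"))
  factor(out, levels = c("double_low", "single_low", "double_high"))
}

fit_or_null <- function(formula, data, ...) {
  tryCatch(fit_survey_logistic(formula, data, ...), error = function(e) NULL)
}

#' Primary association analysis
#'
#' For each outcome (KDM acceleration; diarrhea) and each covariate set
#' (Model 1; Model 2), fits a survey-weighted logistic regression of the
#' outcome on the exposure plus covariates and extracts the exposure odds
#' ratio as a forest-table row.
#'
#' @param scored output of the internal scoring step (a cohort carrying
#'   `accelerated`, `digm`, `cdai`, design columns); obtained via
#'   [run_study()] or by scoring manually.
#' @param config [analysis_config()].
#' @return forest-style data frame (one row per outcome x model).
#' @export
run_primary_analysis <- function(scored, config = analysis_config()) {
  fits <- list()
  for (oc in c("accelerated", "diarrhea")) {
    dat <- scored
    if (oc == "accelerated") dat <- dat[!is.na(dat$accelerated), ]
    for (m in c("model1", "model2")) {
      covars <- if (m == "model1") config$covariates_model1 else config$covariates_model2
      f <- stats::reformulate(c(config$exposure, covars), response = oc)
      fits[[paste(oc, m, sep = ".")]] <- fit_or_null(f, dat)
    }
  }
  odds_ratio_table(fits, config$exposure)
}

#' Stratified effect-modification analysis
#'
#' Median splits on DI-GM and CDAI (already attached to the scored cohort),
#' per-stratum exposure odds ratios for both outcomes, and the joint
#' grouping double-low / single-low / double-high.  Strata are mutually
#' exclusive and exhaustive; an empty or inestimable stratum yields a row
#' flagged `not estimable`.  Model 1 covariates are used within strata.
#'
#' @inheritParams run_primary_analysis
#' @return forest-style data frame (one row per outcome x stratum).
#' @export
run_effect_modification <- function(scored, config = analysis_config()) {
  groupings <- list(
    digm = split(seq_len(nrow(scored)), scored$digm_group),
    cdai = split(seq_len(nrow(scored)), scored$cdai_group),
    joint = split(seq_len(nrow(scored)), scored$joint_group)
  )
  fits <- list()
  for (oc in c("accelerated", "diarrhea")) {
    for (g in names(groupings)) {
      for (lev in names(groupings[[g]])) {
        idx <- groupings[[g]][[lev]]
        dat <- scored[idx, , drop = FALSE]
        if (oc == "accelerated") dat <- dat[!is.na(dat$accelerated), ]
        key <- paste(oc, g, lev, sep = ".")
        if (nrow(dat) < 10L) { fits[key] <- list(NULL); next }
        f <- stats::reformulate(c(config$exposure, config$covariates_model1),
                                response = oc)
        fits[key] <- list(fit_or_null(f, dat))
      }
    }
  }
  odds_ratio_table(fits, config$exposure)
}

#' Run the full population study on a cohort
#'
#' Orchestrates the complete sequence: cycle-weight combination,
#' exclusions, KDM training and scoring, dietary index scoring, median
#' splits, the primary Model 1/Model 2 analyses and the stratified
#' effect-modification analyses.  KDM and index values are computed once
#' and reused by every model.
#'
#' @param cohort cohort table (e.g. from [generate_cohort()] or read from
#'   CSV).
#' @param config [analysis_config()].
#' @return list: `exclusions` (telescoping report), `kdm_model`, `scored`
#'   (analytic cohort with kdm_age/acceleration/digm/cdai/groups),
#'   `primary` and `modification` forest tables, `sex_medians`,
#'   `cdai_references`.
#' @export
run_study <- function(cohort, config = analysis_config()) {
  cohort$weight <- combine_cycle_weights(cohort$weight, config$n_cycles)
  excl <- apply_exclusions(cohort, config)
  sc <- score_cohort(excl, config)
  primary <- run_primary_analysis(sc$analytic, config)
  modification <- run_effect_modification(sc$analytic, config)
  list(exclusions = excl$report, kdm_model = sc$kdm_model,
       scored = sc$analytic, primary = primary, modification = modification,
       sex_medians = sc$sex_medians, cdai_references = sc$cdai_references)
}

#' Write study outputs as plain-text report files
#'
#' Emits the forest tables as TSV, the exclusion flowchart as text, and the
#' KDM model as a key-value file.
#'
#' @param study output of [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_reports <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$primary, file.path(dir, "primary_or_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(study$modification, file.path(dir, "modification_or_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rep <- study$exclusions
  writeLines(c("participant exclusion flowchart",
               sprintf("%-28s %8s %8s %8s", "step", "before", "removed", "after"),
               sprintf("%-28s %8d %8d %8d", rep$step, rep$n_before,
                       rep$n_removed, rep$n_after)),
             file.path(dir, "exclusion_flowchart.txt"))
  write_kdm_model(study$kdm_model, file.path(dir, "kdm_model.tsv"))
  invisible(dir)
}
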