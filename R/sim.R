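#' Default biomarker trajectory specifications
#'
#' Linear-Gaussian working trajectories `x = q_true + k_true * bioage +
#' Normal(0, s_true)` for the ten KDM biomarkers, in their clinical units
#' (mmHg, g/dL, U/L, mg/dL, mg/dL, %, mg/dL, %, 10^3 cells/uL, fL).
#' Intercepts and slopes are in the range of published NHANES age
#' gradients; residual SDs are set so each marker predicts age to roughly
#' +/- 11 years, a deliberately high-signal panel that keeps the planted
#' accelerated-aging class identifiable by the downstream KDM residual
#' split (see the methods vignette).  White blood cell count is kept
#' nearly flat in age, so the panel also exercises the near-zero-weight
#' case.
#'
#' @return data frame `name, q_true, k_true, s_true`.
#' @export
default_biomarker_specs <- function() {
  data.frame(
    name = kdm_biomarkers(),
    q_true = c(95, 4.8, 58, 8.5, 0.72, 4.9, 150, 38, 6.8, 86),
    k_true = c(0.60, -0.008, 0.35, 0.14, 0.004, 0.018, 1.1, -0.18, 0.012, 0.08),
    s_true = c(6.5, 0.09, 4.0, 1.5, 0.045, 0.20, 12, 2.0, 1.4, 1.0)
  )
}

#' Default dietary intake distributions
#'
#' Sex-specific lognormal intakes for the scorable DI-GM food groups
#' (g/day; coffee in g fluid/day) and the six CDAI nutrients (vitamin A in
#' ug RAE/day, vitamin C and E and zinc in mg/day, beta-carotene and
#' selenium in ug/day).  Men's location parameters sit slightly above
#' women's, mirroring higher total intakes.
#'
#' @return data frame `component, male_meanlog, female_meanlog, sdlog`.
#' @export
default_diet_specs <- function() {
  comp <- c("avocado", "broccoli", "chickpeas", "coffee", "cranberries",
            "fermented_dairy", "fiber", "soybean", "whole_grains",
            "red_meat", "processed_meat", "refined_grains",
            "vitamin_a", "vitamin_c", "vitamin_e", "beta_carotene",
            "selenium", "zinc")
  female <- log(c(5, 15, 8, 300, 3, 80, 15, 10, 40,
                  50, 20, 120,
                  550, 70, 7.5, 1800, 95, 9.5))
  male <- female + log(1.15)
  data.frame(component = comp, male_meanlog = male, female_meanlog = female,
             sdlog = 0.5)
}

#' Simulation configuration for an NHANES-like cohort
#'
#' All generative parameters in one validated object: design geometry
#' (strata, PSUs, lognormal weights), demographics, biomarker trajectories,
#' dietary intake distributions, the exposure model, and the outcome models
#' with planted log odds ratios (optionally stratum-specific for effect
#' modification by a dietary index).
#'
#' The accelerated-aging outcome is generated by drawing the binary
#' accelerated status from its logistic model and then shifting each
#' participant's latent biological age by `gap + |Normal(0, sd)|` years in
#' the corresponding direction, so the downstream KDM residual split
#' inherits the planted odds ratio without circular use of the estimator.
#' Its marginal prevalence is held at 1/2 (it is a residual split) by
#' calibrating the intercept numerically; the diarrhea intercept is
#' calibrated to `prevalence` the same way.
#'
#' @param n_participants cohort size.
#' @param n_strata,psus_per_stratum sampling design geometry (every stratum
#'   receives exactly `psus_per_stratum` PSUs).
#' @param weight_meanlog,weight_sdlog lognormal law for sampling weights.
#' @param age_range chronological age bounds (years), uniform.
#' @param sex_ratio proportion female.
#' @param biomarker_specs data frame `name, q_true, k_true, s_true`.
#' @param exposure list: `prevalence` (30-day antibiotic use), `beta_age`
#'   (per year, centered at 50), `beta_female`.
#' @param accelerated list: `log_or` (planted exposure log-OR) or
#'   `log_or_low`/`log_or_high` with `modifier` (`"digm"` or `"cdai"`);
#'   `beta_female`.
#' @param diarrhea list: `prevalence`, `log_or` (or stratified as above),
#'   `beta_female`, `beta_age`.
#' @param latent_shift list: `gap` and `sd` (years) of the bioage shift.
#' @param diet_specs data frame per [default_diet_specs()].
#' @param missing_rate MCAR missingness probability for `missing_columns`.
#' @param missing_columns columns targeted by missingness.
#' @param seed integer seed; one pseudorandom stream per cohort with
#'   purpose-keyed substreams.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 5000,
                       n_strata = 45,
                       psus_per_stratum = 2,
                       weight_meanlog = 0,
                       weight_sdlog = 0.6,
                       age_range = c(20, 85),
                       sex_ratio = 0.52,
                       biomarker_specs = default_biomarker_specs(),
                       exposure = list(prevalence = 0.08, beta_age = 0.015,
                                       beta_female = 0.10),
                       accelerated = list(log_or = log(1.64),
                                          log_or_low = NULL, log_or_high = NULL,
                                          modifier = NULL, beta_female = 0),
                       diarrhea = list(prevalence = 0.08, log_or = log(2.66),
                                       log_or_low = NULL, log_or_high = NULL,
                                       modifier = NULL, beta_female = 0.10,
                                       beta_age = 0.005),
                       latent_shift = list(gap = 14, sd = 2),
                       diet_specs = default_diet_specs(),
                       missing_rate = 0,
                       missing_columns = kdm_biomarkers(),
                       seed = 1L) {
  cfg <- list(n_participants = n_participants, n_strata = n_strata,
              psus_per_stratum = psus_per_stratum,
              weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
              age_range = age_range, sex_ratio = sex_ratio,
              biomarker_specs = biomarker_specs, exposure = exposure,
              accelerated = accelerated, diarrhea = diarrhea,
              latent_shift = latent_shift, diet_specs = diet_specs,
              missing_rate = missing_rate, missing_columns = missing_columns,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (cfg$n_strata * cfg$psus_per_stratum < 2) fail("n_strata/psus_per_stratum", "must give >= 2 PSUs in total")
  if (cfg$n_participants < cfg$n_strata * cfg$psus_per_stratum) {
    fail("n_participants", "must be at least one record per PSU")
  }
  if (any(cfg$biomarker_specs$s_true < 0)) fail("biomarker_specs", "has s_true < 0")
  if (!is.finite(cfg$weight_sdlog) || cfg$weight_sdlog < 0) fail("weight_sdlog", "must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) fail("missing_rate", "must be in [0, 1)")
  if (cfg$age_range[1] >= cfg$age_range[2]) fail("age_range", "must be increasing")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) fail("sex_ratio", "must be a proportion")
  if (cfg$exposure$prevalence <= 0 || cfg$exposure$prevalence >= 1) fail("exposure$prevalence", "must be in (0, 1)")
  if (cfg$diarrhea$prevalence <= 0 || cfg$diarrhea$prevalence >= 1) fail("diarrhea$prevalence", "must be in (0, 1)")
  if (cfg$latent_shift$gap <= 0) fail("latent_shift$gap", "must be > 0")
  if (cfg$latent_shift$sd < 0) fail("latent_shift$sd", "must be >= 0")
  for (oc in c("accelerated", "diarrhea")) {
    m <- cfg[[oc]]
    strat <- !is.null(m$log_or_low) || !is.null(m$log_or_high)
    if (strat && (is.null(m$modifier) || !m$modifier %in% c("digm", "cdai"))) {
      fail(paste0(oc, "$modifier"), "must be 'digm' or 'cdai' when stratum log-ORs are given")
    }
    if (strat && (is.null(m$log_or_low) || is.null(m$log_or_high))) {
      fail(paste0(oc, "$log_or_low/high"), "must both be given for a stratified effect")
    }
  }
  invisible(TRUE)
}

# per-record planted log-OR for one outcome model, given modifier strata
planted_log_or <- function(model, modifier_low) {
  if (!is.null(model$log_or_low)) {
    low <- modifier_low[[model$modifier]]
    ifelse(low, model$log_or_low, model$log_or_high)
  } else {
    rep(model$log_or, length(modifier_low[[1]]))
  }
}

# intercept such that mean(plogis(a + lp)) == target
calibrate_intercept <- function(lp, target) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                 interval = c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic NHANES-like cohort
#'
#' Draws the sampling design, demographics, dietary intakes, exposure,
#' outcomes and biomarker panel described by a [sim_config()].  Identical
#' config and seed give identical tables.  Ground-truth columns
#' (`true_accelerated`, `bioage_shift`) are included for recovery testing
#' and would not exist in real data.
#'
#' When an outcome has stratum-specific planted effects, the modifier
#' stratum (low/high DI-GM or CDAI) is derived from the drawn intakes with
#' the package's own scoring functions, using weighted sex-specific medians
#' computed on the over-45 subsample — the same construction the analysis
#' pipeline applies — so the planted strata coincide with the analysis
#' strata.
#'
#' @param config a [sim_config()].
#' @return data frame (one row per participant) with attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_participants
  seed <- config$seed

  # --- sampling design: balanced strata, every PSU populated
  design <- with_substream(seed, "design", {
    stratum_id <- sample(rep_len(seq_len(config$n_strata), n))
    psu_id <- integer(n)
    for (h in seq_len(config$n_strata)) {
      idx <- which(stratum_id == h)
      psu_id[idx] <- sample(rep_len(seq_len(config$psus_per_stratum), length(idx)))
    }
    weight <- stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog)
    list(stratum_id = stratum_id, psu_id = psu_id, weight = weight)
  })

  # --- demographics and covariates
  demo <- with_substream(seed, "demographics", {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
    list(
      age = age, sex = sex,
      race = sample(c("white", "black", "hispanic", "other"), n, TRUE,
                    prob = c(0.45, 0.20, 0.25, 0.10)),
      marital_status = sample(c("married", "previously_married", "never_married"),
                              n, TRUE, prob = c(0.55, 0.25, 0.20)),
      income_poverty_ratio = pmin(stats::rlnorm(n, log(2), 0.6), 5),
      smoking = sample(c("never", "former", "current"), n, TRUE,
                       prob = c(0.50, 0.30, 0.20)),
      alcohol = stats::rgamma(n, shape = 1.5, scale = 3),
      energy_intake = stats::rlnorm(n, log(2000), 0.3),
      bmi = pmax(stats::rnorm(n, 28.5, 5.5), 15),
      crp = stats::rlnorm(n, log(0.2), 1)
    )
  })

  # --- dietary intakes (sex-specific lognormal) and fat energy share
  diet <- with_substream(seed, "diet", {
    out <- list(fat_energy_share = stats::rbeta(n, 17, 33))
    for (i in seq_len(nrow(config$diet_specs))) {
      sp <- config$diet_specs[i, ]
      ml <- ifelse(demo$sex == "male", sp$male_meanlog, sp$female_meanlog)
      out[[sp$component]] <- stats::rlnorm(n, ml, sp$sdlog)
    }
    out
  })

  # --- exposure: 30-day antibiotic use
  abx <- with_substream(seed, "exposure", {
    lp <- config$exposure$beta_age * (demo$age - 50) +
      config$exposure$beta_female * (demo$sex == "female")
    a <- calibrate_intercept(lp, config$exposure$prevalence)
    stats::rbinom(n, 1, stats::plogis(a + lp))
  })

  cohort <- data.frame(
    participant_id = seq_len(n),
    chronological_age = demo$age,
    sex = demo$sex,
    race = demo$race,
    marital_status = demo$marital_status,
    income_poverty_ratio = demo$income_poverty_ratio,
    smoking = demo$smoking,
    alcohol = demo$alcohol,
    energy_intake = demo$energy_intake,
    bmi = demo$bmi,
    crp = demo$crp,
    antibiotic_use = abx,
    stratum_id = design$stratum_id,
    psu_id = design$psu_id,
    weight = design$weight
  )
  for (nm in names(diet)) cohort[[nm]] <- diet[[nm]]

  # --- modifier strata for planted effect modification (pipeline's own
  #     scoring, weighted medians on the over-45 subsample)
  modifier_low <- list(digm = rep(FALSE, n), cdai = rep(FALSE, n))
  needs <- unique(c(
    if (!is.null(config$accelerated$log_or_low)) config$accelerated$modifier,
    if (!is.null(config$diarrhea$log_or_low)) config$diarrhea$modifier))
  if (length(needs)) {
    over45 <- cohort[cohort$chronological_age > 45, , drop = FALSE]
    if ("digm" %in% needs) {
      meds <- compute_sex_medians(over45)
      sc <- compute_digm(cohort, sex_medians = meds)
      split_med <- attr(median_split(
        sc$digm[cohort$chronological_age > 45],
        over45$weight), "median")
      modifier_low$digm <- sc$digm < split_med
    }
    if ("cdai" %in% needs) {
      refs <- compute_sex_references(over45)
      sc <- compute_cdai(cohort, refs)
      split_med <- attr(median_split(
        sc$cdai[cohort$chronological_age > 45],
        over45$weight), "median")
      modifier_low$cdai <- sc$cdai < split_med
    }
  }

  # --- outcomes
  outc <- with_substream(seed, "outcomes", {
    female <- demo$sex == "female"
    # accelerated aging: marginal prevalence 1/2 (residual split semantics)
    lp_a <- planted_log_or(config$accelerated, modifier_low) * abx +
      config$accelerated$beta_female * female
    a_acc <- calibrate_intercept(lp_a, 0.5)
    accel <- stats::rbinom(n, 1, stats::plogis(a_acc + lp_a))
    # diarrhea
    lp_d <- planted_log_or(config$diarrhea, modifier_low) * abx +
      config$diarrhea$beta_female * female +
      config$diarrhea$beta_age * (demo$age - 50)
    a_d <- calibrate_intercept(lp_d, config$diarrhea$prevalence)
    diarrhea <- stats::rbinom(n, 1, stats::plogis(a_d + lp_d))
    # latent biological-age shift consistent with accelerated status
    shift <- (config$latent_shift$gap +
                abs(stats::rnorm(n, 0, config$latent_shift$sd))) *
      (2 * accel - 1)
    list(accel = accel, diarrhea = diarrhea, shift = shift)
  })
  cohort$diarrhea <- outc$diarrhea
  cohort$true_accelerated <- outc$accel
  cohort$bioage_shift <- outc$shift

  # --- biomarkers on the shifted trajectories
  bm <- with_substream(seed, "biomarkers", {
    bioage <- demo$age + outc$shift
    out <- list()
    for (i in seq_len(nrow(config$biomarker_specs))) {
      sp <- config$biomarker_specs[i, ]
      out[[sp$name]] <- sp$q_true + sp$k_true * bioage +
        stats::rnorm(n, 0, sp$s_true)
    }
    out
  })
  for (nm in names(bm)) cohort[[nm]] <- bm[[nm]]

  if (config$missing_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 config$missing_columns,
                                 seed = substream_seed(seed, "missingness"))
  }
  attr(cohort, "config") <- config
  cohort
}

#' Inject MCAR missingness
#'
#' Each targeted cell is independently set to `NA` with probability `rate`;
#' reproducible under `seed`.
#'
#' @param cohort data frame.
#' @param rate missingness probability in `[0, 1)`.
#' @param columns columns to target.
#' @param seed integer seed.
#' @return the cohort with missing cells.
#' @export
inject_missingness <- function(cohort, rate, columns, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  stop_if_missing_cols(cohort, columns)
  if (rate == 0) return(cohort)
  with_substream(seed, "inject", {
    for (nm in columns) {
      hit <- stats::runif(nrow(cohort)) < rate
      cohort[[nm]][hit] <- NA
    }
  })
  cohort
}

#' Planted odds ratios of a simulation config
#'
#' Ground truth for recovery tests: the exponential of every planted
#' log-OR, overall and per modifier stratum.
#'
#' @param config a [sim_config()].
#' @return data frame `outcome, stratum, log_or, or`.
#' @export
true_effect_summary <- function(config) {
  rows <- list()
  for (oc in c("accelerated", "diarrhea")) {
    m <- config[[oc]]
    if (!is.null(m$log_or_low)) {
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc,
        stratum = paste0(m$modifier, c("_low", "_high")),
        log_or = c(m$log_or_low, m$log_or_high))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, stratum = "overall", log_or = m$log_or)
    }
  }
  out <- do.call(rbind, rows)
  out$or <- exp(out$log_or)
  rownames(out) <- NULL
  out
}

#' Write a cohort as CSV with a column dictionary
#'
#' @param cohort from [generate_cohort()].
#' @param path CSV path; the dictionary is written next to it as
#'   `<path>.dictionary.tsv`.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  dict <- data.frame(column = names(cohort),
                     class = vapply(cohort, function(x) class(x)[1], ""))
  utils::write.table(dict, paste0(path, ".dictionary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
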