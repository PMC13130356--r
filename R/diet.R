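#' Default DI-GM component roster
#'
#' The dietary index for gut microbiota scores fourteen food groups or
#' nutrients: ten beneficial (avocado, broccoli, chickpeas, coffee,
#' cranberries, fermented dairy, fiber, green tea, soybean, whole grains)
#' and four unfavorable (red meat, processed meat, refined grains, and a
#' high-fat diet defined as 40% or more of energy from fat).  Green tea
#' intake is unavailable in NHANES-like inputs, so it is defined but not
#' scorable and the attainable score runs 0-13.
#'
#' Rules: a beneficial component scores 1 when intake is at or above the
#' sex-specific median (`median_ge`); an unfavorable component scores 1 when
#' intake is below the sex-specific median (`median_lt`); the high-fat
#' component scores 1 when the share of energy from fat is below 0.40
#' (`fat_share_lt`), reading the `fat_energy_share` column.
#'
#' @return data frame of class `digm_config` with columns
#'   `name, direction, rule, scorable` and attribute `max_score`.
#' @export
digm_config <- function() {
  comp <- rbind(
    data.frame(name = c("avocado", "broccoli", "chickpeas", "coffee",
                        "cranberries", "fermented_dairy", "fiber",
                        "green_tea", "soybean", "whole_grains"),
               direction = "beneficial", rule = "median_ge",
               scorable = TRUE),
    data.frame(name = c("red_meat", "processed_meat", "refined_grains"),
               direction = "unfavorable", rule = "median_lt",
               scorable = TRUE),
    data.frame(name = "high_fat_diet", direction = "unfavorable",
               rule = "fat_share_lt", scorable = TRUE)
  )
  comp$scorable[comp$name == "green_tea"] <- FALSE
  attr(comp, "max_score") <- sum(comp$scorable)
  class(comp) <- c("digm_config", class(comp))
  comp
}

#' CDAI nutrient set
#'
#' The six antioxidant nutrients entering the composite dietary antioxidant
#' index: vitamins A, C, and E, beta-carotene, selenium, and zinc.
#'
#' @return character vector of column names.
#' @export
cdai_nutrients <- function() {
  c("vitamin_a", "vitamin_c", "vitamin_e", "beta_carotene", "selenium", "zinc")
}

#' Sex-specific reference means and scales for CDAI
#'
#' Computes, per sex and nutrient, the sample mean and a scale: the standard
#' error of the mean (`SE`, the default, following the index definition used
#' here) or the standard deviation (`SD`, the convention in much of the CDAI
#' literature).  The choice is recorded in the output so downstream metadata
#' can state it.
#'
#' @param cohort data frame with a `sex` column (`"male"`/`"female"`) and the
#'   nutrient columns; references are computed on the rows supplied, so pass
#'   the analytic sample.
#' @param nutrient_names default [cdai_nutrients()].
#' @param scale_kind `"SE"` or `"SD"`.
#' @return data frame of class `cdai_config`: `sex, nutrient, mean, scale`
#'   with attribute `scale_kind`.
#' @export
compute_sex_references <- function(cohort, nutrient_names = cdai_nutrients(),
                                   scale_kind = c("SE", "SD")) {
  scale_kind <- match.arg(scale_kind)
  stop_if_missing_cols(cohort, c("sex", nutrient_names))
  sexes <- sort(unique(cohort$sex))
  rows <- list()
  for (sx in sexes) {
    sub <- cohort[cohort$sex == sx, , drop = FALSE]
    for (nm in nutrient_names) {
      v <- sub[[nm]][!is.na(sub[[nm]])]
      if (length(v) < 2L) stop(sprintf("sex '%s' has fewer than 2 records for '%s'", sx, nm))
      sdv <- stats::sd(v)
      sc <- if (scale_kind == "SE") sdv / sqrt(length(v)) else sdv
      if (sc == 0) stop(sprintf("degenerate nutrient '%s' (zero variance) for sex '%s'", nm, sx))
      rows[[length(rows) + 1L]] <- data.frame(sex = sx, nutrient = nm,
                                              mean = mean(v), scale = sc)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scale_kind") <- scale_kind
  class(out) <- c("cdai_config", class(out))
  out
}

#' Composite dietary antioxidant index
#'
#' \deqn{CDAI = \sum_{i=1}^{6} \frac{intake_i - Mean_i}{Scale_i}}
#' with sex-specific references.  Records missing any nutrient are excluded
#' (complete-case) and their count reported via the `n_excluded` attribute.
#'
#' @param cohort data frame with `participant_id`, `sex` and the nutrient
#'   columns.
#' @param references `cdai_config` from [compute_sex_references()].
#' @return data frame `participant_id, cdai` with attribute `n_excluded`.
#' @export
compute_cdai <- function(cohort, references) {
  nutrients <- unique(references$nutrient)
  stop_if_missing_cols(cohort, c("participant_id", "sex", nutrients))
  complete <- stats::complete.cases(cohort[, nutrients, drop = FALSE]) & !is.na(cohort$sex)
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("compute_cdai: %d record(s) missing a nutrient excluded", n_excluded))
  }
  dat <- cohort[complete, , drop = FALSE]
  score <- rep(0, nrow(dat))
  for (nm in nutrients) {
    ref <- references[references$nutrient == nm, ]
    m <- ref$mean[match(dat$sex, ref$sex)]
    sc <- ref$scale[match(dat$sex, ref$sex)]
    if (anyNA(m)) stop(sprintf("no reference for some sex level in nutrient '%s'", nm))
    score <- score + (dat[[nm]] - m) / sc
  }
  out <- data.frame(participant_id = dat$participant_id, cdai = score)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Sex-specific component medians for DI-GM scoring
#'
#' Weighted (default) or unweighted medians of every median-ruled component,
#' per sex, computed on the rows supplied.
#'
#' @param cohort data frame with `sex`, the component intake columns, and
#'   (if `weighted`) a `weight` column.
#' @param config `digm_config`.
#' @param weighted use the survey weights for the medians.
#' @return data frame `sex, component, median`.
#' @export
compute_sex_medians <- function(cohort, config = digm_config(), weighted = TRUE) {
  comps <- config$name[config$scorable & config$rule %in% c("median_ge", "median_lt")]
  stop_if_missing_cols(cohort, c("sex", comps, if (weighted) "weight"))
  rows <- list()
  for (sx in sort(unique(cohort$sex))) {
    sub <- cohort[cohort$sex == sx, , drop = FALSE]
    for (nm in comps) {
      keep <- !is.na(sub[[nm]])
      med <- weighted_median(sub[[nm]][keep],
                             if (weighted) sub$weight[keep] else NULL)
      rows[[length(rows) + 1L]] <- data.frame(sex = sx, component = nm, median = med)
    }
  }
  do.call(rbind, rows)
}

#' Dietary index for gut microbiota
#'
#' Sums binary component scores: beneficial components score 1 at or above
#' the sex-specific median, unfavorable components score 1 below it, and the
#' high-fat component scores 1 when the fat energy share is below
#' `fat_share_cutoff`.  Unscorable components contribute 0.  Records missing
#' any scorable component are excluded (complete-case) with the count in the
#' `n_excluded` attribute.
#'
#' @param cohort data frame with `participant_id`, `sex`, scorable component
#'   columns and `fat_energy_share`.
#' @param config `digm_config`.
#' @param sex_medians from [compute_sex_medians()]; computed from `cohort`
#'   (weighted) when `NULL`.
#' @param fat_share_cutoff energy-share threshold for the high-fat rule.
#' @return data frame `participant_id, digm` with attribute `n_excluded`.
#' @export
compute_digm <- function(cohort, config = digm_config(), sex_medians = NULL,
                         fat_share_cutoff = 0.40) {
  scorable <- config[config$scorable, , drop = FALSE]
  med_comps <- scorable$name[scorable$rule %in% c("median_ge", "median_lt")]
  needs_fat <- any(scorable$rule == "fat_share_lt")
  cols <- c(med_comps, if (needs_fat) "fat_energy_share")
  stop_if_missing_cols(cohort, c("participant_id", "sex", cols))
  if (is.null(sex_medians)) sex_medians <- compute_sex_medians(cohort, config)

  complete <- stats::complete.cases(cohort[, cols, drop = FALSE]) & !is.na(cohort$sex)
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("compute_digm: %d record(s) missing a scorable component excluded", n_excluded))
  }
  dat <- cohort[complete, , drop = FALSE]
  score <- rep(0L, nrow(dat))
  for (i in seq_len(nrow(scorable))) {
    nm <- scorable$name[i]
    rule <- scorable$rule[i]
    if (rule == "fat_share_lt") {
      score <- score + as.integer(dat$fat_energy_share < fat_share_cutoff)
    } else {
      sm <- sex_medians[sex_medians$component == nm, ]
      med <- sm$median[match(dat$sex, sm$sex)]
      if (anyNA(med)) stop(sprintf("no sex median for component '%s'", nm))
      hit <- if (rule == "median_ge") dat[[nm]] >= med else dat[[nm]] < med
      score <- score + as.integer(hit)
    }
  }
  out <- data.frame(participant_id = dat$participant_id, digm = score)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "max_score") <- attr(config, "max_score")
  out
}

#' Median split of a score
#'
#' Dichotomizes at the (survey-weighted, by default) median; values at or
#' above the median are labeled `"high"`, values below `"low"`.
#'
#' @param values numeric score per record.
#' @param weights optional positive weights; `NULL` for an unweighted split.
#' @return factor with levels `low, high` (NA preserved) and attribute
#'   `median`.
#' @export
median_split <- function(values, weights = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  med <- weighted_median(values[ok], if (!is.null(weights)) weights[ok])
  if (all(values[ok] == values[ok][1])) {
    warning("all values identical: every record labeled 'high'")
  }
  lab <- ifelse(values >= med, "high", "low")
  out <- factor(lab, levels = c("low", "high"))
  attr(out, "median") <- med
  out
}
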