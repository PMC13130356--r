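# Independent oracles and small fixture builders shared across tests.

# Naive per-record evaluation of the KDM formula, written as a plain loop so
# it shares no code path with compute_kdm().
naive_kdm <- function(model, cohort) {
  out <- numeric(nrow(cohort))
  for (r in seq_len(nrow(cohort))) {
    num <- cohort$chronological_age[r] / model$s_ba^2
    den <- 1 / model$s_ba^2
    for (i in seq_len(nrow(model$fits))) {
      q <- model$fits$q[i]; k <- model$fits$k[i]; s <- model$fits$s[i]
      x <- cohort[[model$fits$name[i]]][r]
      num <- num + (x - q) * k / s^2
      den <- den + k^2 / s^2
    }
    out[r] <- num / den
  }
  out
}

# Closed-form simple OLS: intercept, slope, residuals.
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  list(intercept = a, slope = b, residuals = y - (a + b * x))
}

# Attach a trivial one-stratum, record-per-PSU, equal-weight design.
with_iid_design <- function(df) {
  df$stratum_id <- 1L
  df$psu_id <- seq_len(nrow(df))
  df$weight <- 1
  df
}

# 2x2 table expanded to records: counts (case_exp, noncase_exp, case_unexp,
# noncase_unexp), optionally as weights on 4 records instead.
expand_2x2 <- function(a, b, c, d) {
  with_iid_design(data.frame(
    y = rep(c(1, 0, 1, 0), times = c(a, b, c, d)),
    x = rep(c(1, 1, 0, 0), times = c(a, b, c, d))))
}

# A small random cohort with valid biomarker columns for KDM property tests.
# Includes true biological-age dispersion (SD 5 years) around chronological
# age so the fitted s_ba is well away from its floor.
random_kdm_cohort <- function(n, seed, specs = default_biomarker_specs()) {
  set.seed(seed)
  age <- runif(n, 30, 80)
  bioage <- age + rnorm(n, 0, 5)
  co <- data.frame(participant_id = seq_len(n), chronological_age = age)
  for (i in seq_len(nrow(specs))) {
    co[[specs$name[i]]] <- specs$q_true[i] + specs$k_true[i] * bioage +
      rnorm(n, 0, specs$s_true[i])
  }
  co
}

# A custom 3-component DI-GM config (2 beneficial, 1 unfavorable).
toy_digm_config <- function() {
  comp <- data.frame(
    name = c("ben1", "ben2", "unf1"),
    direction = c("beneficial", "beneficial", "unfavorable"),
    rule = c("median_ge", "median_ge", "median_lt"),
    scorable = TRUE)
  attr(comp, "max_score") <- 3L
  class(comp) <- c("digm_config", class(comp))
  comp
}

# Build one record that scores exactly `hits` of the 13 scorable default
# DI-GM components, given sex medians `med` (a single value used for every
# component) -- used for the bounds enumeration.
digm_record_with_score <- function(hits, med = 10) {
  cfg <- digm_config()
  scorable <- cfg[cfg$scorable, ]
  rec <- data.frame(participant_id = 1L, sex = "female")
  take <- rep(FALSE, nrow(scorable))
  take[seq_len(hits)] <- TRUE
  for (i in seq_len(nrow(scorable))) {
    nm <- scorable$name[i]
    if (scorable$rule[i] == "fat_share_lt") {
      rec$fat_energy_share <- if (take[i]) 0.30 else 0.55
    } else if (scorable$rule[i] == "median_ge") {
      rec[[nm]] <- if (take[i]) med else med / 2
    } else {
      rec[[nm]] <- if (take[i]) med / 2 else med * 2
    }
  }
  # unscorable components need no column
  rec
}

flat_sex_medians <- function(med = 10) {
  cfg <- digm_config()
  comps <- cfg$name[cfg$scorable & cfg$rule != "fat_share_lt"]
  expand.grid(sex = c("female", "male"), component = comps,
              stringsAsFactors = FALSE) |>
    transform(median = med)
}
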