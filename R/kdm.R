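#' Biomarkers used for KDM biological age
#'
#' The ten blood-chemistry and examination biomarkers conventionally used to
#' train the Klemera-Doubal estimator on NHANES-style cohorts: systolic blood
#' pressure, albumin, alkaline phosphatase, blood urea nitrogen, creatinine,
#' glycated hemoglobin, total cholesterol, lymphocyte percent, white blood
#' cell count, and mean cell volume.
#'
#' @return character vector of column names.
#' @export
kdm_biomarkers <- function() {
  c("sbp", "albumin", "alkaline_phosphatase", "bun", "creatinine",
    "hba1c", "total_cholesterol", "lymphocyte_pct", "wbc", "mcv")
}

#' Per-biomarker regressions on chronological age
#'
#' Fits ordinary least squares of each biomarker on chronological age and
#' returns, per biomarker, the intercept `q`, slope `k` (units per year) and
#' residual root mean squared error `s`.  These are the building blocks of
#' the Klemera-Doubal estimator: a biomarker's contribution weight is
#' `k^2/s^2`, so a flat trajectory (`k = 0`) carries zero weight.
#'
#' @param cohort data frame with a `chronological_age` column and the
#'   biomarker columns; rows with a missing age or missing biomarker are
#'   dropped per biomarker (complete-case).
#' @param biomarker_names columns to fit; default [kdm_biomarkers()].
#' @param rmse_divisor `"n"` (population RMSE, the default) or `"n-2"`
#'   (unbiased residual variance).
#' @param s_floor lower bound on each fitted RMSE (biomarker units).  A
#'   perfectly deterministic trajectory would give `s = 0` and an
#'   unevaluable `1/s^2` weight; the floor keeps the noiseless limit
#'   well-defined (the KDM mean-trajectory identity holds for any s > 0).
#' @return data frame of class `biomarker_fits` with columns
#'   `name, q, k, s, n_train`.
#' @export
fit_biomarker_regressions <- function(cohort,
                                      biomarker_names = kdm_biomarkers(),
                                      rmse_divisor = c("n", "n-2"),
                                      s_floor = 1e-8) {
  rmse_divisor <- match.arg(rmse_divisor)
  stop_if_missing_cols(cohort, c("chronological_age", biomarker_names))
  fits <- lapply(biomarker_names, function(nm) {
    keep <- !is.na(cohort$chronological_age) & !is.na(cohort[[nm]])
    ca <- cohort$chronological_age[keep]
    x <- cohort[[nm]][keep]
    n <- length(ca)
    if (n < 3L) stop(sprintf("biomarker '%s': fewer than 3 complete records", nm))
    if (stats::var(ca) == 0) stop("degenerate age column: chronological age is constant")
    k <- stats::cov(ca, x) / stats::var(ca)
    q <- mean(x) - k * mean(ca)
    rss <- sum((x - (q + k * ca))^2)
    s <- max(sqrt(rss / if (rmse_divisor == "n") n else (n - 2L)), s_floor)
    if (k == 0) {
      warning(sprintf("biomarker '%s' has zero slope on age and carries zero KDM weight", nm))
    }
    data.frame(name = nm, q = q, k = k, s = s, n_train = n)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("biomarker_fits", class(out))
  out
}

#' Scaling factor s_BA of the KDM estimator
#'
#' `s_BA` governs how strongly chronological age anchors the KDM score; it is
#' interpreted as the standard deviation of true biological-age deviation
#' from chronological age.  The default estimator is a variance
#' decomposition: form the unscaled biomarker-only estimate
#' `BA_E = sum((x_i - q_i) k_i / s_i^2) / sum(k_i^2 / s_i^2)` per
#' participant, then subtract the estimation-noise variance
#' `1 / sum(k_i^2 / s_i^2)` from `Var(BA_E - CA)` and take the square root,
#' floored at `sqrt(eps)`.
#'
#' @param cohort complete-case training data.
#' @param fits `biomarker_fits` from [fit_biomarker_regressions()].
#' @param eps variance floor (years squared).
#' @return scalar `s_ba` (years) with attribute `method`.
#' @export
estimate_sba <- function(cohort, fits, eps = 1e-6) {
  prec <- sum(fits$k^2 / fits$s^2)
  if (prec == 0) stop("no informative biomarkers: all slopes are zero")
  ba_e <- kdm_ba_e(cohort, fits)
  keep <- !is.na(ba_e) & !is.na(cohort$chronological_age)
  v <- stats::var(ba_e[keep] - cohort$chronological_age[keep])
  sba2 <- v - 1 / prec
  if (sba2 < eps) {
    warning("explained-variance estimate at or below the floor; s_ba set to sqrt(eps)")
    sba2 <- eps
  }
  out <- sqrt(sba2)
  attr(out, "method") <- "variance_decomposition"
  out
}

# unscaled biomarker-only estimate BA_E; NA where any model biomarker missing
kdm_ba_e <- function(cohort, fits) {
  prec <- sum(fits$k^2 / fits$s^2)
  num <- rep(0, nrow(cohort))
  for (i in seq_len(nrow(fits))) {
    x <- cohort[[fits$name[i]]]
    num <- num + (x - fits$q[i]) * fits$k[i] / fits$s[i]^2
  }
  num / prec
}

#' Assemble a KDM model
#'
#' @param fits `biomarker_fits`.
#' @param s_ba positive scaling factor (years); from [estimate_sba()] or a
#'   fixed value for strict reproduction of another implementation.
#' @return object of class `kdm_model`.
#' @export
kdm_model <- function(fits, s_ba) {
  method <- attr(s_ba, "method")
  s_ba <- as.numeric(s_ba)
  if (!is.finite(s_ba) || s_ba <= 0) stop("s_ba must be a positive number")
  if (all(fits$k == 0)) stop("no informative biomarkers: all slopes are zero")
  structure(list(fits = fits, s_ba = s_ba,
                 sba_method = if (is.null(method)) "fixed" else method),
            class = "kdm_model")
}

#' Train a KDM model on a cohort
#'
#' Convenience wrapper: per-biomarker regressions plus the s_BA estimate on
#' the same (complete-case) training sample.
#'
#' @inheritParams fit_biomarker_regressions
#' @param s_ba optional fixed value overriding the estimator.
#' @return `kdm_model`.
#' @export
fit_kdm <- function(cohort, biomarker_names = kdm_biomarkers(),
                    rmse_divisor = c("n", "n-2"), s_ba = NULL) {
  complete <- stats::complete.cases(cohort[, c("chronological_age", biomarker_names)])
  train <- cohort[complete, , drop = FALSE]
  fits <- fit_biomarker_regressions(train, biomarker_names, rmse_divisor)
  if (is.null(s_ba)) s_ba <- estimate_sba(train, fits)
  kdm_model(fits, s_ba)
}

#' @export
print.kdm_model <- function(x, ...) {
  cat(sprintf("KDM model: %d biomarkers, s_ba = %.4f years (%s)\n",
              nrow(x$fits), x$s_ba, x$sba_method))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Klemera-Doubal biological age
#'
#' Evaluates, per record,
#' \deqn{KDM = \frac{\sum_i (x_i - q_i) k_i / s_i^2 + CA / s_{BA}^2}
#'                  {\sum_i k_i^2 / s_i^2 + 1 / s_{BA}^2}}
#' A record lying exactly on every fitted mean trajectory scores its own
#' chronological age.  Records missing any model biomarker (or age) are
#' excluded from the scores and their count reported via the
#' `n_excluded` attribute.
#'
#' @param model `kdm_model`.
#' @param cohort data frame with `participant_id`, `chronological_age`, and
#'   the model's biomarker columns.
#' @return data frame `participant_id, kdm_age` with attribute `n_excluded`.
#' @export
compute_kdm <- function(model, cohort) {
  stopifnot(inherits(model, "kdm_model"))
  stop_if_missing_cols(cohort, c("participant_id", "chronological_age", model$fits$name))
  complete <- stats::complete.cases(
    cohort[, c("chronological_age", model$fits$name), drop = FALSE])
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("compute_kdm: %d record(s) missing a model biomarker excluded", n_excluded))
  }
  dat <- cohort[complete, , drop = FALSE]
  fits <- model$fits
  num <- dat$chronological_age / model$s_ba^2
  den <- sum(fits$k^2 / fits$s^2) + 1 / model$s_ba^2
  for (i in seq_len(nrow(fits))) {
    num <- num + (dat[[fits$name[i]]] - fits$q[i]) * fits$k[i] / fits$s[i]^2
  }
  out <- data.frame(participant_id = dat$participant_id, kdm_age = num / den)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Age acceleration from KDM scores
#'
#' Age acceleration is the residual of KDM biological age regressed (OLS,
#' with intercept) on chronological age over the scored sample; residuals
#' therefore average zero on that sample.  `accelerated` flags residuals
#' above `threshold` (default 0, i.e. older-than-expected physiology).
#'
#' @param scores output of [compute_kdm()].
#' @param cohort cohort carrying `participant_id` and `chronological_age`.
#' @param threshold residual cutoff in years for the binary flag.
#' @return `scores` with `acceleration` (years) and `accelerated` (0/1).
#' @export
compute_age_acceleration <- function(scores, cohort, threshold = 0) {
  stop_if_missing_cols(scores, c("participant_id", "kdm_age"), "scores")
  ca <- cohort$chronological_age[match(scores$participant_id, cohort$participant_id)]
  if (nrow(scores) < 3L) stop("need at least 3 scored records")
  if (stats::var(ca) == 0) stop("degenerate age column: chronological age is constant")
  b <- stats::cov(ca, scores$kdm_age) / stats::var(ca)
  a <- mean(scores$kdm_age) - b * mean(ca)
  scores$acceleration <- scores$kdm_age - (a + b * ca)
  scores$accelerated <- as.integer(scores$acceleration > threshold)
  scores
}

#' Write / read a KDM model as a plain-text key-value file
#'
#' Serializes the per-biomarker `(q, k, s)` table and `s_ba` at full
#' precision so scoring is reproducible bit-for-bit across runs.
#'
#' @param model `kdm_model`.
#' @param path file path.
#' @return `path` (write) or a `kdm_model` (read).
#' @export
write_kdm_model <- function(model, path) {
  lines <- c(
    sprintf("s_ba\t%.17g", model$s_ba),
    sprintf("sba_method\t%s", model$sba_method),
    "biomarker\tq\tk\ts\tn_train",
    sprintf("%s\t%.17g\t%.17g\t%.17g\t%d",
            model$fits$name, model$fits$q, model$fits$k, model$fits$s,
            model$fits$n_train)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kdm_model
#' @export
read_kdm_model <- function(path) {
  lines <- readLines(path)
  s_ba <- as.numeric(strsplit(lines[1], "\t")[[1]][2])
  method <- strsplit(lines[2], "\t")[[1]][2]
  tab <- utils::read.delim(text = lines[-(1:2)], stringsAsFactors = FALSE)
  fits <- data.frame(name = tab$biomarker, q = tab$q, k = tab$k, s = tab$s,
                     n_train = tab$n_train)
  class(fits) <- c("biomarker_fits", class(fits))
  m <- kdm_model(fits, s_ba)
  m$sba_method <- method
  m
}
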