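#' Combine sampling weights across survey cycles
#'
#' When several release cycles are pooled, each record's weight is divided by
#' the number of cycles so the combined weights still sum to (one copy of)
#' the target population.
#'
#' @param weights positive sampling weights.
#' @param n_cycles number of cycles pooled (>= 1).
#' @return adjusted weights.
#' @export
combine_cycle_weights <- function(weights, n_cycles) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite")
  }
  weights / n_cycles
}

#' Survey-weighted logistic regression with Taylor-linearized variance
#'
#' Point estimates maximize the weighted pseudo-log-likelihood via
#' iteratively reweighted least squares (gradient sup-norm tolerance
#' `tol`, weights normalized internally so the criterion is scale-free).
#' The covariance is the design-based sandwich: weighted score totals are
#' aggregated per primary sampling unit (PSU), centered within stratum, and
#' their between-PSU covariance accumulated with the small-sample factor
#' `n_h / (n_h - 1)` per stratum.  A stratum containing a single PSU is
#' centered at the grand mean of PSU totals (the "adjust" convention) and
#' logged.  Confidence intervals use the normal 1.96 quantile by default;
#' `ci = "t"` uses the t distribution with design degrees of freedom
#' (PSUs minus strata).
#'
#' Rows with a missing value anywhere in the model frame are dropped
#' (complete-case) and counted in `n_dropped`.
#'
#' @param formula model formula, e.g. `outcome ~ exposure + age + sex`.
#' @param data data frame containing the model variables and design columns.
#' @param strata,psu,weights names of the design columns in `data`.
#' @param ci `"normal"` or `"t"`.
#' @param level confidence level.
#' @param max_iter,tol IRLS controls.
#' @return object of class `svylogit`: `term, beta, se, or, ci_low, ci_high,
#'   p_value` in `$table`, plus `beta`, `cov`, `n_used`, `n_dropped`,
#'   `design_df`, `converged`, `n_iter`.
#' @export
fit_survey_logistic <- function(formula, data, strata = "stratum_id",
                                psu = "psu_id", weights = "weight",
                                ci = c("normal", "t"), level = 0.95,
                                max_iter = 100L, tol = 1e-8) {
  ci <- match.arg(ci)
  stop_if_missing_cols(data, c(strata, psu, weights))
  vars <- all.vars(formula)
  stop_if_missing_cols(data, vars)
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!keep)
  dat <- data[keep, , drop = FALSE]

  mf <- stats::model.frame(formula, dat)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  w_raw <- dat[[weights]]
  if (any(!is.finite(w_raw)) || any(w_raw <= 0)) stop("weights must be positive and finite")
  # normalize to mean 1: point estimates and the sandwich are invariant to
  # the weight scale, and the gradient tolerance becomes scale-free
  w <- w_raw / mean(w_raw)
  n <- length(y)
  p_terms <- ncol(X)

  beta <- rep(0, p_terms)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, w * (y - mu)))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    mu_c <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    wirls <- w * mu_c * (1 - mu_c)
    if (max(abs(beta)) > 15 && any(mu_c <= 1e-10 | mu_c >= 1 - 1e-10)) break
    fit <- tryCatch(
      stats::lm.wfit(X, eta + (y - mu_c) / (mu_c * (1 - mu_c)), wirls),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      stop("weighted IRLS failed: singular information matrix (collinear terms?)")
    }
    beta <- fit$coefficients
  }
  # under (quasi-)complete separation the pseudo-likelihood gradient itself
  # vanishes while coefficients diverge, so the trigger is the magnitude
  bad <- which(abs(beta) > 15)
  if (length(bad)) {
    stop(sprintf("separation detected: coefficient(s) diverging for term(s) %s",
                 paste(colnames(X)[bad], collapse = ", ")))
  }
  if (!converged) {
    warning("IRLS did not meet the gradient tolerance within max_iter")
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # observed information of the pseudo-log-likelihood
  A <- crossprod(X * sqrt(w * mu * (1 - mu)))
  # per-record scores, aggregated to PSU totals within strata
  U <- X * (w * (y - mu))
  stratum <- as.character(dat[[strata]])
  psu_id <- paste(stratum, as.character(dat[[psu]]), sep = "\r")
  Z <- rowsum(U, group = psu_id, reorder = FALSE)
  z_stratum <- stratum[!duplicated(psu_id)][match(rownames(Z), unique(psu_id))]
  B <- matrix(0, p_terms, p_terms)
  grand <- colMeans(Z)
  singletons <- character(0)
  for (h in unique(z_stratum)) {
    Zh <- Z[z_stratum == h, , drop = FALSE]
    nh <- nrow(Zh)
    if (nh == 1L) {
      singletons <- c(singletons, h)
      d <- Zh[1, ] - grand
      B <- B + tcrossprod(d)
    } else {
      C <- sweep(Zh, 2, colMeans(Zh))
      B <- B + (nh / (nh - 1)) * crossprod(C)
    }
  }
  if (length(singletons)) {
    message(sprintf("fit_survey_logistic: %d singleton-PSU stratum(s) centered at the grand mean: %s",
                    length(singletons), paste(singletons, collapse = ", ")))
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2

  se <- sqrt(pmax(diag(V), 0))
  design_df <- length(unique(psu_id)) - length(unique(stratum))
  qq <- if (ci == "normal") stats::qnorm(1 - (1 - level) / 2) else {
    if (design_df < 1) stop("design df < 1: cannot form t intervals")
    stats::qt(1 - (1 - level) / 2, df = design_df)
  }
  zstat <- ifelse(se > 0, beta / se, NA_real_)
  table <- data.frame(
    term = colnames(X),
    beta = unname(beta),
    se = se,
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - qq * se),
    ci_high = exp(unname(beta) + qq * se),
    p_value = 2 * stats::pnorm(-abs(zstat)),
    row.names = NULL
  )
  structure(list(table = table, beta = stats::setNames(unname(beta), colnames(X)),
                 cov = V, n_used = n, n_dropped = n_dropped,
                 design_df = design_df, converged = converged, n_iter = iter,
                 formula = formula, ci = ci, level = level),
            class = "svylogit")
}

#' @export
print.svylogit <- function(x, digits = 3, ...) {
  cat(sprintf("Survey-weighted logistic regression (n = %d, %d dropped; design df = %d)\n",
              x$n_used, x$n_dropped, x$design_df))
  tab <- x$table
  tab$beta <- round(tab$beta, digits); tab$se <- round(tab$se, digits)
  tab$or <- round(tab$or, digits)
  tab$ci_low <- round(tab$ci_low, digits); tab$ci_high <- round(tab$ci_high, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Forest-style table of odds ratios for one term across models
#'
#' @param results named list of `svylogit` fits (names label the rows).
#' @param focus_term term whose OR is extracted, e.g. `"antibiotic_use"`.
#' @return data frame: `model, term, or, ci_low, ci_high, p_value, n,
#'   or_display` (rounded 2-decimal display column; full precision retained).
#' @export
odds_ratio_table <- function(results, focus_term) {
  if (is.null(names(results))) names(results) <- paste0("model_", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (is.null(r) || is.null(r$table)) {
      return(data.frame(model = nm, term = focus_term, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, n = NA_integer_,
                        or_display = "not estimable"))
    }
    i <- match(focus_term, r$table$term)
    if (is.na(i)) stop(sprintf("term '%s' absent from model '%s'", focus_term, nm))
    t <- r$table[i, ]
    data.frame(model = nm, term = focus_term, or = t$or, ci_low = t$ci_low,
               ci_high = t$ci_high, p_value = t$p_value, n = r$n_used,
               or_display = sprintf("%.2f (%.2f-%.2f)", t$or, t$ci_low, t$ci_high))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
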