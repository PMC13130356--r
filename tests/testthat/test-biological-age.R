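test_that("biomarker regression matches the closed-form OLS oracle", {
  co <- data.frame(participant_id = 1:3, chronological_age = c(40, 50, 60),
                   marker = c(10, 20, 24))
  fit <- fit_biomarker_regressions(co, "marker")
  oracle <- ols_oracle(co$chronological_age, co$marker)
  expect_equal(fit$k, 0.7)
  expect_equal(fit$q, -17)
  expect_equal(fit$k, oracle$slope)
  expect_equal(fit$s, sqrt(sum(oracle$residuals^2) / 3))
  expect_equal(fit$s, sqrt(2))
  # n-2 divisor option
  fit2 <- fit_biomarker_regressions(co, "marker", rmse_divisor = "n-2")
  expect_equal(fit2$s, sqrt(6 / 1))
})

test_that("degenerate regressions are caught or flagged", {
  noiseless <- data.frame(participant_id = 1:4, chronological_age = c(40, 50, 60, 70))
  noiseless$marker <- 2 + 0.5 * noiseless$chronological_age
  fit <- fit_biomarker_regressions(noiseless, "marker")
  expect_equal(fit$q, 2)
  expect_equal(fit$k, 0.5)
  expect_lte(fit$s, 1e-7)

  flat <- data.frame(participant_id = 1:4, chronological_age = c(40, 50, 60, 70),
                     marker = 5)
  expect_warning(fitf <- fit_biomarker_regressions(flat, "marker"), "zero KDM weight")
  expect_equal(fitf$k, 0)

  const_age <- data.frame(participant_id = 1:4, chronological_age = 50,
                          marker = c(1, 2, 3, 4))
  expect_error(fit_biomarker_regressions(const_age, "marker"), "degenerate age")
  expect_error(fit_biomarker_regressions(noiseless[1:2, ], "marker"), "fewer than 3")
})

test_that("s_ba variance decomposition matches the direct-evaluation oracle", {
  fits <- data.frame(name = "marker", q = 0, k = 1, s = 1, n_train = 3)
  co <- data.frame(participant_id = 1:2, chronological_age = c(40, 60),
                   marker = c(41, 59))
  # BA_E = {41, 59}; Var(BA_E - CA) = 2; estimation noise 1/sum(k^2/s^2) = 1
  expect_equal(as.numeric(estimate_sba(co, fits)), 1)
  # degenerate limit: records exactly on the trajectory -> floor + warning
  co_exact <- data.frame(participant_id = 1:3, chronological_age = c(40, 50, 60))
  co_exact$marker <- co_exact$chronological_age
  expect_warning(sba <- estimate_sba(co_exact, fits), "floor")
  expect_equal(as.numeric(sba), sqrt(1e-6))
  # all-zero slopes are rejected
  expect_error(estimate_sba(co, transform(fits, k = 0)), "no informative")
})

test_that("compute_kdm evaluates the estimator formula exactly", {
  fits <- data.frame(name = c("m1", "m2"), q = c(0, 10), k = c(1, 2),
                     s = c(1, 2), n_train = 10)
  model <- kdm_model(fits, s_ba = 10)
  co <- data.frame(participant_id = 1, chronological_age = 50, m1 = 57, m2 = 100)
  expect_equal(compute_kdm(model, co)$kdm_age, 102.5 / 2.01, tolerance = 1e-12)

  # mean-trajectory identity for arbitrary s_ba
  co_traj <- data.frame(participant_id = 1:3, chronological_age = c(35, 60, 82))
  co_traj$m1 <- 0 + 1 * co_traj$chronological_age
  co_traj$m2 <- 10 + 2 * co_traj$chronological_age
  for (sba in c(0.5, 10, 1e4)) {
    scores <- compute_kdm(kdm_model(fits, sba), co_traj)
    expect_lt(max(abs(scores$kdm_age - co_traj$chronological_age)), 1e-9)
  }

  # limits: s_ba -> Inf gives the pure biomarker estimate, s_ba -> 0 gives CA
  co_off <- data.frame(participant_id = 1, chronological_age = 50, m1 = 60, m2 = 130)
  ba_e <- ((60 - 0) * 1 / 1 + (130 - 10) * 2 / 4) / (1 + 1)
  expect_equal(compute_kdm(kdm_model(fits, 1e8), co_off)$kdm_age, ba_e,
               tolerance = 1e-6)
  expect_equal(compute_kdm(kdm_model(fits, 1e-8), co_off)$kdm_age, 50,
               tolerance = 1e-6)

  # records missing a biomarker are excluded and counted
  co_miss <- rbind(co, data.frame(participant_id = 2, chronological_age = 55,
                                  m1 = NA, m2 = 100))
  expect_message(scores <- compute_kdm(model, co_miss), "1 record")
  expect_equal(nrow(scores), 1L)
  expect_equal(attr(scores, "n_excluded"), 1L)
})

test_that("compute_kdm agrees with a naive formula evaluation on random records", {
  co <- random_kdm_cohort(1000, seed = 31)
  model <- fit_kdm(co)
  expect_lt(max(abs(compute_kdm(model, co)$kdm_age - naive_kdm(model, co))), 1e-10)
})

test_that("KDM scores are invariant to affine biomarker rescaling", {
  co <- random_kdm_cohort(400, seed = 17)
  base <- compute_kdm(fit_kdm(co), co)
  tr <- co
  a <- c(2.5, -1, 0.03, 10, 4, 0.5, 1.7, -3, 2, 0.25)
  b <- c(-7, 3, 100, 0, 1, 2, -50, 8, 0, 40)
  for (i in seq_along(kdm_biomarkers())) {
    nm <- kdm_biomarkers()[i]
    tr[[nm]] <- a[i] * co[[nm]] + b[i]
  }
  refit <- compute_kdm(fit_kdm(tr), tr)
  expect_lt(max(abs(refit$kdm_age - base$kdm_age)), 1e-8)
})

test_that("a zero-slope biomarker carries zero weight", {
  co <- random_kdm_cohort(200, seed = 23)
  model <- fit_kdm(co)
  with_flat <- model
  with_flat$fits <- rbind(with_flat$fits,
                          data.frame(name = "flat", q = 5, k = 0, s = 2, n_train = 200))
  co$flat <- 5 + rnorm(200, 0, 2)
  expect_equal(compute_kdm(with_flat, co)$kdm_age, compute_kdm(model, co)$kdm_age,
               tolerance = 1e-12)
})

test_that("age acceleration is the OLS residual with the stated properties", {
  co <- data.frame(participant_id = 1:3, chronological_age = c(40, 50, 60))
  scores <- data.frame(participant_id = 1:3,
                       kdm_age = co$chronological_age + c(2, -2, 0))
  out <- compute_age_acceleration(scores, co)
  oracle <- ols_oracle(co$chronological_age, scores$kdm_age)
  expect_equal(oracle$slope, 0.9)
  expect_equal(out$acceleration, oracle$residuals)
  expect_equal(sum(out$acceleration), 0, tolerance = 1e-12)
  expect_equal(out$accelerated, as.integer(oracle$residuals > 0))

  # kdm identically CA: no residuals, nobody accelerated
  same <- data.frame(participant_id = 1:3, kdm_age = co$chronological_age)
  out2 <- compute_age_acceleration(same, co)
  expect_equal(out2$acceleration, rep(0, 3))
  expect_equal(out2$accelerated, rep(0L, 3))

  # residuals over a larger scored sample average zero
  co_big <- random_kdm_cohort(500, seed = 41)
  sc <- compute_age_acceleration(compute_kdm(fit_kdm(co_big), co_big), co_big)
  expect_lt(abs(mean(sc$acceleration)), 1e-8)
})

test_that("trained parameters are recovered on a linear-Gaussian cohort", {
  specs <- default_biomarker_specs()
  cfg <- sim_config(n_participants = 10000, latent_shift = list(gap = 1e-9, sd = 0),
                    seed = 51)
  co <- generate_cohort(cfg)
  fits <- fit_biomarker_regressions(co)
  n <- nrow(co)
  for (i in seq_len(nrow(specs))) {
    f <- summary(lm(co[[specs$name[i]]] ~ co$chronological_age))$coefficients
    expect_lt(abs(fits$k[i] - specs$k_true[i]), 3 * f[2, 2])
    expect_lt(abs(fits$q[i] - specs$q_true[i]), 3 * f[1, 2])
    expect_lt(abs(fits$s[i] - specs$s_true[i]), 3 * specs$s_true[i] / sqrt(2 * n))
  }
})

test_that("model serialization round-trips scores bit for bit", {
  co <- random_kdm_cohort(150, seed = 61)
  model <- fit_kdm(co)
  path <- file.path(tempdir(), "kdm_model.tsv")
  write_kdm_model(model, path)
  back <- read_kdm_model(path)
  expect_equal(back$s_ba, model$s_ba)
  expect_identical(compute_kdm(back, co)$kdm_age, compute_kdm(model, co)$kdm_age)
})
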