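test_that("sex-specific references match hand-calculated mean and scale", {
  co <- data.frame(participant_id = 1:6,
                   sex = rep(c("female", "male"), each = 3),
                   vitamin_c = c(2, 4, 6, 10, 20, 30))
  refs <- compute_sex_references(co, "vitamin_c", scale_kind = "SE")
  f <- refs[refs$sex == "female", ]
  expect_equal(f$mean, 4)
  expect_equal(f$scale, 2 / sqrt(3))
  refs_sd <- compute_sex_references(co, "vitamin_c", scale_kind = "SD")
  expect_equal(refs_sd$scale[refs_sd$sex == "female"], 2)
  expect_identical(attr(refs, "scale_kind"), "SE")

  # references are per sex: permuting records within sex changes nothing
  perm <- co[c(3, 1, 2, 5, 6, 4), ]
  expect_equal(compute_sex_references(perm, "vitamin_c"), refs)

  co$vitamin_c[co$sex == "male"] <- 7
  expect_error(compute_sex_references(co, "vitamin_c"), "degenerate nutrient")
  expect_error(compute_sex_references(co[c(1, 2, 3, 4), ], "vitamin_c"),
               "fewer than 2")
})

test_that("CDAI is zero at the reference means, additive, and linear", {
  set.seed(5)
  n <- 40
  co <- data.frame(participant_id = seq_len(n),
                   sex = rep(c("female", "male"), n / 2))
  for (nm in cdai_nutrients()) co[[nm]] <- rlnorm(n, log(10), 0.4)
  refs <- compute_sex_references(co)

  at_mean <- data.frame(participant_id = 1:2, sex = c("female", "male"))
  for (nm in cdai_nutrients()) {
    at_mean[[nm]] <- refs$mean[refs$nutrient == nm][match(at_mean$sex,
                       refs$sex[refs$nutrient == nm])]
  }
  expect_equal(compute_cdai(at_mean, refs)$cdai, c(0, 0), tolerance = 1e-12)

  # one scale-unit above the mean on every nutrient scores exactly 6
  plus_one <- at_mean
  for (nm in cdai_nutrients()) {
    plus_one[[nm]] <- plus_one[[nm]] +
      refs$scale[refs$nutrient == nm][match(plus_one$sex,
        refs$sex[refs$nutrient == nm])]
  }
  expect_equal(compute_cdai(plus_one, refs)$cdai, c(6, 6), tolerance = 1e-12)

  # doubling every deviation doubles the score
  base <- compute_cdai(co, refs)$cdai
  doubled <- co
  for (nm in cdai_nutrients()) {
    m <- refs$mean[refs$nutrient == nm][match(co$sex, refs$sex[refs$nutrient == nm])]
    doubled[[nm]] <- m + 2 * (co[[nm]] - m)
  }
  expect_equal(compute_cdai(doubled, refs)$cdai, 2 * base, tolerance = 1e-10)

  # missing nutrient: record excluded and counted
  co$zinc[1] <- NA
  expect_message(sc <- compute_cdai(co, refs), "1 record")
  expect_equal(attr(sc, "n_excluded"), 1L)
  expect_false(1 %in% sc$participant_id)
})

test_that("DI-GM default config defines 14 components, 13 scorable", {
  cfg <- digm_config()
  expect_equal(nrow(cfg), 14L)
  expect_equal(sum(cfg$scorable), 13L)
  expect_equal(attr(cfg, "max_score"), 13L)
  expect_setequal(unique(cfg$direction), c("beneficial", "unfavorable"))
})

test_that("DI-GM scoring follows the component rules on a toy config", {
  cfg <- toy_digm_config()
  meds <- data.frame(sex = "female", component = c("ben1", "ben2", "unf1"),
                     median = c(10, 10, 10))
  # beneficial hits 1 of 2 (one at median counts via >=), unfavorable below
  rec <- data.frame(participant_id = 1, sex = "female",
                    ben1 = 10, ben2 = 3, unf1 = 4)
  expect_equal(compute_digm(rec, cfg, meds)$digm, 2L)
  # reverse pattern scores zero
  rec0 <- data.frame(participant_id = 1, sex = "female",
                     ben1 = 1, ben2 = 1, unf1 = 50)
  expect_equal(compute_digm(rec0, cfg, meds)$digm, 0L)
})

test_that("DI-GM attains every score 0..13 and never leaves the range", {
  meds <- flat_sex_medians()
  for (k in 0:13) {
    rec <- digm_record_with_score(k)
    expect_equal(compute_digm(rec, sex_medians = meds)$digm, k)
  }
  # random intake patterns stay inside the bounds
  set.seed(7)
  cfg <- digm_config()
  comps <- cfg$name[cfg$scorable & cfg$rule != "fat_share_lt"]
  n <- 200
  co <- data.frame(participant_id = seq_len(n),
                   sex = sample(c("female", "male"), n, TRUE),
                   fat_energy_share = runif(n, 0.1, 0.7))
  for (nm in comps) co[[nm]] <- rlnorm(n, log(10), 1)
  sc <- compute_digm(co, sex_medians = flat_sex_medians())
  expect_true(all(sc$digm >= 0 & sc$digm <= 13))
})

test_that("DI-GM is monotone in component intakes", {
  meds <- flat_sex_medians()
  rec <- digm_record_with_score(5)
  base <- compute_digm(rec, sex_medians = meds)$digm
  up <- rec; up$fiber <- rec$fiber * 10          # beneficial: never decreases
  expect_gte(compute_digm(up, sex_medians = meds)$digm, base)
  worse <- rec; worse$red_meat <- rec$red_meat * 10  # unfavorable: never increases
  expect_lte(compute_digm(worse, sex_medians = meds)$digm, base)
})

test_that("median split follows the stated tie and weighting rules", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(attr(s, "median"), 2.5)
  expect_equal(as.character(s), c("low", "low", "high", "high"))

  # value exactly at the median is labeled high
  s2 <- median_split(c(1, 2, 3))
  expect_equal(as.character(s2)[2], "high")

  # weighted toy: weighted median 1, the value-1 records are high
  s3 <- median_split(c(1, 10), weights = c(3, 1))
  expect_equal(attr(s3, "median"), 1)
  expect_equal(as.character(s3), c("high", "high"))

  # partition: low and high are disjoint and exhaustive
  set.seed(3)
  v <- rnorm(101)
  s4 <- median_split(v)
  expect_equal(sum(s4 == "low") + sum(s4 == "high"), 101L)

  expect_warning(s5 <- median_split(c(2, 2, 2)), "identical")
  expect_true(all(s5 == "high"))
  expect_error(median_split(c(1, NA)), "at least 2")
})

test_that("weighted median matches the weighted-quantile oracle", {
  expect_equal(weighted_median(c(1, 2, 3, 4)), 2.5)
  expect_equal(weighted_median(c(1, 10), c(3, 1)), 1)
  expect_equal(weighted_median(c(5, 1, 3), c(1, 1, 1)), 3)
  # equal weights reproduce the sample median on odd n
  set.seed(9)
  v <- rnorm(51)
  expect_equal(weighted_median(v), median(v))
})
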