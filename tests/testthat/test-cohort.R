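test_that("the derived HAIR chain on a cohort matches per-subject math", {
  cohort <- add_hair(make_mini_cohort())
  # subject 1: worst-case epistaxis answers under the hybrid scheme
  expect_equal(cohort$nosebleed_ml_month[1], 12719)
  expect_equal(cohort$extra_mg_day[1], 12719 / 80 * 6.1)
  expect_equal(cohort$hair_mg_day[1], 8 + 12719 / 80 * 6.1)
  expect_equal(round_half_up(cohort$hair_mg_day[1]), 978)
  # premenopausal subject 3 has no bleeds: HAIR is her higher base
  expect_equal(cohort$hair_mg_day[3], 18)
  expect_equal(cohort$log_hair, log(cohort$hair_mg_day))
  expect_equal(cohort$shortfall_mg_day,
               cohort$hair_mg_day - cohort$total_intake_mg)
  expect_error(add_hair(make_mini_cohort()[, 1:4]), "missing column")
})

test_that("cohort summaries report proportions with CIs and medians", {
  cohort <- add_hair(make_mini_cohort())
  smry <- summarize_cohort(cohort)
  male_row <- smry[smry$variable == "male", ]
  expect_equal(male_row$n_yes, 2L)
  expect_equal(male_row$percent, 100 * 2 / 6)
  # proportions always lie inside their CIs
  bin <- smry[smry$type == "binary", ]
  expect_true(all(bin$percent >= bin$ci_low & bin$percent <= bin$ci_high))
  diet_row <- smry[smry$variable == "diet_intake_mg", ]
  expect_equal(diet_row$median, median(cohort$diet_intake_mg))
  # degenerate one-subject cohort: 100% with a collapsed CI
  one <- summarize_cohort(add_hair(make_mini_cohort()[1, ]))
  male_one <- one[one$variable == "male", ]
  expect_equal(male_one$percent, 100)
  expect_equal(male_one$ci_low, 100)
  expect_error(summarize_cohort(cohort[0, ]), "empty")
})

test_that("a 28-of-50 male cohort summarises to 56%", {
  cohort <- tibble::tibble(
    sex = rep(c("male", "female"), c(28, 22)),
    menstrual_status = rep(c("not_applicable", "postmenopausal",
                             "premenopausal"), c(28, 17, 5))
  )
  smry <- summarize_cohort(cohort)
  expect_equal(smry$percent[smry$variable == "male"], 56)
  expect_equal(smry$percent[smry$variable == "premenopausal_female"], 10)
})

test_that("natural breaks cut at the widest gaps", {
  values <- c(1, 2, 3, 10, 11, 20, 21, 30, 31, 40, 41)
  nb <- natural_breaks_quintiles(values, k = 5)
  expect_equal(nb$assignments, c(1, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  expect_equal(nb$bins$lower, c(1, 10, 20, 30, 40))
  expect_equal(nb$bins$upper, c(3, 11, 21, 31, 41))
  # equally spaced values: ties broken by the lowest cuts first
  nb <- natural_breaks_quintiles(1:10, k = 3)
  expect_equal(nb$assignments, c(1, rep(2, 1), rep(3, 8)))
  expect_error(natural_breaks_quintiles(c(1, 1, 1, 2, 3), k = 5),
               "distinct")
})

test_that("natural breaks agree with exhaustive partition search", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(6:15, 1)
    k <- sample(2:min(5, n - 1), 1)
    values <- round(runif(n, 0, 100), 1)
    if (length(unique(values)) < k) next
    nb <- natural_breaks_quintiles(values, k)
    oracle <- oracle_natural_breaks(values, k)
    expect_equal(nb$assignments, oracle$assignments)
  }
})

test_that("the published quintile ranges are a representable output", {
  bounds <- list(c(8.7, 10.4), c(14.0, 24.2), c(35.3, 56),
                 c(114, 121.5), c(195, 979))
  # fill each published range densely enough that the five between-range
  # gaps are the widest gaps in the data
  values <- unlist(lapply(bounds, function(b) {
    unique(c(seq(b[1], b[2], by = 3), b[2]))
  }))
  nb <- natural_breaks_quintiles(values, k = 5)
  expect_equal(nb$bins$lower, vapply(bounds, `[`, numeric(1), 1))
  expect_equal(nb$bins$upper, vapply(bounds, `[`, numeric(1), 2))
})

test_that("quadratic HAIR regression validates inputs and design", {
  cohort <- generate_cohort(generator_config(n_subjects = 60, seed = 21))
  fit <- quadratic_hair_regression(cohort, "hb")
  expect_s3_class(fit, "hair_regression")
  expect_true(fit$ci[1] <= fit$coefficient && fit$coefficient <= fit$ci[2])
  expect_equal(fit$n, 60L)
  expect_gt(fit$n, nrow(fit$terms))
  # zero-variance outcome
  cohort$flat <- 5
  expect_error(quadratic_hair_regression(cohort, "flat"), "zero variance")
  # a covariate duplicating HAIR makes the design rank-deficient
  cohort$hair_copy <- cohort$hair_mg_day
  expect_error(quadratic_hair_regression(cohort, "hb",
                                         covariates = c("age", "hair_copy")),
               "collinear")
  expect_error(quadratic_hair_regression(cohort[1:5, ], "hb"), "fewer than 10")
  # ln transform demands positive outcomes
  cohort$neg <- cohort$hb - 100
  expect_error(quadratic_hair_regression(cohort, "neg", transform = "ln"),
               "positive")
})

test_that("HAIR-permuted outcomes give a uniform type-I error rate", {
  cohort <- generate_cohort(generator_config(n_subjects = 50, seed = 33))
  set.seed(91)
  pvals <- replicate(150, {
    shuffled <- cohort
    shuffled$hb <- sample(shuffled$hb)
    quadratic_hair_regression(shuffled, "hb")$p_value
  })
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals < 0.5), 0.3)
})

test_that("supplement-attenuated generation blunts the HAIR coefficient", {
  cfg_blunt <- generator_config(n_subjects = 2000, seed = 55,
                                supplement_use_prob = 0.5,
                                supplement_attenuation = 0.3)
  cfg_full <- generator_config(n_subjects = 2000, seed = 55,
                               supplement_use_prob = 0.5,
                               supplement_attenuation = 1)
  co_blunt <- quadratic_hair_regression(generate_cohort(cfg_blunt), "hb")
  co_full <- quadratic_hair_regression(generate_cohort(cfg_full), "hb")
  expect_lt(abs(co_blunt$coefficient), abs(co_full$coefficient))
})

test_that("transform selection picks ln for lognormal data", {
  set.seed(14)
  ln_wins <- mean(replicate(100, {
    transform_select(rlnorm(40, 2, 0.9))$transform == "ln"
  }))
  expect_gt(ln_wins, 0.95)
  # a clearly-spread normal (log transform would skew it left)
  id_wins <- mean(replicate(100, {
    transform_select(abs(rnorm(60, 15, 6)))$transform == "identity"
  }))
  expect_gt(id_wins, 0.85)
  expect_error(transform_select(rep(3, 10)), "constant")
  forced <- transform_select(c(-1, rlnorm(30)))
  expect_equal(forced$transform, "identity")
  expect_true(forced$forced)
})

test_that("rank tests match exhaustive permutation enumeration", {
  # identical groups: no evidence of a difference
  res <- nonparametric_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gt(res$p_value, 0.9)
  # all-tied data is flagged degenerate
  res <- nonparametric_compare(c(2, 2), c(2, 2))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  # small fixed lists against the enumeration oracle (no ties -> exact)
  cases <- list(
    list(a = c(1.2, 3.4, 5.1), b = c(2.2, 6.7, 8.1, 9.3)),
    list(a = c(10, 20), b = c(1, 2, 3, 4)),
    list(a = c(5, 1, 9, 13), b = c(2, 6, 10, 14))
  )
  for (cs in cases) {
    res <- nonparametric_compare(cs$a, cs$b)
    expect_equal(res$p_value, oracle_ranksum_p(cs$a, cs$b))
  }
  # perfectly ordered vectors: rank correlation 1
  res <- nonparametric_compare(1:8, (1:8)^2, method = "rank_correlation")
  expect_equal(res$estimate, 1)
})

test_that("backward elimination retains strong predictors and drops noise", {
  survey <- generate_anemia_survey(n = 424, seed = 77)
  fit <- stepwise_logistic_anemia(
    survey, "persistent_anemia",
    c("stop_iron", "diarrhoea", "switch_iron", "age", "male"))
  expect_true("stop_iron" %in% fit$retained)
  ss <- fit$terms[fit$terms$variable == "stop_ironTRUE", ]
  expect_true(ss$ci_low <= 3.7 && 3.7 <= ss$ci_high)
  expect_true(all(fit$terms$p_wald <= 0.10))
  # null covariates are usually all eliminated
  set.seed(101)
  retention <- replicate(30, {
    null_df <- tibble::tibble(y = runif(200) < 0.3,
                              v1 = rnorm(200), v2 = runif(200) < 0.5,
                              v3 = rnorm(200))
    length(stepwise_logistic_anemia(null_df, "y",
                                    c("v1", "v2", "v3"))$retained)
  })
  expect_lt(mean(retention), 3 * 0.2)
  # constant outcome is an error
  const <- tibble::tibble(y = rep(TRUE, 20), x = rnorm(20))
  expect_error(stepwise_logistic_anemia(const, "y", "x"), "constant")
  # a perfect separator is dropped with a warning
  sep_df <- tibble::tibble(y = rep(c(FALSE, TRUE), each = 25),
                           x = rep(c(0, 1), each = 25) + 0,
                           z = rnorm(50))
  warns <- capture_warnings(stepwise_logistic_anemia(sep_df, "y",
                                                     c("x", "z")))
  expect_true(any(grepl("separation", warns)))
})
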