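test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_subjects = 40, seed = 12)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(generate_timed_bleeds(60, seed = 12),
                   generate_timed_bleeds(60, seed = 12))
  expect_identical(generate_hepcidin_panels(21, seed = 12),
                   generate_hepcidin_panels(21, seed = 12))
  expect_identical(generate_anemia_survey(100, seed = 12),
                   generate_anemia_survey(100, seed = 12))
  # different seeds differ
  expect_false(identical(generate_cohort(cfg),
                         generate_cohort(generator_config(n_subjects = 40,
                                                          seed = 13))))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_cohort(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("generator config validates probabilities", {
  expect_error(generator_config(class_probabilities = c(0.5, 0.3, 0.1)),
               "summing to 1")
  expect_error(generator_config(ess_frequency_probs = rep(0.2, 6)),
               "summing to 1")
  expect_error(generator_config(gushing_prob = 1.4), "gushing_prob")
})

test_that("generated records satisfy the consuming modules' invariants", {
  cohort <- generate_cohort(generator_config(n_subjects = 200, seed = 4))
  expect_true(all(cohort$ess_frequency %in% ess_frequency_levels))
  expect_true(all(cohort$ess_duration %in% ess_duration_levels))
  expect_true(all(cohort$sex %in% c("male", "female")))
  expect_true(all((cohort$sex == "male") ==
                    (cohort$menstrual_status == "not_applicable")))
  expect_true(all(cohort$diet_intake_mg > 0))
  expect_true(all(cohort$supplement_elemental_mg[!cohort$uses_supplement]
                  == 0))
  expect_true(all(cohort$supplement_elemental_mg[cohort$uses_supplement]
                  >= 20))
  expect_true(all(cohort$hair_mg_day >= cohort$base_mg_day))
  for (col in c("hb", "hct", "mcv", "mch", "mchc", "rdw", "serum_iron",
                "tfsi", "ferritin")) {
    expect_true(all(cohort[[col]] > 0), info = col)
  }
  # derived columns are recomputable from the raw answers
  rechained <- add_hair(cohort[, 1:11])
  expect_equal(rechained$hair_mg_day, cohort$hair_mg_day)

  tb <- generate_timed_bleeds(500, seed = 4)
  expect_true(all(tb$duration_min > 0))
  expect_true(all(tb$volume_value > 0))
  expect_true(all(tb$volume_unit %in% volume_units))

  panels <- generate_hepcidin_panels(100, seed = 4)
  expect_true(all(panels$hepcidin > 0))
  expect_true(all(panels$ferritin >= 6 & panels$ferritin <= 203))
  expect_equal(panels$ratio, panels$hepcidin / panels$ferritin)
})

test_that("large cohorts match the demographic calibration targets", {
  cohort <- generate_cohort(generator_config(n_subjects = 10000, seed = 8))
  expect_equal(mean(cohort$sex == "male"), 0.56, tolerance = 0.04)
  expect_equal(median(cohort$diet_intake_mg), 11.3, tolerance = 0.05)
  expect_equal(mean(cohort$ess_gushing), 0.34, tolerance = 0.06)
  # category medians under the default maps match the anchored statistics
  expect_equal(median(frequency_to_monthly_count(cohort$ess_frequency)), 17.7)
  expect_equal(median(duration_to_minutes(cohort$ess_duration)), 2.5)
})

test_that("timed-bleed generation hits its rate target and edge cases", {
  tb <- generate_timed_bleeds(5000, seed = 16)
  rs <- rate_percentiles(tb)
  expect_equal(rs$median, 7.9, tolerance = 0.5 / 7.9)
  # no implausible records when the outlier fraction is zero
  clean <- generate_timed_bleeds(1500, seed = 17, outlier_fraction = 0)
  expect_equal(rate_percentiles(clean)$n_excluded, 0L)
  # a lone record survives the calibration pipeline
  one <- generate_timed_bleeds(1, seed = 18)
  expect_equal(rate_percentiles(one)$n_used, 1L)
  # outliers are uncorroborated and get excluded downstream
  salted <- generate_timed_bleeds(800, seed = 19, outlier_fraction = 0.2)
  expect_gt(rate_percentiles(salted)$n_excluded, 0L)
})

test_that("hepcidin generation respects its null and noise-free limits", {
  cfg0 <- generator_config(hepcidin_coefs = c(b0 = 3, b1 = 0, b2 = 0,
                                              noise_sd = 0.5))
  set.seed(43)
  ests <- t(vapply(sample.int(1e6, 60), function(s) {
    fit <- fit_hepcidin_ferritin(generate_hepcidin_panels(40, seed = s,
                                                          config = cfg0))
    fit$coefficients[c("ferritin", "ferritin_sq")]
  }, numeric(2)))
  # refits under a null model centre on zero
  expect_lt(abs(mean(ests[, 1])) / (sd(ests[, 1]) / sqrt(60)), 3.5)
  expect_lt(abs(mean(ests[, 2])) / (sd(ests[, 2]) / sqrt(60)), 3.5)
  # zero noise: perfect fit
  cfg_exact <- generator_config(hepcidin_coefs = c(b0 = 1.5, b1 = 0.04,
                                                   b2 = -0.00015,
                                                   noise_sd = 0))
  fit <- suppressWarnings( # summary warns on an essentially perfect fit
    fit_hepcidin_ferritin(generate_hepcidin_panels(21, seed = 2,
                                                   config = cfg_exact)))
  expect_equal(fit$r_squared_adj, 1, tolerance = 1e-8)
})

test_that("the full pipeline recovers the generative hemoglobin slope", {
  # no supplement users, so the generative slope applies to every subject
  cohort <- generate_cohort(generator_config(n_subjects = 3000, seed = 26,
                                             supplement_use_prob = 0))
  fit <- quadratic_hair_regression(cohort, "hb")
  expect_true(fit$ci[1] <= -0.0038 && -0.0038 <= fit$ci[2])
  expect_lt(fit$p_value, 0.001)
})
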