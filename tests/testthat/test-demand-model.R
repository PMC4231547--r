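test_that("individual predictions reproduce the packaged national model", {
  coefs <- dutch_gp_coefficients()
  # reference category (male, 25-39, rural) with zero proportions
  expect_equal(as.numeric(predict_individual(coefs, 0, "25-39")), 15.33892)
  # female aged 75+, very strongly urbanised
  expect_equal(
    as.numeric(predict_individual(coefs, 1, "75+", urbanisation = 5)),
    78.485215
  )
  # moving all three proportions from 0 to 1 shifts the prediction by the
  # sum of the proportion coefficients
  delta <- as.numeric(predict_individual(coefs, 0, "25-39", 1, 1, 1, 1)) -
    as.numeric(predict_individual(coefs, 0, "25-39", 0, 0, 0, 1))
  expect_equal(delta, 25.924542)

  expect_error(predict_individual(coefs, 0, "80+"), "age band")
  expect_error(predict_individual(coefs, 2, "25-39"), "0 or 1")
  expect_error(predict_individual(coefs, 0, "25-39", urbanisation = 6),
               "urbanisation")
  expect_error(predict_individual(coefs, 0, "25-39", prop_nonwestern = 1.2),
               "\\[0, 1\\]")
})

test_that("negative individual predictions are floored with a warning", {
  est <- dutch_gp_coefficients()$estimate
  est["intercept"] <- -100
  low <- demand_coefficients(est)
  expect_warning(out <- predict_individual(low, 0, "25-39"), "floored")
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "n_floored"), 1L)
})

test_that("area projection agrees with the exact roster expansion", {
  coefs <- dutch_gp_coefficients()
  profiles <- random_rational_profiles(30, seed = 404)
  est <- predict_area(coefs, profiles)
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    roster <- expand_roster(p)
    indiv <- predict_individual(
      coefs, roster$female, roster$age_band,
      p$prop_nonwestern, p$prop_one_person, p$prop_low_income, p$urbanisation
    )
    expect_equal(est$total_minutes[i], sum(indiv), tolerance = 1e-10)
  }
  expect_equal(est$total_minutes,
               est$minutes_per_inhabitant * est$population)
})

test_that("a single reference inhabitant matches the individual prediction", {
  coefs <- dutch_gp_coefficients()
  p <- make_profile("ONE", 1, 0, c(0, 0, 0, 1, 0, 0, 0))
  est <- predict_area(coefs, p)
  expect_equal(est$total_minutes, 15.33892)
  expect_equal(est$minutes_per_inhabitant, 15.33892)
})

test_that("area projection is additive over disjoint subpopulations", {
  coefs <- dutch_gp_coefficients()
  a <- make_profile("A", 120, 70, c(10, 15, 20, 30, 30, 10, 5),
                    prop_nonwestern = 0.25, prop_one_person = 0.5,
                    prop_low_income = 0.125, urbanisation = 3)
  b <- make_profile("B", 80, 30, c(5, 5, 10, 20, 25, 10, 5),
                    prop_nonwestern = 0.25, prop_one_person = 0.5,
                    prop_low_income = 0.125, urbanisation = 3)
  ab <- make_profile("AB", 200, 100, c(15, 20, 30, 50, 55, 20, 10),
                     prop_nonwestern = 0.25, prop_one_person = 0.5,
                     prop_low_income = 0.125, urbanisation = 3)
  expect_equal(predict_area(coefs, ab)$total_minutes,
               predict_area(coefs, a)$total_minutes +
                 predict_area(coefs, b)$total_minutes)
})

test_that("an empty area yields zero total and an undefined rate", {
  coefs <- dutch_gp_coefficients()
  p <- make_profile("EMPTY", 0, 0, rep(0, 7))
  est <- predict_area(coefs, p)
  expect_equal(est$total_minutes, 0)
  expect_true(is.na(est$minutes_per_inhabitant))
})

test_that("fitting on contacts rescaled by 10 equals fitting on minutes", {
  country <- small_country(seed = 61, n_areas = 25,
                           pop_range = c(100L, 300L))
  pat <- generate_patients(country$profiles,
                           noise = noise_spec(residual_sd = 20, seed = 61))
  fit_min <- fit_demand_model(pat, outcome = "minutes")
  fit_con <- fit_demand_model(pat, outcome = "contacts")
  expect_equal(fit_con$estimate, fit_min$estimate, tolerance = 1e-12)
  expect_equal(fit_con$ci_lower, fit_min$ci_lower, tolerance = 1e-12)
})

test_that("degenerate and deficient designs are reported clearly", {
  country <- small_country(seed = 71, n_areas = 20,
                           pop_range = c(50L, 150L))
  pat <- generate_patients(country$profiles,
                           noise = noise_spec(residual_sd = 10, seed = 71))

  zero <- pat
  zero$annual_minutes <- 0
  fit <- suppressWarnings(fit_demand_model(zero))  # zero residual variance
  expect_equal(unname(fit$estimate), rep(0, 15))
  expect_true(is.na(fit$fit_stats$r_squared))
  expect_true(fit$fit_stats$degenerate_outcome)

  flat <- pat
  flat$urbanisation <- 3L  # a single urbanisation level is collinear
  expect_error(fit_demand_model(flat), "collinear.*urbanisation")

  noctx <- pat[, c("patient_id", "area_id", "female", "age_band",
                   "annual_minutes")]
  expect_error(fit_demand_model(noctx), "contextual")
  expect_error(
    fit_demand_model(noctx, profiles = country$profiles[-1, ]),
    "not found"
  )
})

test_that("fitted confidence intervals cover the truth at nominal rate", {
  # 20 modest replicates; each true coefficient should fall inside its 95%
  # Wald interval in at least 90% of them
  truth <- dutch_gp_coefficients()
  hits <- matrix(NA, nrow = 20, ncol = 15)
  for (r in seq_len(20)) {
    country <- small_country(seed = 500 + r, n_areas = 30,
                             pop_range = c(150L, 400L))
    pat <- generate_patients(country$profiles, truth,
                             noise_spec(residual_sd = 43.4,
                                        seed = 900 + r))
    fit <- fit_demand_model(pat)
    hits[r, ] <- truth$estimate >= fit$ci_lower &
      truth$estimate <= fit$ci_upper
  }
  expect_gte(mean(hits), 0.9)
})

test_that("the population filter flags the documented boundary", {
  est <- data.frame(area_id = c("P1", "P2", "P3"),
                    population = c(999L, 1000L, 5000L),
                    total_minutes = c(1, 2, 3) * 1e4,
                    stringsAsFactors = FALSE)
  out <- apply_population_filter(est)
  expect_equal(out$included, c(FALSE, TRUE, TRUE))
  all_in <- apply_population_filter(est, min_population = 500)
  expect_equal(mean(all_in$included), 1.0)
})
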