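# Two-stage synthetic estimation: (1) patient-level OLS of annual GP
# consultation minutes on demographics plus area context; (2) projection of
# the fitted coefficients onto the census composition of every area.

# raw linear predictor in minutes/year (no flooring); vectorized
linear_predictor <- function(b, female, age_band, prop_nonwestern,
                             prop_one_person, prop_low_income, urbanisation) {
  check_covariates(female, age_band, urbanisation)
  age_slopes <- c(b[c("age_0_4", "age_5_14", "age_15_24")], 0,
                  b[c("age_40_64", "age_65_74", "age_75plus")])
  urb_slopes <- c(0, b[.cp_urb_terms[2:5]])
  age_term <- age_slopes[match(age_band, .cp_age_bands)]
  urb_term <- urb_slopes[urbanisation]
  unname(
    b["intercept"] + female * b["female"] + age_term +
      prop_nonwestern * b["prop_nonwestern"] +
      prop_one_person * b["prop_one_person"] +
      prop_low_income * b["prop_low_income"] + urb_term
  )
}

check_covariates <- function(female, age_band, urbanisation) {
  if (!all(female %in% c(0, 1))) {
    stop("`female` must be 0 or 1", call. = FALSE)
  }
  bad_age <- setdiff(unique(age_band), .cp_age_bands)
  if (length(bad_age)) {
    stop("unknown age band(s): ", toString(bad_age),
         "; valid bands are ", toString(.cp_age_bands), call. = FALSE)
  }
  if (!all(urbanisation %in% 1:5)) {
    stop("`urbanisation` must be an integer category 1 (rural) .. 5 ",
         "(very strongly urbanised)", call. = FALSE)
  }
  invisible(TRUE)
}

validate_profiles <- function(profiles) {
  req <- c("area_id", "population", "female_count", .cp_age_cols,
           "prop_nonwestern", "prop_one_person", "prop_low_income",
           "urbanisation")
  miss <- setdiff(req, names(profiles))
  if (length(miss)) {
    stop("profiles are missing column(s): ", toString(miss), call. = FALSE)
  }
  if (anyDuplicated(profiles$area_id)) {
    stop("area ids must be unique", call. = FALSE)
  }
  age_sum <- rowSums(profiles[, .cp_age_cols])
  if (any(age_sum != profiles$population)) {
    stop("age-band counts must sum exactly to the population in every area",
         call. = FALSE)
  }
  if (any(profiles$female_count < 0 |
          profiles$female_count > profiles$population)) {
    stop("`female_count` must lie in [0, population]", call. = FALSE)
  }
  props <- profiles[, .cp_prop_terms]
  if (any(props < 0 | props > 1)) {
    stop("area proportions must lie in [0, 1]", call. = FALSE)
  }
  if (!all(profiles$urbanisation %in% 1:5)) {
    stop("`urbanisation` must be a category 1..5", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit the patient-level demand model
#'
#' Ordinary least squares of annual GP consultation minutes on the 14
#' regressors of the demand model: a female dummy, six age-band dummies
#' (25-39 as reference), the three area proportions attached to each patient
#' as contextual covariates, and four urbanisation dummies (rural as
#' reference). Confidence intervals are classical 95% Wald/t intervals.
#'
#' @param patients data frame of patient records. Must carry `female`,
#'   `age_band`, `annual_minutes` (and `annual_contacts` when fitting on
#'   contacts). The contextual covariates (`prop_*`, `urbanisation`) may be
#'   present already, or are merged in from `profiles` by `area_id`.
#' @param profiles optional area profiles used to resolve contextual
#'   covariates when the patient table does not carry them.
#' @param outcome fit on `"minutes"` (default) or on `"contacts"`; the
#'   contact-scale fit is rescaled by the 10 minutes of an average
#'   consultation, which is algebraically identical.
#' @return A [demand_coefficients] object with estimates, 95% CIs and fit
#'   statistics (`r_squared`, `f_statistic`, `df`, `n`, and a
#'   `degenerate_outcome` flag when the outcome has zero variance).
#' @export
fit_demand_model <- function(patients, profiles = NULL,
                             outcome = c("minutes", "contacts")) {
  outcome <- match.arg(outcome)
  ctx <- c(.cp_prop_terms, "urbanisation")
  if (!all(ctx %in% names(patients))) {
    if (is.null(profiles)) {
      stop("patients lack contextual covariates and no `profiles` supplied",
           call. = FALSE)
    }
    validate_profiles(profiles)
    unresolved <- setdiff(unique(patients$area_id), profiles$area_id)
    if (length(unresolved)) {
      stop("patient area id(s) not found in profiles: ",
           toString(utils::head(unresolved, 5)), call. = FALSE)
    }
    idx <- match(patients$area_id, profiles$area_id)
    patients[, ctx] <- profiles[idx, ctx]
  }
  req <- c("female", "age_band", ctx,
           if (outcome == "minutes") "annual_minutes" else "annual_contacts")
  miss <- setdiff(req, names(patients))
  if (length(miss)) {
    stop("patients are missing column(s): ", toString(miss), call. = FALSE)
  }
  check_covariates(patients$female, patients$age_band, patients$urbanisation)
  if (nrow(patients) <= length(.cp_terms)) {
    stop("need more patients than model parameters to fit", call. = FALSE)
  }

  d <- data.frame(
    y = if (outcome == "minutes") patients$annual_minutes else
      patients$annual_contacts,
    female = patients$female,
    age_band = factor(patients$age_band, levels = .cp_age_bands),
    prop_nonwestern = patients$prop_nonwestern,
    prop_one_person = patients$prop_one_person,
    prop_low_income = patients$prop_low_income,
    urbanisation = factor(patients$urbanisation, levels = 1:5)
  )
  d$age_band <- stats::relevel(d$age_band, ref = "25-39")
  for (fac in c("age_band", "urbanisation")) {
    if (length(unique(d[[fac]])) < 2) {
      stop("rank-deficient design; collinear term(s): ", fac,
           " (single observed level)", call. = FALSE)
    }
  }
  fit <- stats::lm(y ~ female + age_band + prop_nonwestern +
                     prop_one_person + prop_low_income + urbanisation,
                   data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear term(s): ",
         toString(names(cf)[is.na(cf)]), call. = FALSE)
  }

  # map lm names onto canonical terms
  name_map <- c(
    "(Intercept)" = "intercept", female = "female",
    "age_band0-4" = "age_0_4", "age_band5-14" = "age_5_14",
    "age_band15-24" = "age_15_24", "age_band40-64" = "age_40_64",
    "age_band65-74" = "age_65_74", "age_band75+" = "age_75plus",
    prop_nonwestern = "prop_nonwestern",
    prop_one_person = "prop_one_person",
    prop_low_income = "prop_low_income",
    urbanisation2 = "urb_low", urbanisation3 = "urb_moderate",
    urbanisation4 = "urb_strong", urbanisation5 = "urb_very_strong"
  )
  names(cf) <- name_map[names(cf)]
  ci <- stats::confint(fit, level = 0.95)
  rownames(ci) <- name_map[rownames(ci)]
  lo <- ci[, 1]
  hi <- ci[, 2]
  scale <- if (outcome == "contacts") 10 else 1
  smry <- summary(fit)
  degenerate <- stats::var(d$y) == 0
  fstat <- smry$fstatistic
  fit_stats <- list(
    r_squared = if (degenerate) NA_real_ else smry$r.squared,
    f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df = c(length(.cp_terms) - 1L, unname(fit$df.residual)),
    n = nrow(d),
    degenerate_outcome = degenerate
  )
  demand_coefficients(cf * scale, ci_lower = lo * scale,
                      ci_upper = hi * scale, fit_stats = fit_stats)
}

#' Predict annual consultation minutes for an individual
#'
#' Applies the demand model to one (or a vector of) individual covariate
#' combination(s): intercept plus applicable dummy coefficients plus the
#' proportion coefficients weighted by the area proportions. Negative
#' predictions are floored at zero with a warning (the count of floored
#' values is attached as attribute `n_floored`).
#'
#' @param coefs a [demand_coefficients] object.
#' @param female 0 (male) or 1 (female).
#' @param age_band one of `"0-4"`, `"5-14"`, `"15-24"`, `"25-39"`,
#'   `"40-64"`, `"65-74"`, `"75+"`.
#' @param prop_nonwestern,prop_one_person,prop_low_income the individual's
#'   area proportions in \[0, 1\].
#' @param urbanisation area urbanisation category 1 (rural) .. 5.
#' @return Numeric vector of predicted annual GP consultation minutes.
#' @examples
#' predict_individual(dutch_gp_coefficients(), female = 1, age_band = "75+",
#'                    urbanisation = 5)
#' @export
predict_individual <- function(coefs, female, age_band,
                               prop_nonwestern = 0, prop_one_person = 0,
                               prop_low_income = 0, urbanisation = 1) {
  stopifnot(inherits(coefs, "demand_coefficients"))
  pr <- cbind(prop_nonwestern, prop_one_person, prop_low_income)
  if (any(pr < 0 | pr > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  lp <- linear_predictor(coefs$estimate, female, age_band, prop_nonwestern,
                         prop_one_person, prop_low_income, urbanisation)
  n_floored <- sum(lp < 0)
  if (n_floored > 0) {
    warning(n_floored, " negative prediction(s) floored at 0", call. = FALSE)
    lp <- pmax(lp, 0)
  }
  structure(lp, n_floored = n_floored)
}

#' Project the demand model onto area profiles
#'
#' Second stage of the synthetic estimation: each coefficient is multiplied
#' by the number (or population-weighted amount) of its predictor present in
#' the area, yielding the expected total annual GP consultation minutes for
#' the area and the per-inhabitant rate.
#'
#' @param coefs a [demand_coefficients] object.
#' @param profiles area profiles (one or more rows); see
#'   [generate_area_profiles()] for the column contract.
#' @return Data frame (one row per area) with `area_id`, `population`,
#'   `total_minutes` and `minutes_per_inhabitant` (`NA` for an empty area).
#'   Negative area totals are floored at zero with a warning; the number of
#'   floored areas is attached as attribute `n_floored`.
#' @export
predict_area <- function(coefs, profiles) {
  stopifnot(inherits(coefs, "demand_coefficients"))
  validate_profiles(profiles)
  b <- coefs$estimate
  age_slopes <- c(b[c("age_0_4", "age_5_14", "age_15_24")], 0,
                  b[c("age_40_64", "age_65_74", "age_75plus")])
  age_term <- as.matrix(profiles[, .cp_age_cols]) %*% age_slopes
  urb_slopes <- c(0, b[.cp_urb_terms[2:5]])
  urb_term <- urb_slopes[profiles$urbanisation]
  total <- profiles$population * b["intercept"] +
    profiles$female_count * b["female"] +
    drop(age_term) +
    profiles$population * (
      profiles$prop_nonwestern * b["prop_nonwestern"] +
      profiles$prop_one_person * b["prop_one_person"] +
      profiles$prop_low_income * b["prop_low_income"] + urb_term
    )
  total <- unname(total)
  n_floored <- sum(total < 0)
  if (n_floored > 0) {
    warning(n_floored, " negative area total(s) floored at 0", call. = FALSE)
    total <- pmax(total, 0)
  }
  out <- data.frame(
    area_id = profiles$area_id,
    population = profiles$population,
    total_minutes = total,
    minutes_per_inhabitant = ifelse(profiles$population > 0,
                                    total / profiles$population, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "n_floored") <- n_floored
  out
}

#' Flag areas below the minimum reliable population
#'
#' Area estimates based on very few inhabitants are not considered reliable;
#' areas below the threshold are retained in the data but flagged for
#' suppression in reports.
#'
#' @param estimates data frame with `population` (e.g. from
#'   [predict_area()]).
#' @param min_population inclusion threshold; an area is included when
#'   `population >= min_population`. Default 1,000 inhabitants.
#' @return `estimates` with a logical `included` column.
#' @export
apply_population_filter <- function(estimates, min_population = 1000) {
  if (!"population" %in% names(estimates)) {
    stop("`estimates` must carry a `population` column", call. = FALSE)
  }
  estimates$included <- estimates$population >= min_population
  estimates
}
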