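# Canonical term order for the demand model: intercept + 14 slopes.
# Reference categories (male, age 25-39, rural) carry no term.
.cp_terms <- c(
  "intercept", "female",
  "age_0_4", "age_5_14", "age_15_24", "age_40_64", "age_65_74", "age_75plus",
  "prop_nonwestern", "prop_one_person", "prop_low_income",
  "urb_low", "urb_moderate", "urb_strong", "urb_very_strong"
)

.cp_age_bands <- c("0-4", "5-14", "15-24", "25-39", "40-64", "65-74", "75+")
.cp_age_cols <- c(
  "age_0_4", "age_5_14", "age_15_24", "age_25_39",
  "age_40_64", "age_65_74", "age_75plus"
)
# age band -> coefficient term ("" for the 25-39 reference)
.cp_age_terms <- c(
  "age_0_4", "age_5_14", "age_15_24", "", "age_40_64", "age_65_74", "age_75plus"
)
# urbanisation category 1 (rural, reference) .. 5 (very strongly urbanised)
.cp_urb_terms <- c("", "urb_low", "urb_moderate", "urb_strong", "urb_very_strong")
.cp_prop_terms <- c("prop_nonwestern", "prop_one_person", "prop_low_income")

#' Construct a set of demand-model coefficients
#'
#' Container for the fitted (or assumed) patient-level demand model: an
#' intercept plus 14 slopes, all in annual GP consultation minutes per unit
#' covariate. The dummy coding follows the conventional reference categories
#' male, age 25-39 and rural, which therefore carry no coefficient.
#'
#' @param estimate named numeric vector of length 15; names must be exactly
#'   the canonical terms (see [coefficient_terms()]), in any order.
#' @param ci_lower,ci_upper optional named numeric vectors with the 95%
#'   confidence bounds per term.
#' @param fit_stats optional list with elements `r_squared`, `f_statistic`
#'   and `df` (length-2: model and residual degrees of freedom).
#' @return An object of class `demand_coefficients`.
#' @seealso [dutch_gp_coefficients()] for the packaged national estimates,
#'   [fit_demand_model()] to estimate a set from patient records.
#' @export
demand_coefficients <- function(estimate, ci_lower = NULL, ci_upper = NULL,
                                fit_stats = NULL) {
  if (!is.numeric(estimate) || is.null(names(estimate))) {
    stop("`estimate` must be a named numeric vector", call. = FALSE)
  }
  missing_terms <- setdiff(.cp_terms, names(estimate))
  extra_terms <- setdiff(names(estimate), .cp_terms)
  if (length(missing_terms) || length(extra_terms)) {
    stop(
      "coefficient terms do not match the canonical 15-term model",
      if (length(missing_terms)) paste0("; missing: ", toString(missing_terms)),
      if (length(extra_terms)) paste0("; unknown: ", toString(extra_terms)),
      call. = FALSE
    )
  }
  estimate <- estimate[.cp_terms]
  align <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!all(.cp_terms %in% names(x))) {
      stop(what, " must carry all 15 canonical terms", call. = FALSE)
    }
    x[.cp_terms]
  }
  structure(
    list(
      estimate = estimate,
      ci_lower = align(ci_lower, "`ci_lower`"),
      ci_upper = align(ci_upper, "`ci_upper`"),
      fit_stats = fit_stats
    ),
    class = "demand_coefficients"
  )
}

#' Canonical coefficient terms of the demand model
#'
#' @return Character vector with the 15 term names in canonical order:
#'   intercept, female, six age-band dummies (25-39 is the reference), three
#'   area proportions, and four urbanisation dummies (rural is the reference).
#' @export
coefficient_terms <- function() .cp_terms

#' National Dutch demand-model coefficients
#'
#' The packaged coefficient set estimated on national Dutch sample-based GP
#' registration data (2008; roughly 270,000 listed patients), regressing
#' annual GP consultation minutes (contacts x 10 minutes) on patient gender
#' and age band plus the patient's area composition and urbanisation. These
#' values serve both as defaults for projection onto census profiles and as
#' the ground-truth vector of the synthetic-data generator.
#'
#' @return A [demand_coefficients] object with 95% confidence bounds and fit
#'   statistics (R-squared 0.129, F(14, 269467) = 2852.24).
#' @examples
#' coefs <- dutch_gp_coefficients()
#' # a male aged 25-39 in a rural area with zero proportions:
#' predict_individual(coefs, female = 0, age_band = "25-39")
#' @export
dutch_gp_coefficients <- function() {
  est <- c(
    intercept        = 15.33892,
    female           = 11.92347,
    age_0_4          = 0.411849,
    age_5_14         = -9.006723,
    age_15_24        = -3.599869,
    age_40_64        = 7.796694,
    age_65_74        = 25.50999,
    age_75plus       = 55.09777,
    prop_nonwestern  = 9.313317,
    prop_one_person  = -2.330715,
    prop_low_income  = 18.94194,
    urb_low          = -1.031837,
    urb_moderate     = 0.153963,
    urb_strong       = -0.579397,
    urb_very_strong  = -3.874945
  )
  lo <- c(
    intercept        = 14.42749,
    female           = 11.59783,
    age_0_4          = -0.354851,
    age_5_14         = -9.596515,
    age_15_24        = -4.183009,
    age_40_64        = 7.345136,
    age_65_74        = 24.814,
    age_75plus       = 54.35037,
    prop_nonwestern  = 7.663707,
    prop_one_person  = -4.831568,
    prop_low_income  = 15.96651,
    urb_low          = -1.567949,
    urb_moderate     = -0.426263,
    urb_strong       = -1.158326,
    urb_very_strong  = -4.837014
  )
  hi <- c(
    intercept        = 16.25035,
    female           = 12.2491,
    age_0_4          = 1.178549,
    age_5_14         = -8.416931,
    age_15_24        = -3.016729,
    age_40_64        = 8.248252,
    age_65_74        = 26.20598,
    age_75plus       = 55.84517,
    prop_nonwestern  = 10.96293,
    prop_one_person  = 0.170138,
    prop_low_income  = 21.91738,
    urb_low          = -0.495726,
    urb_moderate     = 0.734188,
    urb_strong       = -0.000468,
    urb_very_strong  = -2.912876
  )
  demand_coefficients(
    est, ci_lower = lo, ci_upper = hi,
    fit_stats = list(r_squared = 0.129, f_statistic = 2852.24,
                     df = c(14, 269467))
  )
}

#' @export
print.demand_coefficients <- function(x, ...) {
  cat("Demand model coefficients (annual GP consultation minutes)\n")
  print(as.data.frame(x), row.names = FALSE, digits = 7)
  fs <- x$fit_stats
  if (!is.null(fs)) {
    cat(sprintf(
      "R-squared: %s   F(%s, %s) = %s\n",
      format(fs$r_squared), format(fs$df[1]), format(fs$df[2]),
      format(fs$f_statistic)
    ))
  }
  invisible(x)
}

#' @export
as.data.frame.demand_coefficients <- function(x, ...) {
  data.frame(
    term = .cp_terms,
    estimate = unname(x$estimate),
    ci_lower = if (is.null(x$ci_lower)) NA_real_ else unname(x$ci_lower),
    ci_upper = if (is.null(x$ci_upper)) NA_real_ else unname(x$ci_upper),
    stringsAsFactors = FALSE
  )
}
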