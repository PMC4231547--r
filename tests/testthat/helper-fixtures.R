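# Fixture builders shared across test files. Everything is built in code;
# no fixture files on disk.

age_cols <- c("age_0_4", "age_5_14", "age_15_24", "age_25_39",
              "age_40_64", "age_65_74", "age_75plus")
age_bands <- c("0-4", "5-14", "15-24", "25-39", "40-64", "65-74", "75+")

# One profile row from explicit parts; age_counts must sum to population.
make_profile <- function(area_id, population, female_count, age_counts,
                         prop_nonwestern = 0, prop_one_person = 0,
                         prop_low_income = 0, urbanisation = 1,
                         centroid = NULL) {
  stopifnot(sum(age_counts) == population)
  p <- data.frame(area_id = area_id, population = as.integer(population),
                  female_count = as.integer(female_count),
                  stringsAsFactors = FALSE)
  p[age_cols] <- as.list(as.integer(age_counts))
  p$prop_nonwestern <- prop_nonwestern
  p$prop_one_person <- prop_one_person
  p$prop_low_income <- prop_low_income
  p$urbanisation <- as.integer(urbanisation)
  if (!is.null(centroid)) {
    p$centroid_x <- centroid[1]
    p$centroid_y <- centroid[2]
  }
  p
}

# Random profiles whose proportion covariates are rational with denominator
# equal to the population, so an exact individual-level roster exists.
random_rational_profiles <- function(n, seed, pop_range = c(20L, 200L)) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      pop <- sample(pop_range[1]:pop_range[2], 1)
      shares <- rgamma(7, 2)
      counts <- careplan:::apportion(pop, shares)
      make_profile(
        area_id = sprintf("R%03d", i),
        population = pop,
        female_count = sample(0:pop, 1),
        age_counts = counts,
        prop_nonwestern = sample(0:pop, 1) / pop,
        prop_one_person = sample(0:pop, 1) / pop,
        prop_low_income = sample(0:pop, 1) / pop,
        urbanisation = sample(1:5, 1),
        centroid = runif(2, 0, 10)
      )
    }))
  })
}

# Expand a rational profile into its exact roster of individuals.
expand_roster <- function(p) {
  n <- p$population
  counts <- as.integer(p[, age_cols])
  data.frame(
    female = rep(c(1L, 0L), c(p$female_count, n - p$female_count)),
    age_band = rep(age_bands, counts),
    stringsAsFactors = FALSE
  )
}

# Small complete synthetic country for integration-style tests.
small_country <- function(seed = 42L, n_areas = 30L,
                          pop_range = c(600L, 4000L)) {
  areas <- generate_geography(geography_spec(
    n_areas = n_areas, population_range = pop_range,
    extent = c(0, 15, 0, 15), seed = seed
  ))
  profiles <- generate_area_profiles(areas, seed = seed + 1L)
  supply <- generate_supply(profiles, supply_scenario(seed = seed + 2L))
  list(areas = areas, profiles = profiles, supply = supply)
}

# Demand/supply pair on explicit numbers, for confrontation tests.
toy_confrontation_inputs <- function() {
  demand <- data.frame(
    area_id = c("X1", "X2", "X3"),
    population = c(2000L, 1500L, 3000L),
    total_minutes = c(74730, 52311, 120000),
    stringsAsFactors = FALSE
  )
  supply <- data.frame(
    area_id = c("X1", "X2", "X3"),
    n_gps = c(1L, 1L, 0L),
    fte = c(1.0, 0.6, 0.0),
    stringsAsFactors = FALSE
  )
  list(demand = demand, supply = supply)
}
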