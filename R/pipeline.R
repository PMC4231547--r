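# End-to-end orchestration: simulate (or read) the four input tables, fit
# the demand model, project it onto every area, confront with supply on the
# area's own footprint and pooled with its surroundings, and render the
# three standard report tables. All artefacts are CSV/JSON on disk and every
# source of randomness flows from one root seed.

#' Build a pipeline configuration
#'
#' Either a `simulation` block (synthetic country) or an `inputs` block
#' (paths to `patients`, `profiles`, `supply` and optionally `distances`
#' CSV files) must be provided; `simulation` is used when both are present.
#'
#' @param out_dir directory for all output files (created if needed).
#' @param seed root integer seed; stage seeds are derived from it.
#' @param simulation list of synthetic-country settings: `n_areas`,
#'   `population_range`, `extent`, `residual_sd`, `rounding`,
#'   `sample_fraction`, `target_patients_per_fte`, `dispersion`, `p_no_gp`.
#'   Missing entries fall back to the package defaults.
#' @param inputs list of input CSV paths (`patients`, `profiles`, `supply`,
#'   optional `distances` in long format).
#' @param min_population suppression threshold for area estimates.
#' @param norm_patients_per_fte,norm_minutes_per_patient norm-workload
#'   parameters (see [norm_workload()]).
#' @param radius_km pooling radius for the surroundings analysis.
#' @param shortage_threshold_fte threshold for a substantial shortage.
#' @param outcome regression outcome scale, `"minutes"` or `"contacts"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulation = list(),
                            inputs = NULL, min_population = 1000,
                            norm_patients_per_fte = 2350,
                            norm_minutes_per_patient = 31.8,
                            radius_km = 3.0, shortage_threshold_fte = 1.0,
                            outcome = c("minutes", "contacts")) {
  outcome <- match.arg(outcome)
  if (min_population <= 0 || radius_km < 0 || shortage_threshold_fte <= 0 ||
      norm_patients_per_fte <= 0 || norm_minutes_per_patient <= 0) {
    stop("thresholds and norm parameters must be positive", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         simulation = simulation, inputs = inputs,
         min_population = min_population,
         norm_patients_per_fte = norm_patients_per_fte,
         norm_minutes_per_patient = norm_minutes_per_patient,
         radius_km = radius_km,
         shortage_threshold_fte = shortage_threshold_fte,
         outcome = outcome),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the fields of [pipeline_config()].
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$out_dir)) {
    stop("config must name an `out_dir`", call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

sim_default <- function(sim, name, default) {
  if (is.null(sim[[name]])) default else sim[[name]]
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage `", name, "`: ", conditionMessage(e), call. = FALSE)
  })
}

write_output <- function(df, dir, name, files) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  files[[name]] <- nrow(df)
  files
}

#' Run the full demand-supply pipeline
#'
#' Executes simulate (or load) -> fit -> predict -> filter -> confront ->
#' surround -> report, writing every artefact to `config$out_dir` and a
#' `manifest.json` describing the run.
#'
#' @param config a [pipeline_config()], or the path to a JSON file readable
#'   by [read_pipeline_config()].
#' @return The run manifest (list of class `run_manifest`): configuration
#'   echo, stage seeds, row counts per output file, warning counters and
#'   headline summary figures.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  warnings_log <- list()
  seeds <- list(geography = config$seed, profiles = config$seed + 1L,
                patients = config$seed + 2L, supply = config$seed + 3L)

  simulate <- length(config$simulation) > 0 || is.null(config$inputs)
  distances <- NULL
  if (simulate) {
    sim <- config$simulation
    spec <- stage("simulate", geography_spec(
      n_areas = sim_default(sim, "n_areas", 400L),
      population_range = sim_default(sim, "population_range",
                                     c(200L, 11342L)),
      extent = sim_default(sim, "extent", c(0, 60, 0, 60)),
      seed = seeds$geography
    ))
    areas <- stage("simulate", generate_geography(spec))
    profiles <- stage("simulate", generate_area_profiles(
      areas, composition_params(), seed = seeds$profiles
    ))
    noise <- stage("simulate", noise_spec(
      residual_sd = sim_default(sim, "residual_sd", .cp_default_residual_sd),
      rounding = sim_default(sim, "rounding", FALSE),
      seed = seeds$patients
    ))
    patients <- stage("simulate", generate_patients(
      profiles, truth = dutch_gp_coefficients(), noise = noise,
      sample_fraction = sim_default(sim, "sample_fraction", 0.12)
    ))
    supply <- stage("simulate", generate_supply(
      profiles, supply_scenario(
        target_patients_per_fte = sim_default(sim, "target_patients_per_fte",
                                              2350),
        dispersion = sim_default(sim, "dispersion", 0.3),
        p_no_gp = sim_default(sim, "p_no_gp", 0.25),
        seed = seeds$supply
      )
    ))
    files <- write_output(areas, config$out_dir, "areas.csv", files)
    files <- write_output(patients, config$out_dir, "patients.csv", files)
    files <- write_output(supply, config$out_dir, "supply.csv", files)
  } else {
    inp <- config$inputs
    for (nm in c("patients", "profiles", "supply")) {
      if (is.null(inp[[nm]])) {
        stop("stage `", if (nm == "supply") "confront" else "fit",
             "`: config names no `", nm, "` input", call. = FALSE)
      }
    }
    patients <- stage("load", utils::read.csv(inp$patients,
                                              stringsAsFactors = FALSE))
    profiles <- stage("load", utils::read.csv(inp$profiles,
                                              stringsAsFactors = FALSE))
    supply <- stage("load", utils::read.csv(inp$supply,
                                            stringsAsFactors = FALSE))
    if (!is.null(inp$distances)) {
      long <- stage("load", utils::read.csv(inp$distances,
                                            stringsAsFactors = FALSE))
      distances <- stage("load", long_to_distances(long, profiles$area_id))
    }
  }
  files <- write_output(profiles, config$out_dir, "profiles.csv", files)

  coefs <- stage("fit", fit_demand_model(patients, profiles,
                                         outcome = config$outcome))
  files <- write_output(as.data.frame(coefs), config$out_dir,
                        "coefficients.csv", files)

  demand <- stage("predict", {
    withCallingHandlers(
      predict_area(coefs, profiles),
      warning = function(w) {
        warnings_log$predict <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    )
  })
  n_floored <- attr(demand, "n_floored")
  demand <- stage("filter",
                  apply_population_filter(demand, config$min_population))
  files <- write_output(demand, config$out_dir, "demand.csv", files)

  norm <- norm_workload(config$norm_patients_per_fte,
                        config$norm_minutes_per_patient)
  own <- stage("confront", confront(demand, supply, norm))
  files <- write_output(own, config$out_dir, "confrontation.csv", files)

  if (is.null(distances)) {
    distances <- stage("surround", euclidean_distances(profiles))
    files <- write_output(distances_to_long(distances), config$out_dir,
                          "distances.csv", files)
  }
  index <- stage("surround", build_neighbourhood(distances,
                                                 config$radius_km))
  pooled <- stage("surround",
                  pooled_confrontation(index, demand, supply, norm))
  files <- write_output(pooled, config$out_dir,
                        "confrontation_pooled.csv", files)
  comp <- stage("surround",
                compensation_report(own, pooled,
                                    config$shortage_threshold_fte))
  comp_df <- data.frame(
    scope = c("own_area", "pooled"),
    pct_areas_shortage = c(comp$own$pct_areas_shortage,
                           comp$pooled$pct_areas_shortage),
    pct_areas_shortage_ge_threshold =
      c(comp$own$pct_areas_shortage_ge_threshold,
        comp$pooled$pct_areas_shortage_ge_threshold),
    total_shortage_fte = c(comp$own$total_shortage_fte,
                           comp$pooled$total_shortage_fte),
    population_in_shortage = c(comp$own$population_in_shortage,
                               comp$pooled$population_in_shortage),
    stringsAsFactors = FALSE
  )
  files <- write_output(comp_df, config$out_dir, "compensation.csv", files)

  reports <- stage("report",
                   render_reports(coefs, own, pooled,
                                  out_dir = config$out_dir))
  for (nm in names(reports)) {
    files[[paste0("table_", nm, ".csv")]] <- nrow(reports[[nm]])
  }

  manifest <- structure(
    list(
      package_version = as.character(utils::packageVersion("careplan")),
      config = unclass(config),
      seeds = seeds,
      files = files,
      warnings = list(
        n_floored_predictions = n_floored,
        n_excluded_areas = sum(!demand$included),
        n_no_gp_areas = sum(own$fte_supply == 0),
        messages = warnings_log
      ),
      summary = list(
        n_areas = nrow(demand),
        n_patients = nrow(patients),
        mean_minutes_per_inhabitant =
          mean(demand$minutes_per_inhabitant[demand$included]),
        pct_areas_shortage_own = comp$own$pct_areas_shortage,
        pct_areas_shortage_pooled = comp$pooled$pct_areas_shortage,
        pct_areas_compensated = comp$pct_areas_compensated
      )
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  %d areas, %d patients\n", x$summary$n_areas,
              x$summary$n_patients))
  cat(sprintf("  mean demand: %.1f min/inhabitant/year\n",
              x$summary$mean_minutes_per_inhabitant))
  cat(sprintf("  areas in shortage: %.1f%% own-area, %.1f%% pooled\n",
              x$summary$pct_areas_shortage_own,
              x$summary$pct_areas_shortage_pooled))
  cat(sprintf("  outputs: %s\n", toString(names(x$files))))
  invisible(x)
}

.cp_pretty_terms <- c(
  intercept = "Constant", female = "Female",
  age_0_4 = "0-4 years", age_5_14 = "5-14 years",
  age_15_24 = "15-24 years", age_40_64 = "40-64 years",
  age_65_74 = "65-74 years", age_75plus = "75 years and older",
  prop_nonwestern = "Proportion non-Western immigrants",
  prop_one_person = "Proportion one-person households",
  prop_low_income = "Proportion persons in low-income households",
  urb_low = "Low urbanisation", urb_moderate = "Moderately urbanised",
  urb_strong = "Strongly urbanised", urb_very_strong = "Very strongly urbanised"
)

#' Render the three standard report tables
#'
#' Produces (1) the coefficient table of the demand model, (2) the
#' distribution of areas and population over workload bands for the own-area
#' and pooled confrontations side by side, and (3) the shortage/surplus
#' summary by residents class for the pooled confrontation. Percentages are
#' reported to one decimal.
#'
#' @param coefs a [demand_coefficients] object.
#' @param own own-area confrontation results (with `population` and
#'   `included`).
#' @param pooled pooled confrontation results.
#' @param out_dir optional directory; when given, each table is written as
#'   `table_<name>.csv`.
#' @return List with data frames `coefficients`, `bands`,
#'   `residents_classes`.
#' @export
render_reports <- function(coefs, own, pooled, out_dir = NULL) {
  stopifnot(inherits(coefs, "demand_coefficients"))
  cf <- as.data.frame(coefs)
  cf$term <- unname(.cp_pretty_terms[cf$term])
  names(cf) <- c("term", "b", "lower_95ci", "upper_95ci")

  bands_own <- summarize_bands(own)
  bands_pooled <- summarize_bands(pooled)
  all_bands <- unique(c(bands_own$band, bands_pooled$band))
  all_bands <- .cp_band_levels[.cp_band_levels %in% all_bands]
  pick <- function(tab, col) {
    v <- tab[[col]][match(all_bands, tab$band)]
    round(ifelse(is.na(v), 0, v), 1)
  }
  bands <- data.frame(
    workload_band = all_bands,
    own_pct_areas = pick(bands_own, "pct_areas"),
    own_pct_population = pick(bands_own, "pct_population"),
    pooled_pct_areas = pick(bands_pooled, "pct_areas"),
    pooled_pct_population = pick(bands_pooled, "pct_population"),
    stringsAsFactors = FALSE
  )

  res <- summarize_by_residents_class(pooled)
  residents <- data.frame(
    residents_class = res$residents_class,
    mean_fte_needed = round(res$mean_fte_needed, 2),
    mean_fte_supply = round(res$mean_fte_supply, 2),
    mean_pct_balance = round(res$mean_pct_balance, 1),
    n_areas = res$n_areas,
    stringsAsFactors = FALSE
  )

  out <- list(coefficients = cf, bands = bands,
              residents_classes = residents)
  if (!is.null(out_dir)) {
    for (nm in names(out)) {
      utils::write.csv(out[[nm]],
                       file.path(out_dir, paste0("table_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}
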