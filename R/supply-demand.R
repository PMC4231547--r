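# Confrontation of estimated demand with FTE GP supply: workload per FTE
# and FTE surplus/deficit against the norm workload, plus the two standard
# summary tables (workload bands; residents classes).

.cp_band_edges <- c(8000, 50000, 100000, 150000, 300000, 500000)
.cp_band_labels <- c("8,000-50,000", "50,000-100,000", "100,000-150,000",
                     "150,000-300,000", "300,000-500,000")
.cp_band_levels <- c(.cp_band_labels, "No GP", "Other")

#' Norm workload of one FTE GP
#'
#' The consultation-minute load that defines one full-time equivalent of
#' demand: the norm list size per FTE multiplied by the mean annual
#' consultation time per patient. With the Dutch norms (2,350 patients per
#' FTE, 31.8 min per patient per year) this is 74,730 minutes per year.
#'
#' @param patients_per_fte norm list size per FTE GP (> 0).
#' @param minutes_per_patient mean annual consultation minutes per listed
#'   patient (> 0).
#' @return A list of class `workload_norm` with `patients_per_fte`,
#'   `minutes_per_patient` and their product `norm_minutes`.
#' @examples
#' norm_workload(2350, 31.8)$norm_minutes  # 74730
#' @export
norm_workload <- function(patients_per_fte = 2350,
                          minutes_per_patient = 31.8) {
  if (length(patients_per_fte) != 1 || is.na(patients_per_fte) ||
      patients_per_fte <= 0 ||
      length(minutes_per_patient) != 1 || is.na(minutes_per_patient) ||
      minutes_per_patient <= 0) {
    stop("`patients_per_fte` and `minutes_per_patient` must be positive",
         call. = FALSE)
  }
  structure(
    list(patients_per_fte = as.numeric(patients_per_fte),
         minutes_per_patient = as.numeric(minutes_per_patient),
         norm_minutes = as.numeric(patients_per_fte) *
           as.numeric(minutes_per_patient)),
    class = "workload_norm"
  )
}

#' @export
print.workload_norm <- function(x, ...) {
  cat(sprintf(
    "Norm workload: %s patients/FTE x %s min/patient = %s min/FTE per year\n",
    format(x$patients_per_fte), format(x$minutes_per_patient),
    format(x$norm_minutes)
  ))
  invisible(x)
}

#' Classify workload per FTE into reporting bands
#'
#' Bands are half-open `[lo, hi)` intervals of annual consultation minutes
#' per FTE: 8,000-50,000; 50,000-100,000; 100,000-150,000; 150,000-300,000;
#' 300,000-500,000. `NA` (no GP in the area) maps to `"No GP"`; nonnegative
#' values outside all bands map to `"Other"`.
#'
#' @param workload_per_fte numeric vector of minutes per FTE per year; `NA`
#'   for areas without GP.
#' @param edges optional alternative band edges (increasing).
#' @return Factor with levels the five bands, `"No GP"` and `"Other"`.
#' @export
classify_workload <- function(workload_per_fte, edges = .cp_band_edges) {
  if (any(!is.na(workload_per_fte) & workload_per_fte < 0)) {
    stop("workload must be nonnegative", call. = FALSE)
  }
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("band `edges` must be strictly increasing", call. = FALSE)
  }
  labels <- if (identical(edges, .cp_band_edges)) .cp_band_labels else
    paste(utils::head(edges, -1), utils::tail(edges, -1), sep = "-")
  idx <- findInterval(workload_per_fte, edges,
                      rightmost.closed = FALSE, left.open = FALSE)
  band <- ifelse(is.na(workload_per_fte), "No GP",
                 ifelse(idx >= 1 & idx <= length(labels), labels[pmax(idx, 1)],
                        "Other"))
  factor(band, levels = c(labels, "No GP", "Other"))
}

#' Confront estimated demand with GP supply
#'
#' Computes, per area, the two indicators of the match between demand and
#' supply: the expected workload per available FTE GP, and the FTE balance
#' (supply minus the FTE needed to carry the estimated demand at the norm
#' workload; positive = surplus).
#'
#' @param demand data frame with `area_id` and `total_minutes` (and
#'   optionally `population`, `included`), e.g. from [predict_area()].
#' @param supply data frame with `area_id` and `fte`.
#' @param norm a [norm_workload()].
#' @return Data frame with one row per demand area: `area_id`, `scope`
#'   (`"own_area"`), `demand_minutes`, `fte_supply`, `workload_per_fte`
#'   (`NA` when the area has no GP), `fte_needed`, `fte_balance`,
#'   `pct_balance` (100 x balance / needed; `NA` when nothing is needed) and
#'   `workload_band`.
#' @export
confront <- function(demand, supply, norm = norm_workload()) {
  stopifnot(inherits(norm, "workload_norm"))
  if (!all(c("area_id", "total_minutes") %in% names(demand))) {
    stop("`demand` must carry `area_id` and `total_minutes`", call. = FALSE)
  }
  if (!all(c("area_id", "fte") %in% names(supply))) {
    stop("`supply` must carry `area_id` and `fte`", call. = FALSE)
  }
  if (any(supply$fte < 0)) stop("`fte` must be nonnegative", call. = FALSE)
  missing_supply <- setdiff(demand$area_id, supply$area_id)
  if (length(missing_supply)) {
    stop("no supply record for area(s): ",
         toString(utils::head(missing_supply, 5)), call. = FALSE)
  }
  fte <- supply$fte[match(demand$area_id, supply$area_id)]
  confrontation_rows(
    area_id = demand$area_id,
    scope = "own_area",
    demand_minutes = demand$total_minutes,
    fte_supply = fte,
    norm = norm,
    population = if ("population" %in% names(demand)) demand$population,
    included = if ("included" %in% names(demand)) demand$included
  )
}

# shared arithmetic for own-area and pooled confrontations
confrontation_rows <- function(area_id, scope, demand_minutes, fte_supply,
                               norm, population = NULL, included = NULL) {
  workload <- ifelse(fte_supply > 0, demand_minutes / fte_supply, NA_real_)
  fte_needed <- demand_minutes / norm$norm_minutes
  fte_balance <- fte_supply - fte_needed
  pct_balance <- ifelse(fte_needed > 0, 100 * fte_balance / fte_needed,
                        NA_real_)
  out <- data.frame(
    area_id = area_id,
    scope = scope,
    demand_minutes = demand_minutes,
    fte_supply = fte_supply,
    workload_per_fte = workload,
    fte_needed = fte_needed,
    fte_balance = fte_balance,
    pct_balance = pct_balance,
    workload_band = classify_workload(workload),
    stringsAsFactors = FALSE
  )
  if (!is.null(population)) out$population <- population
  if (!is.null(included)) out$included <- included
  out
}

#' Summarize areas and population over workload bands
#'
#' @param results confrontation results (own-area or pooled). If an
#'   `included` column is present only included areas are summarized.
#' @param profiles optional data frame with `area_id` and `population`;
#'   needed when `results` does not carry `population`.
#' @return Data frame with one row per band: `band`, `n_areas`, `pct_areas`
#'   and `pct_population`. The two percentage columns each sum to 100 (up to
#'   rounding); the `"Other"` band is reported only when occupied.
#' @export
summarize_bands <- function(results, profiles = NULL) {
  if (!"population" %in% names(results)) {
    if (is.null(profiles) ||
        !all(c("area_id", "population") %in% names(profiles))) {
      stop("`results` lack `population`; supply `profiles` with it",
           call. = FALSE)
    }
    results$population <-
      profiles$population[match(results$area_id, profiles$area_id)]
  }
  if ("included" %in% names(results)) {
    results <- results[results$included, , drop = FALSE]
  }
  if (nrow(results) == 0) {
    return(data.frame(band = character(0), n_areas = integer(0),
                      pct_areas = numeric(0), pct_population = numeric(0),
                      stringsAsFactors = FALSE))
  }
  band <- factor(results$workload_band, levels = .cp_band_levels)
  n_areas <- as.integer(table(band))
  pop <- as.numeric(tapply(results$population, band, sum, default = 0))
  out <- data.frame(
    band = .cp_band_levels,
    n_areas = n_areas,
    pct_areas = 100 * n_areas / nrow(results),
    pct_population = 100 * pop / sum(results$population),
    stringsAsFactors = FALSE
  )
  if (out$n_areas[out$band == "Other"] == 0) {
    out <- out[out$band != "Other", , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.cp_residents_edges <- c(1000, 2500, 5000, 7500, 10000, 15000, 20000,
                         30000, Inf)

#' Summarize shortage/surplus by residents class
#'
#' Groups areas by population size and reports, per class, the unweighted
#' means of FTE needed, FTE supplied and the per-area percentage balance
#' (areas with undefined percentage, i.e. zero FTE needed, are excluded from
#' the mean and counted separately).
#'
#' @param results confrontation results carrying `population` (or joined via
#'   `profiles`). Only `included` areas are summarized if the flag is
#'   present.
#' @param profiles optional source of `population` per `area_id`.
#' @param class_edges increasing class boundaries; classes are half-open
#'   `[lo, hi)`; the default gives the eight classes from 1,000-2,500 up to
#'   >30,000 inhabitants.
#' @return Data frame with `residents_class`, `mean_fte_needed`,
#'   `mean_fte_supply`, `mean_pct_balance`, `n_undefined_pct`, `n_areas`.
#' @export
summarize_by_residents_class <- function(results, profiles = NULL,
                                         class_edges = .cp_residents_edges) {
  if (is.unsorted(class_edges, strictly = TRUE)) {
    stop("`class_edges` must be strictly increasing", call. = FALSE)
  }
  if (!"population" %in% names(results)) {
    if (is.null(profiles) ||
        !all(c("area_id", "population") %in% names(profiles))) {
      stop("`results` lack `population`; supply `profiles` with it",
           call. = FALSE)
    }
    results$population <-
      profiles$population[match(results$area_id, profiles$area_id)]
  }
  if ("included" %in% names(results)) {
    results <- results[results$included, , drop = FALSE]
  }
  lo <- utils::head(class_edges, -1)
  hi <- utils::tail(class_edges, -1)
  labels <- ifelse(is.finite(hi),
                   paste0(format(lo, big.mark = ",", trim = TRUE,
                                 scientific = FALSE), "-",
                          format(hi, big.mark = ",", trim = TRUE,
                                 scientific = FALSE)),
                   paste0(">", format(lo, big.mark = ",", trim = TRUE,
                                      scientific = FALSE)))
  idx <- findInterval(results$population, class_edges)
  in_range <- idx >= 1 & idx <= length(labels)
  results <- results[in_range, , drop = FALSE]
  cls <- factor(labels[idx[in_range]], levels = labels)
  agg <- function(x, f) as.numeric(tapply(x, cls, f, default = NA_real_))
  data.frame(
    residents_class = labels,
    mean_fte_needed = agg(results$fte_needed,
                          function(x) mean(x, na.rm = TRUE)),
    mean_fte_supply = agg(results$fte_supply,
                          function(x) mean(x, na.rm = TRUE)),
    mean_pct_balance = agg(results$pct_balance,
                           function(x) mean(x, na.rm = TRUE)),
    n_undefined_pct = as.integer(tapply(is.na(results$pct_balance), cls, sum,
                                        default = 0)),
    n_areas = as.integer(table(cls)),
    stringsAsFactors = FALSE
  )
}
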