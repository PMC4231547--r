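# Catchment pooling: each area is pooled with all areas within a distance
# radius and the supply-demand confrontation is recomputed on the pooled
# totals, letting neighbouring oversupply compensate local undersupply.

#' Euclidean distance matrix between area centroids
#'
#' Straight-line distances are a stand-in for the road distances used with
#' real geographies; a road-distance matrix can be supplied directly to
#' [build_neighbourhood()] instead.
#'
#' @param areas data frame with `area_id`, `centroid_x`, `centroid_y` (km).
#' @return Symmetric numeric matrix of distances in km with area ids as
#'   dimnames and a zero diagonal.
#' @export
euclidean_distances <- function(areas) {
  req <- c("area_id", "centroid_x", "centroid_y")
  if (!all(req %in% names(areas))) {
    stop("`areas` must carry columns: ", toString(req), call. = FALSE)
  }
  if (anyNA(areas$centroid_x) || anyNA(areas$centroid_y)) {
    stop("missing centroid coordinates", call. = FALSE)
  }
  m <- as.matrix(stats::dist(cbind(areas$centroid_x, areas$centroid_y)))
  dimnames(m) <- list(areas$area_id, areas$area_id)
  m
}

#' Convert a distance matrix to/from long format
#'
#' The long format (`area_i`, `area_j`, `km`) is the on-disk interchange
#' format; each unordered pair appears once.
#'
#' @param distances symmetric distance matrix with area-id dimnames.
#' @return `distances_to_long()`: data frame `area_i`, `area_j`, `km`.
#' @export
distances_to_long <- function(distances) {
  ids <- rownames(distances)
  idx <- which(upper.tri(distances), arr.ind = TRUE)
  data.frame(
    area_i = ids[idx[, 1]],
    area_j = ids[idx[, 2]],
    km = distances[idx],
    stringsAsFactors = FALSE
  )
}

#' @rdname distances_to_long
#' @param long data frame with `area_i`, `area_j`, `km`.
#' @param area_ids optional full set of area ids (areas without any listed
#'   pair get only themselves at distance 0).
#' @return `long_to_distances()`: symmetric matrix with zero diagonal.
#' @export
long_to_distances <- function(long, area_ids = NULL) {
  req <- c("area_i", "area_j", "km")
  if (!all(req %in% names(long))) {
    stop("`long` must carry columns: ", toString(req), call. = FALSE)
  }
  ids <- if (is.null(area_ids)) sort(unique(c(long$area_i, long$area_j)))
         else area_ids
  m <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  i <- match(long$area_i, ids)
  j <- match(long$area_j, ids)
  if (anyNA(i) || anyNA(j)) {
    stop("pair list mentions area ids absent from `area_ids`", call. = FALSE)
  }
  m[cbind(i, j)] <- long$km
  m[cbind(j, i)] <- long$km
  m
}

#' Build the neighbourhood index
#'
#' For every area, the set of areas (always including itself) situated at
#' `radius_km` or less — the threshold is inclusive. An optional per-area
#' radius allows different catchment sizes, e.g. for urban versus rural
#' areas.
#'
#' @param distances symmetric nonnegative distance matrix (km) with zero
#'   diagonal and area ids as dimnames.
#' @param radius_km pooling radius in km; the default 3 km reflects the
#'   typical distance between a patient's area and their GP practice.
#' @param per_area_radius optional named numeric vector of radii overriding
#'   `radius_km` for specific focal areas.
#' @return Object of class `neighbourhood_index`: a list with `neighbours`
#'   (named list of area-id vectors) and `radius_km`.
#' @export
build_neighbourhood <- function(distances, radius_km = 3.0,
                                per_area_radius = NULL) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances) ||
      is.null(rownames(distances))) {
    stop("`distances` must be a square matrix with area-id dimnames",
         call. = FALSE)
  }
  if (any(distances < 0)) {
    stop("distances must be nonnegative", call. = FALSE)
  }
  if (any(diag(distances) != 0)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  dt <- t(distances)
  same <- (distances == dt) | (abs(distances - dt) <= 1e-9)
  if (anyNA(distances) || !all(same, na.rm = TRUE)) {
    stop("distance matrix must be symmetric with no missing entries",
         call. = FALSE)
  }
  if (radius_km < 0) stop("`radius_km` must be nonnegative", call. = FALSE)
  ids <- rownames(distances)
  radii <- rep(radius_km, length(ids))
  names(radii) <- ids
  if (!is.null(per_area_radius)) {
    unknown <- setdiff(names(per_area_radius), ids)
    if (length(unknown)) {
      stop("per-area radius for unknown area(s): ", toString(unknown),
           call. = FALSE)
    }
    radii[names(per_area_radius)] <- per_area_radius
  }
  neighbours <- lapply(seq_along(ids), function(i) {
    ids[distances[i, ] <= radii[i]]
  })
  names(neighbours) <- ids
  structure(
    list(neighbours = neighbours, radius_km = radius_km),
    class = "neighbourhood_index"
  )
}

#' @export
print.neighbourhood_index <- function(x, ...) {
  sizes <- lengths(x$neighbours)
  cat(sprintf(
    "Neighbourhood index: %d areas, radius %s km, %.1f members on average\n",
    length(sizes), format(x$radius_km), mean(sizes)
  ))
  invisible(x)
}

#' Pooled supply-demand confrontation
#'
#' Recomputes the confrontation for each focal area on the totals of its
#' neighbourhood: demand minutes and FTE supply are summed over all members
#' (focal area included) and the indicators recomputed. Each result is
#' attributed to the focal area; neighbourhoods overlap, so pooled results
#' are not additive across areas.
#'
#' @param index a [build_neighbourhood()] result.
#' @param demand data frame with `area_id`, `total_minutes` (and optionally
#'   `population`, `included`) covering every neighbourhood member.
#' @param supply data frame with `area_id`, `fte` covering every member.
#' @param norm a [norm_workload()].
#' @return Data frame like [confront()]'s but with `scope = "pooled"`;
#'   `population` and `included`, when present, are the focal area's own.
#' @export
pooled_confrontation <- function(index, demand, supply,
                                 norm = norm_workload()) {
  stopifnot(inherits(index, "neighbourhood_index"),
            inherits(norm, "workload_norm"))
  ids <- names(index$neighbours)
  members <- unique(unlist(index$neighbours))
  miss_d <- setdiff(members, demand$area_id)
  miss_s <- setdiff(members, supply$area_id)
  if (length(miss_d) || length(miss_s)) {
    stop("neighbourhood member(s) missing from ",
         if (length(miss_d)) "demand " else "", if (length(miss_s)) "supply ",
         "table: ", toString(utils::head(unique(c(miss_d, miss_s)), 5)),
         call. = FALSE)
  }
  dmap <- stats::setNames(demand$total_minutes, demand$area_id)
  smap <- stats::setNames(supply$fte, supply$area_id)
  pooled_demand <- vapply(index$neighbours,
                          function(nb) sum(dmap[nb]), numeric(1))
  pooled_fte <- vapply(index$neighbours,
                       function(nb) sum(smap[nb]), numeric(1))
  focal <- match(ids, demand$area_id)
  confrontation_rows(
    area_id = ids,
    scope = "pooled",
    demand_minutes = unname(pooled_demand),
    fte_supply = unname(pooled_fte),
    norm = norm,
    population = if ("population" %in% names(demand))
      demand$population[focal],
    included = if ("included" %in% names(demand)) demand$included[focal]
  )
}

#' Compare own-area and pooled shortages
#'
#' Summarizes how much local undersupply is compensated by surrounding
#' areas: the share of areas in shortage before and after pooling, the share
#' with a shortage of at least `shortage_threshold_fte`, the total shortage
#' summed over shortage areas, and the population living in them.
#'
#' @param own own-area confrontation results.
#' @param pooled pooled confrontation results over the same areas.
#' @param shortage_threshold_fte threshold for a "substantial" shortage
#'   (default 1 FTE); an area counts when `fte_balance <= -threshold`.
#' @return A list of class `compensation_report` with per-scope shares (in
#'   percent of areas), total shortage FTEs, affected population, and the
#'   compensation share (own minus pooled shortage share).
#' @export
compensation_report <- function(own, pooled, shortage_threshold_fte = 1.0) {
  if ("included" %in% names(own)) own <- own[own$included, , drop = FALSE]
  if ("included" %in% names(pooled)) {
    pooled <- pooled[pooled$included, , drop = FALSE]
  }
  if (!setequal(own$area_id, pooled$area_id) ||
      nrow(own) != nrow(pooled)) {
    stop("`own` and `pooled` must cover the same areas", call. = FALSE)
  }
  pooled <- pooled[match(own$area_id, pooled$area_id), , drop = FALSE]
  if (shortage_threshold_fte <= 0) {
    stop("`shortage_threshold_fte` must be positive", call. = FALSE)
  }
  scope_stats <- function(r) {
    shortage <- r$fte_balance < 0
    list(
      pct_areas_shortage = 100 * mean(shortage),
      pct_areas_shortage_ge_threshold =
        100 * mean(r$fte_balance <= -shortage_threshold_fte),
      total_shortage_fte = sum(-r$fte_balance[shortage]),
      population_in_shortage = if ("population" %in% names(r))
        sum(r$population[shortage]) else NA_real_
    )
  }
  own_s <- scope_stats(own)
  pooled_s <- scope_stats(pooled)
  structure(
    list(
      n_areas = nrow(own),
      shortage_threshold_fte = shortage_threshold_fte,
      own = own_s,
      pooled = pooled_s,
      pct_areas_compensated = own_s$pct_areas_shortage -
        pooled_s$pct_areas_shortage
    ),
    class = "compensation_report"
  )
}

#' @export
print.compensation_report <- function(x, ...) {
  cat(sprintf("Compensation report over %d areas\n", x$n_areas))
  cat(sprintf("  shortage share: %.1f%% own-area, %.1f%% pooled (%.1f%% compensated)\n",
              x$own$pct_areas_shortage, x$pooled$pct_areas_shortage,
              x$pct_areas_compensated))
  cat(sprintf("  shortage >= %s FTE: %.1f%% own-area, %.1f%% pooled\n",
              format(x$shortage_threshold_fte),
              x$own$pct_areas_shortage_ge_threshold,
              x$pooled$pct_areas_shortage_ge_threshold))
  cat(sprintf("  total shortage: %.1f FTE own-area, %.1f FTE pooled\n",
              x$own$total_shortage_fte, x$pooled$total_shortage_fte))
  invisible(x)
}
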