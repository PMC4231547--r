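test_that("euclidean distances are metric and anchored to simple cases", {
  two <- data.frame(area_id = c("E1", "E2"),
                    centroid_x = c(0, 3), centroid_y = c(0, 0))
  d <- euclidean_distances(two)
  expect_equal(d["E1", "E2"], 3.0)
  expect_equal(diag(d), c(E1 = 0, E2 = 0))

  one <- data.frame(area_id = "E1", centroid_x = 1, centroid_y = 1)
  expect_equal(euclidean_distances(one),
               matrix(0, 1, 1, dimnames = list("E1", "E1")))

  expect_error(
    euclidean_distances(data.frame(area_id = "Q", centroid_x = NA,
                                   centroid_y = 1)),
    "missing centroid"
  )

  # triangle inequality on random point sets
  for (s in 1:5) {
    pts <- withr::with_seed(s, data.frame(
      area_id = sprintf("T%02d", 1:8),
      centroid_x = runif(8, 0, 10), centroid_y = runif(8, 0, 10)
    ))
    d <- euclidean_distances(pts)
    for (i in 1:8) for (j in 1:8) {
      expect_true(all(d[i, j] <= d[i, ] + d[, j] + 1e-12))
    }
  }
})

test_that("distance matrices round-trip through the long format", {
  pts <- withr::with_seed(3, data.frame(
    area_id = sprintf("L%02d", 1:6),
    centroid_x = runif(6, 0, 5), centroid_y = runif(6, 0, 5)
  ))
  d <- euclidean_distances(pts)
  long <- distances_to_long(d)
  expect_equal(nrow(long), 15)  # 6 choose 2
  back <- long_to_distances(long, pts$area_id)
  expect_equal(back, d)
})

test_that("neighbourhoods are reflexive, symmetric and threshold-inclusive", {
  pts <- withr::with_seed(9, data.frame(
    area_id = sprintf("N%02d", 1:12),
    centroid_x = runif(12, 0, 8), centroid_y = runif(12, 0, 8)
  ))
  d <- euclidean_distances(pts)

  nb0 <- build_neighbourhood(d, radius_km = 0)
  expect_true(all(vapply(names(nb0$neighbours), function(i) {
    identical(nb0$neighbours[[i]], i)
  }, logical(1))))

  nb_all <- build_neighbourhood(d, radius_km = max(d) + 1)
  expect_true(all(lengths(nb_all$neighbours) == 12))

  nb <- build_neighbourhood(d, radius_km = 3)
  for (i in pts$area_id) {
    expect_true(i %in% nb$neighbours[[i]])
    for (j in nb$neighbours[[i]]) {
      expect_true(i %in% nb$neighbours[[j]])
      expect_lte(d[i, j], 3)
    }
  }

  # a pair at exactly the radius is included
  exact <- euclidean_distances(data.frame(
    area_id = c("P1", "P2"), centroid_x = c(0, 3), centroid_y = c(0, 0)
  ))
  nb3 <- build_neighbourhood(exact, radius_km = 3)
  expect_setequal(nb3$neighbours[["P1"]], c("P1", "P2"))

  bad <- d
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(build_neighbourhood(bad), "symmetric")
  neg <- d
  neg[1, 2] <- neg[2, 1] <- -1
  expect_error(build_neighbourhood(neg), "nonnegative")
})

# independent brute-force pooling used as oracle below
brute_force_pooled <- function(d, radius, demand, supply, norm_minutes) {
  ids <- rownames(d)
  do.call(rbind, lapply(ids, function(i) {
    members <- ids[d[i, ] <= radius]
    dem <- sum(demand$total_minutes[match(members, demand$area_id)])
    fte <- sum(supply$fte[match(members, supply$area_id)])
    data.frame(
      area_id = i,
      workload_per_fte = if (fte > 0) dem / fte else NA_real_,
      fte_needed = dem / norm_minutes,
      fte_balance = fte - dem / norm_minutes,
      stringsAsFactors = FALSE
    )
  }))
}

test_that("pooled confrontation matches brute-force sums on small fixtures", {
  norm <- norm_workload(2350, 31.8)
  for (s in 1:6) {
    n <- 2 + (s %% 5)  # fixtures of 2..6 areas
    pts <- withr::with_seed(300 + s, data.frame(
      area_id = sprintf("F%02d", seq_len(n)),
      centroid_x = runif(n, 0, 6), centroid_y = runif(n, 0, 6)
    ))
    demand <- withr::with_seed(400 + s, data.frame(
      area_id = pts$area_id,
      population = sample(1000:5000, n, replace = TRUE),
      total_minutes = runif(n, 2e4, 2e5),
      stringsAsFactors = FALSE
    ))
    supply <- withr::with_seed(500 + s, data.frame(
      area_id = pts$area_id,
      fte = round(runif(n, 0, 4) * c(1, 0, 1, 1, 1, 1)[seq_len(n)], 2),
      stringsAsFactors = FALSE
    ))
    d <- euclidean_distances(pts)
    idx <- build_neighbourhood(d, radius_km = 3)
    got <- pooled_confrontation(idx, demand, supply, norm)
    want <- brute_force_pooled(d, 3, demand, supply, norm$norm_minutes)
    expect_equal(got$workload_per_fte, want$workload_per_fte)
    expect_equal(got$fte_needed, want$fte_needed)
    expect_equal(got$fte_balance, want$fte_balance)
  }
})

test_that("radius limits reduce pooling to own-area and national results", {
  country <- small_country(seed = 101, n_areas = 20)
  demand <- apply_population_filter(
    predict_area(dutch_gp_coefficients(), country$profiles)
  )
  norm <- norm_workload()
  own <- confront(demand, country$supply, norm)
  d <- euclidean_distances(country$profiles)

  pooled0 <- pooled_confrontation(build_neighbourhood(d, 0), demand,
                                  country$supply, norm)
  cols <- c("demand_minutes", "fte_supply", "workload_per_fte",
            "fte_needed", "fte_balance", "pct_balance")
  expect_equal(pooled0[, cols], own[, cols], ignore_attr = TRUE)

  sat <- pooled_confrontation(build_neighbourhood(d, max(d)), demand,
                              country$supply, norm)
  national <- sum(demand$total_minutes) / sum(country$supply$fte)
  expect_equal(unique(round(sat$workload_per_fte, 6)), round(national, 6))
})

test_that("neighbour surplus compensates a focal shortage", {
  norm <- norm_workload(2350, 31.8)
  demand <- data.frame(
    area_id = c("S", "N"),
    population = c(2000L, 3000L),
    total_minutes = norm$norm_minutes * c(1.0, 1.0),
    stringsAsFactors = FALSE
  )
  supply <- data.frame(area_id = c("S", "N"), fte = c(0.5, 2.0),
                       stringsAsFactors = FALSE)
  pts <- data.frame(area_id = c("S", "N"), centroid_x = c(0, 2),
                    centroid_y = c(0, 0))
  own <- confront(demand, supply, norm)
  expect_equal(own$fte_balance, c(-0.5, 1.0))
  pooled <- pooled_confrontation(
    build_neighbourhood(euclidean_distances(pts), 3), demand, supply, norm
  )
  expect_equal(pooled$fte_balance, c(0.5, 0.5))
})

test_that("the count of no-GP areas never increases with the radius", {
  country <- small_country(seed = 111, n_areas = 25)
  demand <- predict_area(dutch_gp_coefficients(), country$profiles)
  d <- euclidean_distances(country$profiles)
  norm <- norm_workload()
  n_no_gp <- vapply(c(0, 1, 2, 4, 8, 16), function(r) {
    pooled <- pooled_confrontation(build_neighbourhood(d, r), demand,
                                   country$supply, norm)
    sum(is.na(pooled$workload_per_fte))
  }, numeric(1))
  expect_true(all(diff(n_no_gp) <= 0))
})

test_that("compensation reports compare own and pooled shortages", {
  country <- small_country(seed = 121, n_areas = 20)
  demand <- apply_population_filter(
    predict_area(dutch_gp_coefficients(), country$profiles)
  )
  norm <- norm_workload()
  own <- confront(demand, country$supply, norm)
  d <- euclidean_distances(country$profiles)
  pooled0 <- pooled_confrontation(build_neighbourhood(d, 0), demand,
                                  country$supply, norm)
  rep0 <- compensation_report(own, pooled0)
  expect_equal(rep0$pct_areas_compensated, 0)
  expect_equal(rep0$own$pct_areas_shortage, rep0$pooled$pct_areas_shortage)

  # fixture where pooling clears every shortage
  demand2 <- data.frame(area_id = c("S", "N"), population = c(2000L, 2000L),
                        total_minutes = c(74730, 74730),
                        stringsAsFactors = FALSE)
  supply2 <- data.frame(area_id = c("S", "N"), fte = c(0.5, 4),
                        stringsAsFactors = FALSE)
  pts2 <- data.frame(area_id = c("S", "N"), centroid_x = c(0, 1),
                     centroid_y = c(0, 0))
  own2 <- confront(demand2, supply2, norm)
  pooled2 <- pooled_confrontation(
    build_neighbourhood(euclidean_distances(pts2), 3), demand2, supply2, norm
  )
  rep2 <- compensation_report(own2, pooled2)
  expect_equal(rep2$pooled$pct_areas_shortage, 0)
  expect_equal(rep2$own$pct_areas_shortage, 50)

  expect_error(compensation_report(own, pooled0[-1, ]), "same areas")
})
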