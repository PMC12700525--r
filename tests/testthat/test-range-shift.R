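test_that("km_from_equator is the fixed-constant meridian arc", {
  expect_equal(km_from_equator(0), 0)
  expect_equal(km_from_equator(45), 45 * KM_DEG)
  set.seed(2)
  lats <- sort(runif(20, -90, 90))
  expect_true(all(diff(km_from_equator(lats)) >= 0))
  expect_error(km_from_equator(91), "latitude")
})

test_that("the range-limit estimator matches the brute-force oracle", {
  expect_equal(northern_range_limit(40:55, k = 10), 50.5 * KM_DEG)
  expect_equal(northern_range_limit(rep(42.5, 12), k = 10), 42.5 * KM_DEG)
  expect_error(northern_range_limit(runif(9, 40, 50), k = 10),
               class = "odoshift_insufficient_points")
  set.seed(21)
  for (i in 1:200) {
    k <- sample(c(1L, 5L, 10L), 1)
    n <- sample(k:150, 1)
    lats <- runif(n, -20, 70)
    expect_equal(northern_range_limit(lats, k), oracle_limit_km(lats, k))
  }
})

test_that("range shifts are antisymmetric, translation-equivariant and zero for identical sets", {
  cfg <- fast_config()
  set.seed(4)
  lats <- runif(40, 40, 50)
  rec <- rbind(make_records("a", lats, period = "historical"),
               make_records("a", lats, period = "recent"))
  expect_equal(compute_range_shifts(rec, cfg)$shift_km, 0)

  rec2 <- rbind(make_records("a", runif(30, 40, 50), period = "historical"),
                make_records("a", runif(30, 42, 52), period = "recent"))
  fwd <- compute_range_shifts(rec2, cfg)
  swapped <- rec2
  swapped$period <- ifelse(rec2$period == "historical", "recent", "historical")
  expect_equal(compute_range_shifts(swapped, cfg)$shift_km, -fwd$shift_km)

  up <- rec2
  up$latitude <- up$latitude + 3
  shifted <- compute_range_shifts(up, cfg)
  expect_equal(shifted$shift_km, fwd$shift_km)
  expect_equal(shifted$limit_historical_km,
               fwd$limit_historical_km + 3 * KM_DEG)

  expect_error(compute_range_shifts(rec2[0, ], cfg), "empty")
})

test_that("species without enough points in a period are excluded with a log", {
  cfg <- fast_config()
  rec <- rbind(make_records("rich", runif(30, 40, 50), period = "historical"),
               make_records("rich", runif(30, 40, 50), period = "recent"),
               make_records("sparse", runif(9, 40, 50), period = "historical"),
               make_records("sparse", runif(30, 40, 50), period = "recent"))
  expect_message(out <- compute_range_shifts(rec, cfg), "sparse")
  expect_setequal(out$species, "rich")
})

test_that("spatial randomization preserves counts, bounds and pinned extremes", {
  cfg <- fast_config()
  set.seed(8)
  rec <- rbind(make_records("a", runif(50, 40, 50),
                            longitude = runif(50, 0, 10), period = "historical"),
               make_records("a", runif(80, 41, 51),
                            longitude = runif(80, 0, 10), period = "recent"),
               make_records("b", c(43, 47), longitude = c(2, 5),
                            period = "historical"),
               make_records("b", runif(30, 40, 50),
                            longitude = runif(30, 0, 10), period = "recent"))
  rand <- randomize_occurrences_spatial(rec, cfg, seed = 1)
  expect_identical(randomize_occurrences_spatial(rec, cfg, seed = 1), rand)

  # per-stratum counts preserved and latitudes inside the observed box
  for (sp in c("a", "b")) for (pd in c("historical", "recent")) {
    o <- rec[rec$species == sp & rec$period == pd, ]
    r <- rand[rand$species == sp & rand$period == pd, ]
    expect_equal(nrow(r), nrow(o))
    box <- rec[rec$species == sp, ]  # default pools bounds across periods
    expect_true(all(r$latitude >= min(box$latitude) - 1e-12 &
                      r$latitude <= max(box$latitude) + 1e-12))
  }

  # an n=2 stratum under per-period point pinning is exactly the observed
  # points (forced: both records attain the stratum extremes)
  cfg_pp <- fast_config(null_extremes_per_period = TRUE,
                        null_fix_extreme_points = TRUE)
  rand_pp <- randomize_occurrences_spatial(rec, cfg_pp, seed = 2)
  b_h <- sort_records(rand_pp[rand_pp$species == "b" &
                                rand_pp$period == "historical", ])
  expect_equal(b_h$latitude, c(43, 47))
  expect_equal(b_h$longitude, c(2, 5))
})

test_that("the null limit of dense uniform strata matches order-statistic theory", {
  # oracle: mean of the top-10 order statistics of n uniforms on [a, b]
  # approaches b - (b - a) * (k + 1) / (2 (n + 1))
  cfg <- fast_config()
  n <- 600
  set.seed(30)
  rec <- rbind(make_records("a", runif(n, 40, 50),
                            longitude = runif(n, 0, 5), period = "historical"),
               make_records("a", runif(n, 40, 50),
                            longitude = runif(n, 0, 5), period = "recent"))
  a <- min(rec$latitude); b <- max(rec$latitude)
  theory_deg <- b - (b - a) * 11 / (2 * (n + 1))
  set.seed(31)
  lims <- replicate(150, {
    r <- randomize_occurrences_spatial(rec, cfg, seed = NULL)
    northern_range_limit(r$latitude[r$period == "recent"], 10) / KM_DEG
  })
  mc_direct <- replicate(150, {
    mean(sort(runif(n, a, b), decreasing = TRUE)[1:10])
  })
  expect_equal(mean(lims), theory_deg, tolerance = 0.002)
  expect_equal(mean(lims), mean(mc_direct), tolerance = 0.005)
})

test_that("feeding a null iteration back as observed gives slope 1 with tiny p", {
  cfg <- fast_config(n_null_iterations = 3)
  sc <- small_scenario(n_species = 4, n = 250, seed = 13)
  rec <- suppressMessages(
    assign_periods(simulate_occurrences(sc, seed = 13), cfg))
  set.seed(99)
  first_null <- suppressMessages(
    randomize_occurrences_spatial(rec, cfg, seed = NULL))
  obs_from_null <- suppressMessages(compute_range_shifts(first_null, cfg))
  out <- suppressWarnings(suppressMessages(
    null_model_range(rec, cfg, seed = 99, observed = obs_from_null)))
  expect_equal(out$iterations$slope[1], 1, tolerance = 1e-8)
  expect_lt(out$iterations$p[1], 1e-8)
  # reproducible under the same master seed
  out2 <- suppressWarnings(suppressMessages(
    null_model_range(rec, cfg, seed = 99, observed = obs_from_null)))
  expect_identical(out$iterations, out2$iterations)
})
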