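test_that("reading validates, drops and logs malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_records(c("a", "a", "b", ""), latitude = c(45, 46, 47, 48))
  df$doy[2] <- 400
  write_occurrences(df, path)
  expect_message(got <- read_occurrences(path), "missing species")
  expect_equal(nrow(got), 2)

  # round trip of a clean table
  clean <- make_records(c("a", "b"), latitude = c(45.5, 46.25),
                        longitude = c(1.5, 2.25), year = c(1990, 2010),
                        doy = c(120, 130))
  write_occurrences(clean, path)
  expect_equal(read_occurrences(path), clean)

  # missing column and empty file are hard errors
  utils::write.csv(clean[setdiff(names(clean), "doy")], path,
                   row.names = FALSE)
  expect_error(read_occurrences(path), "doy")
  utils::write.csv(clean[0, ], path, row.names = FALSE)
  expect_error(read_occurrences(path), "empty|no valid")
})

test_that("deduplication keeps one row per unique observation and is idempotent", {
  df <- make_records(c("a", "a", "a"), latitude = c(45, 45, 45),
                     doy = c(150, 150, 151))
  d1 <- suppressMessages(deduplicate(df))
  expect_equal(nrow(d1), 2)  # rows differing only in doy both kept
  expect_identical(suppressMessages(deduplicate(d1)), d1)
})

test_that("densest-continent restriction follows counts with a europe tie-break", {
  na <- make_records("a", latitude = 40 + seq_len(100) / 100,
                     continent = "north_america")
  eu <- make_records("a", latitude = 50 + seq_len(40) / 100,
                     continent = "europe")
  kept <- suppressMessages(restrict_to_densest_continent(rbind(na, eu)))
  expect_true(all(kept$continent == "north_america"))
  expect_equal(nrow(kept), 100)

  # single-continent species unchanged
  expect_identical(restrict_to_densest_continent(na), na)

  # exact tie goes to europe, logged
  tie <- rbind(na[1:40, ], eu)
  expect_message(kept_tie <- restrict_to_densest_continent(tie), "tie")
  expect_true(all(kept_tie$continent == "europe"))
})

test_that("period assignment uses inclusive bounds and drops the gap", {
  cfg <- analysis_config()
  df <- make_records("a", latitude = 45, year = c(1980, 2002, 2005, 2008, 2018))
  out <- suppressMessages(assign_periods(df, cfg))
  expect_equal(out$period[out$year %in% c(1980, 2002)],
               c("historical", "historical"))
  expect_equal(out$period[out$year %in% c(2008, 2018)],
               c("recent", "recent"))
  expect_false(2005 %in% out$year)
  expect_error(suppressMessages(
    assign_periods(make_records("a", 45, year = 2005), cfg)), "no records")
})

test_that("dedup, continent restriction and period assignment commute on generated data", {
  sc <- small_scenario(n_species = 3, n = 60, seed = 9)
  occ <- simulate_occurrences(sc, seed = 9)
  set.seed(11)
  occ <- rbind(occ, occ[sample.int(nrow(occ), 40), ])  # inject duplicates
  cfg <- fast_config()
  f <- list(d = deduplicate, c = restrict_to_densest_continent,
            p = function(x) assign_periods(x, cfg))
  orders <- list(c("d", "c", "p"), c("c", "d", "p"), c("p", "d", "c"),
                 c("d", "p", "c"), c("c", "p", "d"), c("p", "c", "d"))
  results <- lapply(orders, function(o) {
    x <- occ
    for (step in o) x <- suppressMessages(f[[step]](x))
    sort_records(x)
  })
  for (r in results[-1]) expect_equal(r, results[[1]])
})

test_that("quadrat assignment is equal-area, translated consistently, and coarsens", {
  idx100 <- build_quadrat_index(100)
  expect_error(build_quadrat_index(0), "positive")

  # two points ~1 km apart near a cell centre share a 100-km cell
  base <- assign_quadrats(data.frame(latitude = 45.2, longitude = -70.3), idx100)
  near <- assign_quadrats(data.frame(latitude = 45.2 + 0.009,
                                     longitude = -70.3), idx100)
  expect_identical(base[c("cell_x", "cell_y")], near[c("cell_x", "cell_y")])

  # 250 projected km east-west always crosses a 100-km cell boundary
  lon_step <- 250 / (6371.0072 * pi / 180)  # degrees giving 250 km in x
  a <- assign_quadrats(data.frame(latitude = 50, longitude = 10), idx100)
  b <- assign_quadrats(data.frame(latitude = 50, longitude = 10 + lon_step),
                       idx100)
  expect_true((b$cell_x - a$cell_x) %in% c(2L, 3L))

  # translation consistency: one cell width in projected x shifts cell_x by 1
  set.seed(1)
  pts <- data.frame(latitude = runif(200, -60, 70),
                    longitude = runif(200, -170, 169))
  shift_deg <- 100 / (6371.0072 * pi / 180)
  q1 <- assign_quadrats(pts, idx100)
  q2 <- assign_quadrats(transform(pts, longitude = longitude + shift_deg),
                        idx100)
  expect_equal(q2$cell_x, q1$cell_x + 1L)
  expect_equal(q2$cell_y, q1$cell_y)

  # 200-km cells are a coarsening: same-cell points differ < 200 projected km
  idx200 <- build_quadrat_index(200)
  q <- assign_quadrats(pts, idx200)
  xy <- odoshift:::.project_km(idx200, pts$longitude, pts$latitude)
  for (cell in unique(q$cell[duplicated(q$cell)])) {
    in_cell <- q$cell == cell
    expect_lt(diff(range(xy$x[in_cell])), 200)
    expect_lt(diff(range(xy$y[in_cell])), 200)
  }
})

test_that("the quadrat-count species filter cuts exactly at the threshold", {
  # 50 points spaced 2 degrees of longitude apart: all in distinct 100-km cells
  lons <- seq(0, by = 2, length.out = 50)
  sp50 <- make_records("fifty", latitude = 45, longitude = lons)
  sp49 <- make_records("fortynine", latitude = 40, longitude = lons[1:49])
  idx <- build_quadrat_index(100)
  out <- suppressMessages(
    filter_species_by_quadrats(rbind(sp50, sp49), idx, min_quadrats = 50))
  expect_setequal(unique(out$species), "fifty")
  # min_quadrats = 1 is a no-op
  both <- rbind(sp50, sp49)
  expect_equal(sort_records(filter_species_by_quadrats(both, idx, 1)),
               sort_records(both))
  expect_error(suppressMessages(
    filter_species_by_quadrats(sp49, idx, 50)), "all species")
})

test_that("richness per quadrat counts distinct species and is bounded", {
  idx <- build_quadrat_index(100)
  one <- make_records("a", latitude = 45, longitude = 5, period = "historical")
  r1 <- richness_per_quadrat(one, idx)
  expect_equal(r1$n_species, 1)

  sc <- small_scenario(n_species = 4, n = 100, seed = 3)
  occ <- assign_periods(simulate_occurrences(sc, seed = 3), fast_config())
  r <- richness_per_quadrat(occ, idx)
  expect_true(all(r$n_species >= 1 & r$n_species <= 4))

  # disjoint single-species clouds each count 1
  two <- rbind(make_records("a", latitude = 45, longitude = 0),
               make_records("b", latitude = 45, longitude = 90))
  r2 <- richness_per_quadrat(two, idx)
  expect_true(all(r2$n_species == 1))
  expect_equal(nrow(r2), 2)
})
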