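test_that("weibull_onset handles degenerate inputs and bounds the estimate", {
  d <- weibull_onset(rep(120, 30))
  expect_equal(d$onset, 120)
  expect_equal(d$k_used, 1L)
  expect_equal(d$method, "degenerate")

  two <- weibull_onset(c(110, 112, 112))
  expect_equal(two$onset, 110)
  expect_equal(two$method, "min_fallback")

  set.seed(14)
  for (i in 1:100) {
    x <- 100 + rweibull(sample(25:80, 1), runif(1, 0.8, 3), runif(1, 5, 40))
    est <- weibull_onset(x)
    expect_lte(est$onset, min(x))
    expect_lte(est$k_used, 10L)
  }
  expect_error(weibull_onset(numeric(0)), "non-empty")
})

test_that("weibull_onset is exactly equivariant under time translation", {
  set.seed(15)
  x <- 100 + rweibull(40, 2, 30)
  base <- weibull_onset(x)
  for (c_days in c(-20, 7, 33)) {
    shifted <- weibull_onset(x + c_days)
    expect_equal(shifted$onset, base$onset + c_days, tolerance = 1e-9)
    expect_equal(shifted$k_used, base$k_used)
  }
})

test_that("the onset estimator beats the naive minimum's bias (quick check)", {
  # closed-form naive-minimum bias: scale * Gamma(1 + 1/shape) * n^(-1/shape)
  set.seed(16)
  n <- 25; shape <- 2; scale <- 30
  est <- replicate(150, weibull_onset(100 + rweibull(n, shape, scale))$onset)
  naive_bias <- scale * gamma(1 + 1 / shape) * n^(-1 / shape)
  expect_lt(abs(mean(est) - 100), naive_bias)
})

test_that("quadrat onsets enforce the both-periods rule and the window", {
  cfg <- analysis_config()
  same_place <- function(sp, n, period, onset) {
    set.seed(nchar(sp) + n + onset)
    make_records(sp, latitude = 45 + runif(n, 0, 0.1),
                 longitude = 5 + runif(n, 0, 0.1),
                 doy = as.integer(ceiling(onset + rweibull(n, 2, 30))),
                 period = period)
  }
  rec <- rbind(
    same_place("ok", 30, "historical", 120),
    same_place("ok", 30, "recent", 115),
    same_place("uneven", 30, "historical", 120),  # only 20 recent obs
    same_place("uneven", 20, "recent", 120),
    same_place("late", 30, "historical", 290),    # onset past the window
    same_place("late", 30, "recent", 290))
  est <- suppressMessages(estimate_quadrat_onsets(rec, cfg))
  expect_setequal(unique(est$species), "ok")
  expect_equal(nrow(est), 2)
  expect_true(all(est$n_obs >= cfg$min_obs_per_quadrat))
  expect_true(all(est$onset_doy >= 60 & est$onset_doy <= 244))
})

test_that("phenology shifts average quadrats and apply the shift filter", {
  cfg <- analysis_config()
  est <- data.frame(
    species = "a",
    cell = rep(c("c1", "c2", "c3", "c4"), each = 2),
    cell_x = 0L, cell_y = 0L,
    period = rep(c("historical", "recent"), 4),
    onset_doy = c(120, 115, 130, 123, 140, 131, 150, 110),  # shifts -5 -7 -9 -40
    n_obs = 30L, k_used = 10L)
  out <- suppressMessages(compute_phenology_shifts(est, cfg))
  expect_equal(out$mean_shift_days, -7)
  expect_equal(out$n_quadrats, 3L)
  pq <- attr(out, "per_quadrat")
  expect_setequal(pq$cell, c("c1", "c2", "c3"))

  # a species reduced to < 2 quadrats is excluded
  est_b <- est[est$cell %in% c("c1", "c4"), ]
  est_b$species <- "b"
  expect_error(suppressMessages(compute_phenology_shifts(est_b, cfg)),
               "no species")
})

test_that("shift-filter settings are nested: 25 within 30 within 35", {
  set.seed(18)
  cells <- sprintf("c%02d", 1:12)
  shifts <- c(-34, -29, -24, -12, -5, 0, 4, 11, 23, 28, 33, 20)
  est <- data.frame(
    species = rep("a", 24),
    cell = rep(cells, each = 2),
    cell_x = 0L, cell_y = 0L,
    period = rep(c("historical", "recent"), 12),
    onset_doy = as.vector(rbind(rep(150, 12), 150 + shifts)),
    n_obs = 30L, k_used = 10L)
  kept <- lapply(c(25, 30, 35), function(f) {
    cfg <- analysis_config(shift_filter_days = f)
    attr(suppressMessages(compute_phenology_shifts(est, cfg)),
         "per_quadrat")$cell
  })
  expect_true(all(kept[[1]] %in% kept[[2]]))
  expect_true(all(kept[[2]] %in% kept[[3]]))
  expect_equal(lengths(kept), c(sum(abs(shifts) <= 25), sum(abs(shifts) <= 30),
                                sum(abs(shifts) <= 35)))
})

test_that("quadrat onsets shift with the data under time translation", {
  cfg <- analysis_config()
  set.seed(19)
  n <- 40
  cell_recs <- function(lon) rbind(
    make_records("a", 45 + runif(n, 0, 0.1), longitude = lon,
                 doy = as.integer(ceiling(110 + rweibull(n, 2, 25))),
                 period = "historical"),
    make_records("a", 45 + runif(n, 0, 0.1), longitude = lon,
                 doy = as.integer(ceiling(110 + rweibull(n, 2, 25))),
                 period = "recent"))
  rec <- rbind(cell_recs(5), cell_recs(12), cell_recs(19))
  base <- suppressMessages(estimate_quadrat_onsets(rec, cfg))
  moved <- rec
  moved$doy <- moved$doy + 21L
  shifted <- suppressMessages(estimate_quadrat_onsets(moved, cfg))
  expect_equal(shifted$onset_doy, base$onset_doy + 21, tolerance = 1e-9)
  s_base <- suppressMessages(compute_phenology_shifts(base, cfg))
  s_shift <- suppressMessages(compute_phenology_shifts(shifted, cfg))
  expect_equal(s_shift$mean_shift_days, s_base$mean_shift_days,
               tolerance = 1e-9)
})

test_that("the phenology null model is reproducible and summarized", {
  cfg <- fast_config(n_null_iterations = 5)
  sc <- small_scenario(n_species = 3, n = 800, seed = 23)
  rec <- suppressMessages(
    assign_periods(simulate_occurrences(sc, seed = 23), cfg))
  out1 <- suppressMessages(null_model_phenology(rec, cfg, seed = 7))
  out2 <- suppressMessages(null_model_phenology(rec, cfg, seed = 7))
  expect_identical(out1$iterations, out2$iterations)
  expect_equal(out1$n_iterations, 5)
  expect_true(all(is.finite(out1$iterations$slope)))
  expect_true(all(out1$iterations$p >= 0 & out1$iterations$p <= 1))
})
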