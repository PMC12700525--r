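#' Define a synthetic study scenario with known ground truth
#'
#' A scenario fixes, per species, the position of the historical northern
#' range edge, the true range shift, the emergence-onset day and its true
#' shift, the Weibull parameters of the emergence-date distribution, the
#' latitudinal/longitudinal extent of the range band, the continent, and the
#' per-period sampling intensity. Species ranges are simulated as latitudinal
#' bands with uniform scatter: the downstream statistics depend only on the
#' marginal latitude and day-of-year distributions, so a band is the simplest
#' geometry carrying the relevant ground truth.
#'
#' @param species data.frame with columns `species`, `historical_limit_deg`,
#'   `true_range_shift_km` (positive = northward), `onset_doy`,
#'   `true_phenology_shift_days` (negative = earlier), `weibull_shape`,
#'   `weibull_scale`, `lat_span_deg`, `lon_span_deg`, `lon_center_deg`,
#'   `continent` (`"north_america"` or `"europe"`).
#' @param n_historical,n_recent per-species record counts per period
#'   (recycled if scalar); a recent count larger than the historical one
#'   emulates rising sampling intensity.
#' @param period_historical,period_recent year ranges for the two periods.
#' @param temp_params list with `mean_tmax` (deg C at the reference latitude),
#'   `lat_gradient` (deg C per degree latitude), `seasonal_amplitude` (deg C),
#'   `sd_historical`, `sd_recent` (interannual s.d. of the yearly
#'   flight-season mean, deg C per period).
#' @param noise_sd_days residual s.d. (days) coupling species-level phenology
#'   responses to range responses in [default_scenario()].
#' @param seed integer seed stored with the scenario.
#'
#' @return an object of class `synthetic_scenario`.
#' @seealso [default_scenario()], [simulate_occurrences()],
#'   [simulate_temperature_grid()]
#' @export
synthetic_scenario <- function(species,
                               n_historical,
                               n_recent,
                               period_historical = c(1980L, 2002L),
                               period_recent = c(2008L, 2018L),
                               temp_params = list(mean_tmax = 18,
                                                  lat_gradient = -0.4,
                                                  seasonal_amplitude = 10,
                                                  sd_historical = 0.8,
                                                  sd_recent = 0.8),
                               noise_sd_days = 2,
                               seed = 1L) {
  req <- c("species", "historical_limit_deg", "true_range_shift_km",
           "onset_doy", "true_phenology_shift_days", "weibull_shape",
           "weibull_scale", "lat_span_deg", "lon_span_deg", "lon_center_deg",
           "continent")
  .assert_cols(species, req, "scenario species table")
  if (anyDuplicated(species$species) > 0L)
    stop("species ids must be unique", call. = FALSE)
  if (any(species$weibull_shape <= 0) || any(species$weibull_scale <= 0))
    stop("weibull_shape and weibull_scale must be > 0", call. = FALSE)
  if (any(species$lat_span_deg <= 0) || any(species$lon_span_deg <= 0))
    stop("lat_span_deg and lon_span_deg must be > 0", call. = FALSE)
  if (!all(species$continent %in% c("north_america", "europe")))
    stop("continent must be 'north_america' or 'europe'", call. = FALSE)
  n <- nrow(species)
  n_historical <- rep_len(as.integer(n_historical), n)
  n_recent <- rep_len(as.integer(n_recent), n)
  if (any(n_historical < 0) || any(n_recent < 0))
    stop("sampling counts must be >= 0", call. = FALSE)
  if (period_historical[1] > period_historical[2] ||
      period_recent[1] > period_recent[2] ||
      period_historical[2] >= period_recent[1])
    stop("invalid period bounds", call. = FALSE)
  if (noise_sd_days < 0) stop("noise_sd_days must be >= 0", call. = FALSE)
  for (nm in c("mean_tmax", "lat_gradient", "seasonal_amplitude",
               "sd_historical", "sd_recent")) {
    if (is.null(temp_params[[nm]]))
      stop("temp_params is missing '", nm, "'", call. = FALSE)
  }
  if (temp_params$sd_historical < 0 || temp_params$sd_recent < 0)
    stop("temperature s.d. values must be >= 0", call. = FALSE)

  structure(list(
    n_species = n,
    species = species,
    n_historical = n_historical,
    n_recent = n_recent,
    period_historical = as.integer(period_historical),
    period_recent = as.integer(period_recent),
    temp_params = temp_params,
    noise_sd_days = noise_sd_days,
    seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

#' Default multi-species study scenario
#'
#' The default conditions emulate the structure of a two-continent odonate
#' occurrence aggregation: 20 species split between North America and Europe,
#' historical northern edges staggered over 46-56 deg latitude, range bands
#' 8 deg of latitude by 12 deg of longitude (wide enough to occupy well over
#' 50 100-km quadrats), Weibull(shape 2, scale 30) emergence-date scatter
#' above species onsets of 115-145, and 1200 records per species per period.
#' True range shifts default to an even spread over [-100, +300] km and true
#' phenology shifts are coupled to them with slope -0.03 days/km plus
#' Gaussian noise, so the downstream shift-vs-shift regression has a designed
#' negative relationship.
#'
#' @param n_species number of species (>= 2).
#' @param n_per_period historical per-species record count.
#' @param recent_multiplier multiplier on the recent-period record count
#'   (values > 1 emulate rising sampling intensity).
#' @param range_shifts_km optional vector of true range shifts; default an
#'   even grid on [-100, 300].
#' @param phenology_shifts_days optional vector of true phenology shifts;
#'   default `-0.03 * range_shifts_km + rnorm(0, noise_sd_days)`, drawn with
#'   `seed`.
#' @param noise_sd_days residual s.d. of the phenology/range coupling (days).
#' @param sd_historical,sd_recent interannual temperature s.d. per period.
#' @param seed integer seed.
#' @return a `synthetic_scenario`.
#' @export
#' @examples
#' sc <- default_scenario(n_species = 4, n_per_period = 200, seed = 7)
#' sc$species$true_range_shift_km
default_scenario <- function(n_species = 20L,
                             n_per_period = 1200L,
                             recent_multiplier = 1,
                             range_shifts_km = NULL,
                             phenology_shifts_days = NULL,
                             noise_sd_days = 2,
                             sd_historical = 0.8,
                             sd_recent = 0.8,
                             seed = 1L) {
  if (n_species < 2L) stop("n_species must be >= 2", call. = FALSE)
  ids <- sprintf("sp%02d", seq_len(n_species))
  if (is.null(range_shifts_km))
    range_shifts_km <- seq(-100, 300, length.out = n_species)
  range_shifts_km <- rep_len(range_shifts_km, n_species)
  if (is.null(phenology_shifts_days)) {
    set.seed(seed)
    phenology_shifts_days <- -0.03 * range_shifts_km +
      rnorm(n_species, 0, noise_sd_days)
  }
  phenology_shifts_days <- rep_len(phenology_shifts_days, n_species)
  continent <- rep(c("north_america", "europe"), length.out = n_species)
  species <- data.frame(
    species = ids,
    historical_limit_deg = seq(46, 56, length.out = n_species),
    true_range_shift_km = range_shifts_km,
    onset_doy = round(seq(115, 145, length.out = n_species)),
    true_phenology_shift_days = phenology_shifts_days,
    weibull_shape = 2,
    weibull_scale = 30,
    lat_span_deg = 8,
    lon_span_deg = 12,
    lon_center_deg = ifelse(continent == "north_america", -95, 15),
    continent = continent,
    stringsAsFactors = FALSE
  )
  synthetic_scenario(
    species,
    n_historical = n_per_period,
    n_recent = as.integer(round(n_per_period * recent_multiplier)),
    noise_sd_days = noise_sd_days,
    temp_params = list(mean_tmax = 18, lat_gradient = -0.4,
                       seasonal_amplitude = 10,
                       sd_historical = sd_historical, sd_recent = sd_recent),
    seed = seed
  )
}

#' Simulate occurrence records from a scenario
#'
#' For each species and period the configured number of records is drawn:
#' latitudes uniform over a band whose northern edge is the historical limit
#' (historical period) or the historical limit plus the true shift converted
#' to degrees at 111.195 km/deg (recent period); longitudes uniform over the
#' species' longitude span; years uniform over the period's bounds; and
#' day-of-year equal to `ceiling(onset + Weibull(shape, scale))`, with the
#' onset moved by the true phenology shift in the recent period (so the
#' empirical minimum day never precedes the true onset).
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer seed (defaults to the scenario's seed).
#' @return a data.frame with columns `species`, `latitude`, `longitude`,
#'   `year`, `doy`, `continent`, sorted by species, year, doy, latitude.
#' @export
#' @examples
#' occ <- simulate_occurrences(default_scenario(4, 100), seed = 1)
#' head(occ)
simulate_occurrences <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(seed)
  sp <- scenario$species
  out <- vector("list", scenario$n_species * 2L)
  idx <- 0L
  for (i in seq_len(scenario$n_species)) {
    for (period in c("historical", "recent")) {
      idx <- idx + 1L
      n <- if (period == "historical") scenario$n_historical[i] else
        scenario$n_recent[i]
      if (n == 0L) next
      edge <- sp$historical_limit_deg[i] +
        if (period == "recent") sp$true_range_shift_km[i] / .KM_PER_DEG else 0
      onset <- sp$onset_doy[i] +
        if (period == "recent") sp$true_phenology_shift_days[i] else 0
      yrs <- if (period == "historical") scenario$period_historical else
        scenario$period_recent
      lat <- edge - sp$lat_span_deg[i] * runif(n)
      lon <- sp$lon_center_deg[i] + sp$lon_span_deg[i] * (runif(n) - 0.5)
      doy <- pmin(366, pmax(1, ceiling(onset +
        rweibull(n, shape = sp$weibull_shape[i], scale = sp$weibull_scale[i]))))
      out[[idx]] <- data.frame(
        species = sp$species[i],
        latitude = lat,
        longitude = lon,
        year = .resample(seq.int(yrs[1], yrs[2]), n),
        doy = as.integer(doy),
        continent = sp$continent[i],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(res$species, res$year, res$doy, res$latitude), ]
  rownames(res) <- NULL
  res
}

# cells (on the range grid) covering all species bands of a scenario,
# with a one-cell margin
.scenario_cells <- function(scenario, cell_km = 100) {
  index <- build_quadrat_index(cell_km)
  sp <- scenario$species
  cells <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    edge <- sp$historical_limit_deg[i] +
      max(0, sp$true_range_shift_km[i]) / .KM_PER_DEG
    lat_rng <- c(sp$historical_limit_deg[i] - sp$lat_span_deg[i], edge)
    lon_rng <- sp$lon_center_deg[i] + c(-0.5, 0.5) * sp$lon_span_deg[i]
    xy <- .project_km(index, lon_rng, lat_rng)
    cx <- seq.int(floor(xy$x[1] / cell_km) - 1L, floor(xy$x[2] / cell_km) + 1L)
    cy <- seq.int(floor(xy$y[1] / cell_km) - 1L, floor(xy$y[2] / cell_km) + 1L)
    cells[[i]] <- expand.grid(cell_x = cx, cell_y = cy)
  }
  unique(do.call(rbind, cells))
}

#' Simulate a gridded monthly maximum-temperature series
#'
#' Generates one tmax value per (cell, year, month) for every year of both
#' periods, over the quadrats covering the scenario's species ranges. Monthly
#' values are a deterministic cell mean (latitude gradient) plus a
#' deterministic seasonal cycle plus a single interannual year effect shared
#' by all months of a cell-year, drawn with the period's configured s.d.; the
#' yearly flight-season means therefore have exactly that interannual s.d. in
#' expectation, and an s.d. of zero makes all years of a period identical.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer seed (defaults to the scenario's seed).
#' @param cell_km grid size matching the analysis range grid.
#' @return a data.frame with columns `cell_x`, `cell_y`, `year`, `month`,
#'   `tmax`.
#' @export
simulate_temperature_grid <- function(scenario, seed = scenario$seed,
                                      cell_km = 100) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(seed)
  tp <- scenario$temp_params
  cells <- .scenario_cells(scenario, cell_km)
  years <- c(seq.int(scenario$period_historical[1], scenario$period_historical[2]),
             seq.int(scenario$period_recent[1], scenario$period_recent[2]))
  n_cells <- nrow(cells)
  n_years <- length(years)
  # cell centre latitude from the inverse equal-area projection
  cell_lat <- asin(pmin(1, pmax(-1, (cells$cell_y + 0.5) * cell_km / .EARTH_R_KM))) *
    180 / pi
  base <- tp$mean_tmax + tp$lat_gradient * (cell_lat - 50)
  period_sd <- ifelse(years <= scenario$period_historical[2],
                      tp$sd_historical, tp$sd_recent)
  # one interannual effect per (cell, year), constant across months
  year_eff <- matrix(rnorm(n_cells * n_years), n_cells, n_years) *
    rep(period_sd, each = n_cells)
  months <- 1:12
  seas <- -tp$seasonal_amplitude * cospi(2 * (months - 1) / 12)  # peak in July
  grid <- expand.grid(cell_i = seq_len(n_cells), year_i = seq_len(n_years),
                      month = months)
  data.frame(
    cell_x = cells$cell_x[grid$cell_i],
    cell_y = cells$cell_y[grid$cell_i],
    year = years[grid$year_i],
    month = grid$month,
    tmax = base[grid$cell_i] + seas[grid$month] +
      year_eff[cbind(grid$cell_i, grid$year_i)]
  )
}

#' Simulate a phylogeny and species trait table
#'
#' Grows a pure-birth tree rescaled to unit height, simulates a continuous
#' trait by Brownian motion along it (`signal_mode = "brownian"`) or as
#' i.i.d. standard normals (`"independent"`), and derives the functional
#' traits used by the driver models: flight duration (days) and body size
#' (abdomen length, mm) as positive transforms of independent BM/iid draws,
#' plus categorical breeding-habitat, egg-laying and suborder labels drawn
#' with configurable class probabilities.
#'
#' @param n_species number of tips (>= 3).
#' @param signal_mode `"brownian"` or `"independent"`.
#' @param seed integer seed.
#' @param species optional character vector of tip labels.
#' @param class_probs named list of class probabilities for
#'   `breeding_habitat` (lotic/lentic/both), `egg_laying`
#'   (exophytic/endophytic) and `suborder` (anisoptera/zygoptera).
#' @return list with elements `tree` (an `ape` phylo object, unit height) and
#'   `traits` (data.frame with a raw continuous `trait_bm` column and the
#'   functional traits).
#' @export
simulate_tree_and_traits <- function(n_species,
                                     signal_mode = c("brownian", "independent"),
                                     seed = 1L,
                                     species = NULL,
                                     class_probs = list(
                                       breeding_habitat = c(lotic = 0.4, lentic = 0.4, both = 0.2),
                                       egg_laying = c(exophytic = 0.6, endophytic = 0.4),
                                       suborder = c(anisoptera = 0.6, zygoptera = 0.4))) {
  signal_mode <- match.arg(signal_mode)
  if (n_species < 3L) stop("n_species must be >= 3", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- species %||% sprintf("sp%02d", seq_len(n_species))

  draw <- function() {
    if (signal_mode == "brownian") ape::rTraitCont(tree, model = "BM", sigma = 1)
    else setNames(rnorm(n_species), tree$tip.label)
  }
  z1 <- draw(); z2 <- draw(); z3 <- draw()
  std <- function(z) if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
  traits <- data.frame(
    species = tree$tip.label,
    trait_bm = as.numeric(z1),
    flight_duration = pmax(10, round(75 + 20 * std(z2))),
    body_size = pmax(8, round(32 + 9 * std(z3), 1)),
    breeding_habitat = sample(names(class_probs$breeding_habitat), n_species,
                              replace = TRUE, prob = class_probs$breeding_habitat),
    egg_laying = sample(names(class_probs$egg_laying), n_species,
                        replace = TRUE, prob = class_probs$egg_laying),
    suborder = sample(names(class_probs$suborder), n_species,
                      replace = TRUE, prob = class_probs$suborder),
    stringsAsFactors = FALSE
  )
  rownames(traits) <- NULL
  list(tree = tree, traits = traits)
}

#' Simulate species-level coupled shift responses
#'
#' Direct fixture for the shift-vs-shift regression: draws per-species range
#' shifts as standard normals, sets
#' `phenology_shift = slope * range_shift + Normal(0, noise_sd)`, Z-scores
#' both columns, and alternates continent labels.
#'
#' @param n_species number of species.
#' @param slope true coupling slope (on the pre-scaling variables).
#' @param noise_sd residual standard deviation (>= 0).
#' @param seed integer seed.
#' @return data.frame with `species`, `range_shift_z`, `phenology_shift_z`,
#'   `continent`.
#' @export
#' @examples
#' head(simulate_species_responses(10, -0.45, 1, seed = 2))
simulate_species_responses <- function(n_species, slope, noise_sd, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  range_shift <- rnorm(n_species)
  phen <- slope * range_shift + rnorm(n_species, 0, noise_sd)
  data.frame(
    species = sprintf("sp%02d", seq_len(n_species)),
    range_shift_z = zscore(range_shift),
    phenology_shift_z = zscore(phen),
    continent = rep(c("north_america", "europe"), length.out = n_species),
    stringsAsFactors = FALSE
  )
}
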