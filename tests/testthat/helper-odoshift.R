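# shared fixtures and independent oracles, built in code

KM_DEG <- 111.195

# a fast configuration for unit tests: paper-scale thresholds are exercised
# in dedicated tests; pipelines here use relaxed data-sufficiency filters
fast_config <- function(...) {
  args <- list(...)
  if (is.null(args$min_quadrats_per_species))
    args$min_quadrats_per_species <- 5
  if (is.null(args$n_null_iterations)) args$n_null_iterations <- 10
  do.call(analysis_config, args)
}

# small dense scenario for pipeline-level tests
small_scenario <- function(n_species = 4, n = 400, seed = 1, ...) {
  default_scenario(n_species = n_species, n_per_period = n, seed = seed, ...)
}

# brute-force oracle for the range-limit statistic: full sort, take top k,
# average (kept independent of the package's radix-sort path)
oracle_limit_km <- function(lats, k) {
  mean(rev(lats[order(lats)])[seq_len(k)]) * KM_DEG
}

# occurrence rows at explicit coordinates, recycled over the other fields
make_records <- function(species, latitude, longitude = 0, year = 1990,
                         doy = 150, continent = "europe", period = NULL) {
  df <- data.frame(species = species, latitude = latitude,
                   longitude = longitude, year = year, doy = doy,
                   continent = continent, stringsAsFactors = FALSE)
  if (!is.null(period)) df$period <- period
  df
}

# canonical row order for comparing tables regardless of processing order
sort_records <- function(df) {
  df <- df[do.call(order, df[intersect(c("species", "year", "doy", "latitude",
                                         "longitude"), names(df))]), ]
  rownames(df) <- NULL
  df
}
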