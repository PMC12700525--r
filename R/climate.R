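#' Yearly flight-season mean temperatures per quadrat
#'
#' Arithmetic mean of monthly maximum temperatures over the flight-season
#' months, per cell and year. Cell-years missing any flight month are
#' excluded with a logged count.
#'
#' @param grid data.frame with `cell_x`, `cell_y`, `year`, `month`, `tmax`.
#' @param flight_months months defining the flight season (default
#'   April-October).
#' @return data.frame with `cell_x`, `cell_y`, `year`, `tmax_flight`.
#' @export
#' @examples
#' g <- data.frame(cell_x = 0, cell_y = 0, year = 2000, month = 4:10,
#'                 tmax = c(10, 12, 14, 16, 18, 20, 22))
#' flight_season_yearly_mean(g)$tmax_flight  # 16
flight_season_yearly_mean <- function(grid, flight_months = 4:10) {
  .assert_cols(grid, c("cell_x", "cell_y", "year", "month", "tmax"),
               "temperature grid")
  sub <- grid[grid$month %in% flight_months, , drop = FALSE]
  agg <- aggregate(cbind(tmax_flight = tmax, n_months = 1) ~
                     cell_x + cell_y + year, sub,
                   function(z) c(mean(z), length(z)))
  # aggregate with cbind returns matrices; flatten
  out <- data.frame(cell_x = agg$cell_x, cell_y = agg$cell_y, year = agg$year,
                    tmax_flight = agg$tmax_flight[, 1L],
                    n_months = agg$n_months[, 2L])
  incomplete <- out$n_months < length(flight_months)
  if (any(incomplete))
    .msg("excluded %d cell-year(s) with incomplete flight-month coverage",
         sum(incomplete))
  out <- out[!incomplete, c("cell_x", "cell_y", "year", "tmax_flight")]
  rownames(out) <- NULL
  out
}

#' Coefficient of variation of yearly flight-season means
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. The CV is
#' only meaningful for a ratio-scale variable; temperatures are in deg C as
#' provided, so quadrats whose mean is not positive are flagged (`NA` with a
#' warning) and excluded upstream.
#'
#' @param yearly_means numeric vector (>= 2 values).
#' @return the CV, or `NA` if the mean is not positive.
#' @export
#' @examples
#' quadrat_cv(c(10, 12, 14))  # 2/12
quadrat_cv <- function(yearly_means) {
  if (length(yearly_means) < 2L)
    stop("need at least 2 yearly values for a CV", call. = FALSE)
  m <- mean(yearly_means)
  if (m <= 0) {
    warning("CV undefined for non-positive mean; quadrat flagged",
            call. = FALSE)
    return(NA_real_)
  }
  sd(yearly_means) / m
}

#' Per-species change in flight-season temperature variability
#'
#' For each quadrat and period the interannual CV of yearly flight-season
#' mean tmax is computed (or, in pooled mode, the CV over all monthly values
#' of the period); per species and period those CVs are averaged over the
#' quadrats the species occupies in that period (or the union of both
#' periods' quadrats when `config$cv_occupancy_union` is set). The change is
#' recent minus historical.
#'
#' @param records occurrence data.frame with `period` assigned.
#' @param grid temperature grid data.frame (see
#'   [simulate_temperature_grid()]).
#' @param index the range-scale [build_quadrat_index()].
#' @param config an [analysis_config()].
#' @return data.frame with `species`, `cv_historical`, `cv_recent`,
#'   `delta_cv`.
#' @export
species_delta_cv <- function(records, grid, index, config) {
  .assert_cols(records, c("species", "latitude", "longitude", "period"),
               "records")
  occ <- assign_quadrats(records, index)
  year_period <- function(y)
    ifelse(y >= config$period_historical[1] & y <= config$period_historical[2],
           "historical",
           ifelse(y >= config$period_recent[1] & y <= config$period_recent[2],
                  "recent", NA_character_))
  if (config$cv_pooled_months) {
    vals <- grid[grid$month %in% config$flight_months, , drop = FALSE]
    vals$period <- year_period(vals$year)
    vals <- vals[!is.na(vals$period), ]
    vals$cell <- paste(vals$cell_x, vals$cell_y, sep = ":")
    cv_tab <- aggregate(tmax ~ cell + period, vals,
                        function(z) if (length(z) >= 2L && mean(z) > 0)
                          sd(z) / mean(z) else NA_real_)
    names(cv_tab)[3L] <- "cv"
  } else {
    ym <- suppressMessages(flight_season_yearly_mean(grid, config$flight_months))
    ym$period <- year_period(ym$year)
    ym <- ym[!is.na(ym$period), ]
    ym$cell <- paste(ym$cell_x, ym$cell_y, sep = ":")
    cv_tab <- aggregate(tmax_flight ~ cell + period, ym,
                        function(z) if (length(z) >= 2L && mean(z) > 0)
                          sd(z) / mean(z) else NA_real_)
    names(cv_tab)[3L] <- "cv"
  }

  occupancy <- unique(occ[c("species", "period", "cell")])
  if (config$cv_occupancy_union) {
    cells <- unique(occupancy[c("species", "cell")])
    occupancy <- rbind(
      data.frame(cells[1:2], period = "historical"),
      data.frame(cells[1:2], period = "recent"))
  }
  m <- merge(occupancy, cv_tab, by = c("cell", "period"))
  m <- m[is.finite(m$cv), , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no occupied quadrat has a valid temperature CV", call. = FALSE)
  sp_cv <- aggregate(cv ~ species + period, m, mean)
  h <- sp_cv[sp_cv$period == "historical", c("species", "cv")]
  r <- sp_cv[sp_cv$period == "recent", c("species", "cv")]
  out <- merge(h, r, by = "species", suffixes = c("_historical", "_recent"))
  names(out) <- c("species", "cv_historical", "cv_recent")
  out$delta_cv <- out$cv_recent - out$cv_historical
  omitted <- setdiff(unique(records$species), out$species)
  if (length(omitted) > 0L)
    .msg("omitted %d species without valid CVs in both periods: %s",
         length(omitted), paste(omitted, collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Read a long-format temperature grid CSV
#'
#' @param path CSV with columns `cell_x`, `cell_y`, `year`, `month`, `tmax`.
#' @return validated data.frame.
#' @export
read_temperature_grid <- function(path) {
  g <- utils::read.csv(path)
  .assert_cols(g, c("cell_x", "cell_y", "year", "month", "tmax"),
               "temperature grid file")
  g
}
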