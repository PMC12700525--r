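#' Build an equal-area quadrat index
#'
#' Coordinates are projected with a cylindrical equal-area projection
#' (Lambert form: standard parallel at the equator, authalic sphere of radius
#' 6371.0072 km), and a cell id is the floor of each projected coordinate
#' divided by the cell size. Equal-area cells are what makes a "100 x 100 km
#' quadrat" meaningful; the projection descriptor is stored so outputs are
#' reproducible.
#'
#' @param cell_km cell size in km (> 0).
#' @return an object of class `quadrat_index`.
#' @export
#' @examples
#' idx <- build_quadrat_index(100)
#' assign_quadrats(data.frame(latitude = 45, longitude = -75), idx)
build_quadrat_index <- function(cell_km) {
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0)
    stop("cell_km must be a positive number", call. = FALSE)
  structure(list(
    cell_km = cell_km,
    r_km = .EARTH_R_KM,
    projection = sprintf(
      "cylindrical equal-area; lon_0=0, lat_ts=0, R=%.4f km; cell origin (0,0)",
      .EARTH_R_KM)
  ), class = "quadrat_index")
}

#' @export
print.quadrat_index <- function(x, ...) {
  cat(sprintf("quadrat index: %g x %g km cells\n  %s\n", x$cell_km, x$cell_km,
              x$projection))
  invisible(x)
}

# equal-area projection to km; x is monotone in longitude, y in latitude
.project_km <- function(index, lon, lat) {
  list(x = index$r_km * lon * pi / 180,
       y = index$r_km * sin(lat * pi / 180))
}

#' Assign records to quadrats
#'
#' Adds integer `cell_x`, `cell_y` columns and a combined `cell` id.
#'
#' @param records data.frame with `latitude` and `longitude` columns.
#' @param index a [build_quadrat_index()].
#' @return `records` with cell columns appended.
#' @export
assign_quadrats <- function(records, index) {
  stopifnot(inherits(index, "quadrat_index"))
  .assert_cols(records, c("latitude", "longitude"), "records")
  xy <- .project_km(index, records$longitude, records$latitude)
  records$cell_x <- as.integer(floor(xy$x / index$cell_km))
  records$cell_y <- as.integer(floor(xy$y / index$cell_km))
  records$cell <- paste(records$cell_x, records$cell_y, sep = ":")
  records
}

#' Drop species observed in too few quadrats
#'
#' Counts the distinct cells a species occupies (both periods pooled by
#' default, or requiring the threshold in each period when
#' `config$quadrat_filter_per_period` is set) and removes species below the
#' threshold, logging the removal list.
#'
#' @param records occurrence data.frame (with `period` column if the
#'   per-period mode is used).
#' @param index a [build_quadrat_index()].
#' @param min_quadrats minimum number of distinct cells.
#' @param per_period require the threshold in each period separately.
#' @return filtered data.frame.
#' @export
filter_species_by_quadrats <- function(records, index, min_quadrats,
                                       per_period = FALSE) {
  q <- assign_quadrats(records, index)
  if (per_period) {
    .assert_cols(q, "period", "records")
    counts <- aggregate(cell ~ species + period, q,
                        function(z) length(unique(z)))
    ok_tab <- tapply(counts$cell, counts$species, min)
    n_per <- tapply(counts$period, counts$species, function(z) length(unique(z)))
    keep_sp <- names(ok_tab)[ok_tab >= min_quadrats & n_per == 2L]
  } else {
    counts <- tapply(q$cell, q$species, function(z) length(unique(z)))
    keep_sp <- names(counts)[counts >= min_quadrats]
  }
  removed <- setdiff(unique(records$species), keep_sp)
  if (length(removed) > 0L)
    .msg("removed %d species below the %d-quadrat threshold: %s",
         length(removed), min_quadrats, paste(removed, collapse = ", "))
  out <- records[records$species %in% keep_sp, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("all species were removed by the quadrat-count filter", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Species richness per quadrat
#'
#' Counts distinct species per cell and period (or overall when no `period`
#' column is present).
#'
#' @param records occurrence data.frame.
#' @param index a [build_quadrat_index()].
#' @return data.frame with `cell_x`, `cell_y`, `period`, `n_species`.
#' @export
richness_per_quadrat <- function(records, index) {
  q <- assign_quadrats(records, index)
  if (is.null(q$period)) q$period <- "all"
  out <- aggregate(species ~ cell_x + cell_y + period, q,
                   function(z) length(unique(z)))
  names(out)[names(out) == "species"] <- "n_species"
  out[order(out$period, out$cell_x, out$cell_y), , drop = FALSE]
}
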