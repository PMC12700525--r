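#' Read and validate an occurrence CSV
#'
#' Requires columns `species`, `latitude`, `longitude`, `year`, `doy`,
#' `continent`. Rows with missing species, year or coordinates, and rows
#' failing range validation (latitude in \[-90, 90\], longitude in
#' \[-180, 180\], day-of-year in \[1, 366\]) are dropped with a logged count.
#'
#' @param path path to a CSV file.
#' @return a validated occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("occurrence file is empty: ", path, call. = FALSE)
  validate_occurrences(df)
}

#' Validate an in-memory occurrence table
#'
#' @param records data.frame of occurrence records (see [read_occurrences()]).
#' @return the validated data.frame (invalid rows dropped, counts logged).
#' @export
validate_occurrences <- function(records) {
  .assert_cols(records,
               c("species", "latitude", "longitude", "year", "doy", "continent"),
               "occurrence table")
  for (col in c("latitude", "longitude", "year", "doy"))
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  records$species <- as.character(records$species)

  miss <- is.na(records$species) | records$species == "" |
    is.na(records$year) | is.na(records$latitude) | is.na(records$longitude)
  if (any(miss))
    .msg("dropped %d record(s) with missing species, year or coordinates",
         sum(miss))
  records <- records[!miss, , drop = FALSE]

  bad <- is.na(records$doy) | records$doy < 1 | records$doy > 366 |
    abs(records$latitude) > 90 | abs(records$longitude) > 180
  if (any(bad))
    .msg("dropped %d record(s) failing range validation (lat/lon/doy)",
         sum(bad))
  records <- records[!bad, , drop = FALSE]
  if (nrow(records) == 0L)
    stop("no valid occurrence records remain after validation", call. = FALSE)
  records$year <- as.integer(records$year)
  records$doy <- as.integer(records$doy)
  rownames(records) <- NULL
  records
}

#' Write occurrence records to CSV
#'
#' @param records occurrence data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Collapse exact duplicate observations
#'
#' One record is kept per unique (species, latitude, longitude, year, doy)
#' combination; the operation is idempotent.
#'
#' @param records occurrence data.frame.
#' @return de-duplicated data.frame.
#' @export
deduplicate <- function(records) {
  keep <- !duplicated(records[c("species", "latitude", "longitude", "year", "doy")])
  if (any(!keep)) .msg("collapsed %d duplicate record(s)", sum(!keep))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict each species to its most densely sampled continent
#'
#' Species present on both continents keep only the records of the continent
#' with the larger number of unique observations; ties are broken toward
#' Europe and logged. Sampling density is compared on de-duplicated records
#' so the operation commutes with [deduplicate()].
#'
#' @param records occurrence data.frame with a `continent` column.
#' @return filtered data.frame.
#' @export
restrict_to_densest_continent <- function(records) {
  uniq <- records[!duplicated(records[c("species", "latitude", "longitude",
                                        "year", "doy")]), ]
  tab <- table(uniq$species, uniq$continent)
  if (ncol(tab) < 2L) return(records)
  both <- rownames(tab)[rowSums(tab > 0) > 1L]
  if (length(both) == 0L) return(records)
  keep_cont <- setNames(character(length(both)), both)
  for (sp in both) {
    counts <- tab[sp, ]
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) > 1L) {
      keep_cont[sp] <- "europe"
      .msg("continent tie for %s (%d records each); keeping europe", sp,
           max(counts))
    } else keep_cont[sp] <- winners
  }
  drop <- records$species %in% both &
    records$continent != keep_cont[records$species]
  if (any(drop))
    .msg("dropped %d record(s) from less-sampled continents (%d species)",
         sum(drop), length(both))
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label records with their time period
#'
#' Records are labeled `historical` or `recent` according to the inclusive
#' period bounds of the configuration; records outside both periods are
#' dropped with a logged count.
#'
#' @param records occurrence data.frame.
#' @param config an [analysis_config()].
#' @return data.frame with an added `period` column.
#' @export
assign_periods <- function(records, config) {
  stopifnot(inherits(config, "analysis_config"))
  ph <- config$period_historical
  pr <- config$period_recent
  period <- ifelse(records$year >= ph[1] & records$year <= ph[2], "historical",
                   ifelse(records$year >= pr[1] & records$year <= pr[2],
                          "recent", NA_character_))
  if (anyNA(period))
    .msg("dropped %d record(s) outside both time periods", sum(is.na(period)))
  out <- records[!is.na(period), , drop = FALSE]
  out$period <- period[!is.na(period)]
  if (nrow(out) == 0L)
    stop("no records fall inside either time period", call. = FALSE)
  rownames(out) <- NULL
  out
}
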