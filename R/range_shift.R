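#' Kilometres from the equator
#'
#' Meridian arc distance under a fixed spherical approximation:
#' `latitude * 111.195` km/degree. Using raw latitude rather than a projected
#' coordinate keeps the range-limit statistic projection-independent.
#'
#' @param latitude degrees latitude in \[-90, 90\].
#' @return distance in km (negative south of the equator).
#' @export
#' @examples
#' km_from_equator(45)
km_from_equator <- function(latitude) {
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90))
    stop("latitude must be finite and within [-90, 90]", call. = FALSE)
  latitude * .KM_PER_DEG
}

#' Northern range limit from occurrence latitudes
#'
#' The mean distance from the equator of the `k` most northern points
#' (duplicated latitudes allowed; ties resolved by taking the k largest after
#' a stable sort). Species-periods with fewer than `k` points are not padded:
#' an error of class `odoshift_insufficient_points` is signalled so callers
#' can exclude and log them.
#'
#' @param latitudes numeric vector of record latitudes (degrees).
#' @param k number of northernmost points to average.
#' @return the limit position in km from the equator.
#' @export
#' @examples
#' northern_range_limit(40:55, k = 10) / 111.195  # 50.5 degrees
northern_range_limit <- function(latitudes, k = 10L) {
  if (length(latitudes) < k) {
    stop(structure(class = c("odoshift_insufficient_points", "error", "condition"),
                   list(message = sprintf(
                     "need at least k=%d points, got %d", k, length(latitudes)),
                     call = sys.call(-1))))
  }
  top <- sort(latitudes, decreasing = TRUE, method = "radix")[seq_len(k)]
  mean(km_from_equator(top))
}

#' Per-species northern range-limit shifts between periods
#'
#' Computes the range-limit position per species and period and their
#' difference (recent minus historical; positive = northward). Species whose
#' limit cannot be computed in either period (fewer than `k` records) are
#' omitted and logged.
#'
#' @param records occurrence data.frame with `species`, `latitude`, `period`.
#' @param config an [analysis_config()].
#' @return data.frame with `species`, `limit_historical_km`,
#'   `limit_recent_km`, `shift_km`, `n_historical`, `n_recent`.
#' @export
compute_range_shifts <- function(records, config) {
  .assert_cols(records, c("species", "latitude", "period"), "records")
  if (nrow(records) == 0L) stop("empty occurrence table", call. = FALSE)
  k <- config$k_northernmost
  sp_list <- split(records[c("latitude", "period")], records$species)
  rows <- vector("list", length(sp_list))
  skipped <- character(0)
  for (i in seq_along(sp_list)) {
    d <- sp_list[[i]]
    lat_h <- d$latitude[d$period == "historical"]
    lat_r <- d$latitude[d$period == "recent"]
    if (length(lat_h) < k || length(lat_r) < k) {
      skipped <- c(skipped, names(sp_list)[i])
      next
    }
    lim_h <- northern_range_limit(lat_h, k)
    lim_r <- northern_range_limit(lat_r, k)
    rows[[i]] <- data.frame(species = names(sp_list)[i],
                            limit_historical_km = lim_h,
                            limit_recent_km = lim_r,
                            shift_km = lim_r - lim_h,
                            n_historical = length(lat_h),
                            n_recent = length(lat_r),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L)
    .msg("excluded %d species with < %d points in a period: %s",
         length(skipped), k, paste(skipped, collapse = ", "))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no species had enough points in both periods", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One spatially randomized dataset for the range null model
#'
#' For each stratum (species pooled over periods by default; species-period
#' when `config$null_extremes_per_period` is set) the observed minimum and
#' maximum latitude and longitude are held constant as the bounds of the
#' uniform redraw; with `config$null_fix_extreme_points` the observed records
#' attaining those extremes are additionally retained verbatim as fixed
#' points. The randomization is purely spatial: every record keeps its year,
#' day and period, so per-period counts are preserved under every mode.
#' Strata with fewer than 2 records are copied verbatim and logged.
#'
#' @param records occurrence data.frame with `period` assigned.
#' @param config an [analysis_config()]; `null_fix_extreme_points` and
#'   `null_extremes_per_period` control the pinning behaviour.
#' @param seed integer seed, or `NULL` to draw from the current RNG state
#'   (used inside null-model loops).
#' @return a randomized occurrence data.frame with the same stratum sizes.
#' @export
randomize_occurrences_spatial <- function(records, config, seed = NULL) {
  .assert_cols(records, c("species", "latitude", "longitude", "year", "doy",
                          "period"), "records")
  if (!is.null(seed)) set.seed(seed)
  strat_key <- if (config$null_extremes_per_period)
    interaction(records$species, records$period, drop = TRUE)
  else records$species
  idx_list <- split(seq_len(nrow(records)), strat_key)
  out <- vector("list", length(idx_list))
  n_small <- 0L
  for (s in seq_along(idx_list)) {
    idx <- idx_list[[s]]
    d <- records[idx, , drop = FALSE]
    n <- nrow(d)
    if (n < 2L) {
      n_small <- n_small + 1L
      out[[s]] <- d
      next
    }
    if (config$null_fix_extreme_points) {
      fixed <- unique(c(which.min(d$latitude), which.max(d$latitude),
                        which.min(d$longitude), which.max(d$longitude)))
    } else fixed <- integer(0)
    redraw <- setdiff(seq_len(n), fixed)
    # spatial randomization only: period structure, years and days are kept
    d$latitude[redraw] <- runif(length(redraw), min(d$latitude),
                                max(d$latitude))
    d$longitude[redraw] <- runif(length(redraw), min(d$longitude),
                                 max(d$longitude))
    out[[s]] <- d
  }
  if (n_small > 0L)
    .msg("%d stratum(s) with < 2 records copied verbatim", n_small)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# shared summary for the two null models
.null_outcome <- function(iter_df, kind) {
  ok <- is.finite(iter_df$p)
  structure(list(
    kind = kind,
    iterations = iter_df,
    n_iterations = nrow(iter_df),
    frac_significant = if (any(ok)) mean(iter_df$p[ok] < 0.05) else NA_real_,
    slope_sign = c(negative = sum(iter_df$slope[ok] < 0),
                   positive = sum(iter_df$slope[ok] > 0))
  ), class = "null_model_outcome")
}

#' @export
print.null_model_outcome <- function(x, ...) {
  cat(sprintf("%s null model: %d iterations\n", x$kind, x$n_iterations))
  cat(sprintf("  observed ~ null regressions significant at 0.05: %.1f%%\n",
              100 * x$frac_significant))
  cat(sprintf("  slope sign: %d negative / %d positive\n",
              x$slope_sign["negative"], x$slope_sign["positive"]))
  invisible(x)
}

# observed-vs-null OLS for one iteration; NA when degenerate
.obs_vs_null <- function(obs, null, by = "species", col_obs, col_null) {
  m <- merge(obs[c(by, col_obs)], null[c(by, col_null)], by = by,
             suffixes = c("_obs", "_null"))
  yo <- m[[2L]]; yn <- m[[3L]]
  if (nrow(m) < 3L || sd(yn) == 0 || sd(yo) == 0)
    return(c(slope = NA_real_, p = NA_real_, n = nrow(m)))
  fit <- summary(lm(yo ~ yn))
  c(slope = fit$coefficients[2L, 1L], p = fit$coefficients[2L, 4L],
    n = nrow(m))
}

#' Randomization null model for range shifts
#'
#' Repeatedly randomizes point positions within the observed species-period
#' bounding boxes ([randomize_occurrences_spatial()]), recomputes per-species
#' null range shifts with the full limit pipeline, and regresses the observed
#' shifts on the null shifts (ordinary least squares across species). The
#' summary reports the fraction of iterations whose regression is significant
#' at 0.05: values near the nominal rate indicate the observed shifts are not
#' explained by sampling-intensity changes alone.
#'
#' @param records occurrence data.frame with `period` assigned.
#' @param config an [analysis_config()]; `n_null_iterations` sets the number
#'   of randomized datasets.
#' @param seed master seed for the iteration stream.
#' @param observed optional precomputed result of [compute_range_shifts()].
#' @return a `null_model_outcome` object.
#' @export
null_model_range <- function(records, config, seed = config$seed,
                             observed = NULL) {
  obs <- observed %||% compute_range_shifts(records, config)
  if (nrow(obs) < 2L) stop("need >= 2 species for the null model", call. = FALSE)
  set.seed(seed)
  n_it <- config$n_null_iterations
  res <- matrix(NA_real_, n_it, 3L,
                dimnames = list(NULL, c("slope", "p", "n")))
  for (it in seq_len(n_it)) {
    rand <- suppressMessages(
      randomize_occurrences_spatial(records, config, seed = NULL))
    null_shifts <- suppressMessages(compute_range_shifts(rand, config))
    res[it, ] <- .obs_vs_null(obs, null_shifts, col_obs = "shift_km",
                              col_null = "shift_km")
  }
  iter_df <- data.frame(iteration = seq_len(n_it), res)
  .null_outcome(iter_df, "range-shift")
}
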