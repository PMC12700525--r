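#' Summarize shift tables in the analysis' reporting categories
#'
#' Counts and means over species: how many expanded their northern range
#' limit (shift > 0 km) and their mean expansion; the overall mean range
#' shift; how many maintained or advanced their emergence phenology
#' (shift <= 0 days) and the overall mean phenology shift; and, over species
#' with both metrics, the fractions shifting in both, in one, or in neither
#' dimension (a partition).
#'
#' @param range_shifts output of [compute_range_shifts()].
#' @param phenology_shifts output of [compute_phenology_shifts()], or `NULL`.
#' @return object of class `shift_summary` (a list of counts and means).
#' @export
#' @examples
#' rs <- data.frame(species = c("a", "b", "c"), shift_km = c(10, 20, -5))
#' summarize_shifts(rs)
summarize_shifts <- function(range_shifts, phenology_shifts = NULL) {
  .assert_cols(range_shifts, c("species", "shift_km"), "range shifts")
  expanding <- range_shifts$shift_km > 0
  out <- list(
    n_species_range = nrow(range_shifts),
    n_expanding = sum(expanding),
    frac_expanding = mean(expanding),
    mean_shift_expanders_km = if (any(expanding))
      mean(range_shifts$shift_km[expanding]) else NA_real_,
    mean_shift_km = mean(range_shifts$shift_km)
  )
  if (!is.null(phenology_shifts)) {
    .assert_cols(phenology_shifts, c("species", "mean_shift_days"),
                 "phenology shifts")
    advancing <- phenology_shifts$mean_shift_days <= 0
    out$n_species_phenology <- nrow(phenology_shifts)
    out$n_advancing <- sum(advancing)
    out$frac_advancing <- mean(advancing)
    out$mean_phenology_shift_days <- mean(phenology_shifts$mean_shift_days)
    m <- merge(range_shifts[c("species", "shift_km")],
               phenology_shifts[c("species", "mean_shift_days")],
               by = "species")
    if (nrow(m) > 0L) {
      r <- m$shift_km > 0
      p <- m$mean_shift_days < 0
      out$n_both_metrics <- nrow(m)
      out$frac_shift_both <- mean(r & p)
      out$frac_shift_range_only <- mean(r & !p)
      out$frac_shift_phenology_only <- mean(!r & p)
      out$frac_shift_neither <- mean(!r & !p)
    }
  }
  structure(out, class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("range shifts: %d species; %d expanding north (%.0f%%)\n",
              x$n_species_range, x$n_expanding, 100 * x$frac_expanding))
  cat(sprintf("  mean shift %.1f km overall; %.1f km among expanders\n",
              x$mean_shift_km, x$mean_shift_expanders_km))
  if (!is.null(x$n_species_phenology)) {
    cat(sprintf("phenology shifts: %d species; %d maintaining/advancing (%.0f%%)\n",
                x$n_species_phenology, x$n_advancing, 100 * x$frac_advancing))
    cat(sprintf("  mean shift %.2f days\n", x$mean_phenology_shift_days))
    if (!is.null(x$frac_shift_both))
      cat(sprintf("  both %.0f%% / range only %.0f%% / phenology only %.0f%% / neither %.0f%% (n = %d)\n",
                  100 * x$frac_shift_both, 100 * x$frac_shift_range_only,
                  100 * x$frac_shift_phenology_only, 100 * x$frac_shift_neither,
                  x$n_both_metrics))
  }
  invisible(x)
}

#' Run the full shift-analysis pipeline
#'
#' Orchestrates ingest (validation, de-duplication, continent restriction,
#' period assignment, quadrat-count species filter), range-shift and
#' phenology-shift estimation, the two randomization null models, the
#' temperature-variability metric, predictor assembly with the collinearity
#' screen, the shift-vs-shift model (GLM and phylogenetic mixed model), the
#' drivers-of-range-shift model with backward elimination of non-significant
#' traits, and phylogenetic-signal statistics on both responses. Inputs are
#' either simulated from a [synthetic_scenario()] or supplied as tables.
#'
#' @param config an [analysis_config()].
#' @param scenario a [synthetic_scenario()] used to simulate all inputs when
#'   `occurrences` is `NULL`.
#' @param occurrences,temperature,traits,phylogeny optional observed inputs
#'   (occurrence table, temperature grid, trait table, `ape` tree). All four
#'   must be given together.
#' @param run_null_models logical; compute the two randomization null models
#'   (can be slow for large `n_null_iterations`).
#' @param run_mcmc logical; fit the Bayesian phylogenetic mixed models.
#' @param mcmc_settings list of overrides passed to [fit_phylo_mixed()].
#' @param output_dir if non-`NULL`, tables are written there as CSV plus a
#'   JSON run manifest.
#' @return object of class `odoshift_run`: a list with the stage outputs
#'   (`records`, `range_shifts`, `phenology_shifts`, `delta_cv`,
#'   `predictors`, `screen`, `models`, `signal`, `nulls`, `summary`,
#'   `richness`, `manifest`).
#' @export
run_pipeline <- function(config = analysis_config(),
                         scenario = NULL,
                         occurrences = NULL, temperature = NULL,
                         traits = NULL, phylogeny = NULL,
                         run_null_models = TRUE,
                         run_mcmc = TRUE,
                         mcmc_settings = list(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  seed <- config$seed
  if (is.null(occurrences)) {
    if (is.null(scenario)) scenario <- default_scenario(seed = seed)
    occurrences <- simulate_occurrences(scenario, seed = seed)
    temperature <- simulate_temperature_grid(scenario, seed = seed + 1L,
                                             cell_km = config$grid_km_range)
    tt <- simulate_tree_and_traits(scenario$n_species, "brownian",
                                   seed = seed + 2L,
                                   species = scenario$species$species)
    traits <- tt$traits
    phylogeny <- tt$tree
  } else if (is.null(temperature) || is.null(traits) || is.null(phylogeny)) {
    stop("occurrences, temperature, traits and phylogeny must be supplied together",
         call. = FALSE)
  }

  # ingest
  rec <- validate_occurrences(occurrences)
  rec <- deduplicate(rec)
  rec <- restrict_to_densest_continent(rec)
  rec <- assign_periods(rec, config)
  index_range <- build_quadrat_index(config$grid_km_range)
  rec <- filter_species_by_quadrats(rec, index_range,
                                    config$min_quadrats_per_species,
                                    per_period = config$quadrat_filter_per_period)

  # shift metrics
  range_shifts <- compute_range_shifts(rec, config)
  onsets <- estimate_quadrat_onsets(rec, config)
  phenology_shifts <- compute_phenology_shifts(onsets, config)

  # climate and predictors
  delta_cv <- species_delta_cv(rec, temperature, index_range, config)
  geography <- classify_range_geography(rec, index_range, config)
  predictors <- assemble_predictors(traits, geography, delta_cv,
                                    range_shifts, phenology_shifts)
  screen <- correlation_screen(
    predictors[c("flight_duration", "body_size", "breeding_habitat",
                 "egg_laying", "suborder", "geography", "delta_cv",
                 "range_size")])

  # models
  m1_data <- predictors[complete.cases(predictors[c("shift_km",
                                                    "mean_shift_days")]), ]
  m1_data <- prepare_model_data(m1_data,
                                scale_continuous = c("shift_km",
                                                     "mean_shift_days"))
  m1_formula <- if (length(unique(m1_data$continent)) > 1L)
    mean_shift_days ~ shift_km + continent else mean_shift_days ~ shift_km
  glm_shift_vs_shift <- fit_glm(m1_formula, m1_data)

  m2_data <- predictors[complete.cases(predictors[c("shift_km", "delta_cv")]), ]
  m2_data <- prepare_model_data(m2_data,
                                scale_continuous = c("shift_km", "delta_cv",
                                                     "flight_duration",
                                                     "body_size"))
  cand <- c("geography", "delta_cv", "flight_duration", "body_size",
            "breeding_habitat", "egg_laying")
  usable <- cand[vapply(cand, function(v) {
    z <- m2_data[[v]]
    if (is.numeric(z)) sd(z, na.rm = TRUE) > 0
    else length(unique(z[!is.na(z)])) >= 2L
  }, logical(1))]
  # at small n keep focal predictors first and add traits only while the
  # design retains residual degrees of freedom
  kept <- character(0)
  for (v in usable) {
    trial <- stats::reformulate(c(kept, v), response = "shift_km")
    if (ncol(model.matrix(trial, m2_data)) + 2L <= nrow(m2_data))
      kept <- c(kept, v)
  }
  if (length(kept) < length(usable))
    .msg("omitted %d drivers-model predictor(s) for lack of degrees of freedom: %s",
         length(usable) - length(kept),
         paste(setdiff(usable, kept), collapse = ", "))
  usable <- kept
  if (length(usable) == 0L)
    stop("no usable drivers-model predictors remain", call. = FALSE)
  # drop candidate terms aliased in this sample (possible at small n)
  repeat {
    m2_full <- stats::reformulate(usable, response = "shift_km")
    cf <- coef(lm(m2_full, data = m2_data))
    if (!anyNA(cf)) break
    asgn <- attr(model.matrix(m2_full, m2_data), "assign")
    labs <- attr(stats::terms(m2_full), "term.labels")
    bad <- unique(labs[asgn[is.na(cf)]])
    .msg("dropping aliased predictor(s) before model selection: %s",
         paste(bad, collapse = ", "))
    usable <- setdiff(usable, bad)
    if (length(usable) == 0L)
      stop("no usable drivers-model predictors remain", call. = FALSE)
  }
  drivers <- backward_eliminate(m2_full, m2_data)

  models <- list(shift_vs_shift_glm = glm_shift_vs_shift,
                 drivers_glm = drivers$final,
                 drivers_dropped = drivers$dropped_terms)
  if (run_mcmc) {
    ms <- function(extra) do.call(fit_phylo_mixed,
                                  c(extra, mcmc_settings[setdiff(names(mcmc_settings),
                                                                 names(extra))]))
    tree1 <- ape::keep.tip(phylogeny, m1_data$species)
    models$shift_vs_shift_mcmc <- ms(list(formula = m1_formula, data = m1_data,
                                          phylogeny = tree1,
                                          seed = seed + 3L))
    tree2 <- ape::keep.tip(phylogeny, m2_data$species)
    models$drivers_mcmc <- ms(list(formula = drivers$final$formula,
                                   data = m2_data, phylogeny = tree2,
                                   seed = seed + 4L))
  }

  # phylogenetic signal on both responses
  signal <- list()
  rs <- setNames(range_shifts$shift_km, range_shifts$species)
  rs <- rs[names(rs) %in% phylogeny$tip.label]
  tr_r <- ape::keep.tip(phylogeny, names(rs))
  signal$range_shift <- list(
    lambda = pagels_lambda(rs, tr_r),
    k = blombergs_k(rs, tr_r, n_perm = 999L, seed = seed + 5L))
  ps <- setNames(phenology_shifts$mean_shift_days, phenology_shifts$species)
  ps <- ps[names(ps) %in% phylogeny$tip.label]
  if (length(ps) >= 3L) {
    tr_p <- ape::keep.tip(phylogeny, names(ps))
    signal$phenology_shift <- list(
      lambda = pagels_lambda(ps, tr_p),
      k = blombergs_k(ps, tr_p, n_perm = 999L, seed = seed + 6L))
  }

  nulls <- list()
  if (run_null_models) {
    nulls$range <- null_model_range(rec, config, seed = seed + 7L,
                                    observed = range_shifts)
    nulls$phenology <- null_model_phenology(rec, config, seed = seed + 8L,
                                            observed = phenology_shifts)
  }

  summary <- summarize_shifts(range_shifts, phenology_shifts)
  richness <- list(
    range_grid = richness_per_quadrat(rec, index_range),
    phenology_grid = richness_per_quadrat(
      rec, build_quadrat_index(config$grid_km_phenology)))

  run <- structure(list(
    config = config, records = rec, range_shifts = range_shifts,
    onsets = onsets, phenology_shifts = phenology_shifts,
    delta_cv = delta_cv, geography = geography, predictors = predictors,
    screen = screen, models = models, signal = signal, nulls = nulls,
    summary = summary, richness = richness, manifest = NULL
  ), class = "odoshift_run")
  if (!is.null(output_dir)) run$manifest <- write_run(run, output_dir)
  run
}

#' Write pipeline outputs and a JSON manifest
#'
#' @param run an `odoshift_run`.
#' @param output_dir directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  put(run$range_shifts, "range_shifts.csv")
  put(run$onsets, "phenology_estimates.csv")
  put(run$phenology_shifts, "phenology_shifts.csv")
  put(attr(run$phenology_shifts, "per_quadrat"), "phenology_quadrat_shifts.csv")
  put(run$delta_cv, "species_delta_cv.csv")
  put(run$geography, "range_geography.csv")
  put(run$predictors, "predictors.csv")
  put(run$richness$range_grid, "richness_range_grid.csv")
  put(run$richness$phenology_grid, "richness_phenology_grid.csv")
  put(run$models$shift_vs_shift_glm$terms, "model_shift_vs_shift_glm.csv")
  put(run$models$drivers_glm$terms, "model_drivers_glm.csv")
  if (!is.null(run$models$shift_vs_shift_mcmc)) {
    put(run$models$shift_vs_shift_mcmc$terms, "model_shift_vs_shift_mcmc.csv")
    put(as.data.frame(run$models$shift_vs_shift_mcmc$chains),
        "chains_shift_vs_shift.csv")
    put(run$models$drivers_mcmc$terms, "model_drivers_mcmc.csv")
    put(as.data.frame(run$models$drivers_mcmc$chains), "chains_drivers.csv")
  }
  if (!is.null(run$nulls$range)) {
    put(run$nulls$range$iterations, "null_range_iterations.csv")
    put(run$nulls$phenology$iterations, "null_phenology_iterations.csv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("odoshift")),
    projection = build_quadrat_index(run$config$grid_km_range)$projection,
    seed = run$config$seed,
    config = unclass(run$config),
    summary = unclass(run$summary),
    files = files
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' @export
print.odoshift_run <- function(x, ...) {
  cat("odoshift pipeline run\n")
  print(x$summary)
  cat(sprintf("shift-vs-shift GLM slope %.3f (p = %.3g), pseudo-R2 %.1f%%\n",
              x$models$shift_vs_shift_glm$terms$estimate[2],
              x$models$shift_vs_shift_glm$terms$p[2],
              x$models$shift_vs_shift_glm$pseudo_r2))
  if (!is.null(x$nulls$range))
    cat(sprintf("null models significant at 0.05: range %.1f%%, phenology %.1f%%\n",
                100 * x$nulls$range$frac_significant,
                100 * x$nulls$phenology$frac_significant))
  invisible(x)
}
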