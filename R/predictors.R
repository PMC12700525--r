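#' Classify species range geography and range size
#'
#' Splits the pooled historical occurrence latitudes of each continent at a
#' lower and an upper quantile (terciles by default). A species is `northern`
#' if its historical latitudinal band (10th-90th percentile of its record
#' latitudes) lies entirely above the upper threshold, `southern` if entirely
#' below the lower threshold, and `widespread` otherwise. Species with fewer
#' than 10 historical records are flagged and classified from their full
#' min-max band instead. Range size is the number of distinct range-scale
#' quadrats occupied in the historical period.
#'
#' @param records occurrence data.frame with `period` and `continent`.
#' @param index the range-scale [build_quadrat_index()].
#' @param config an [analysis_config()].
#' @param lower_quantile,upper_quantile latitude quantiles of the pooled
#'   continental occurrences used as thresholds.
#' @return data.frame with `species`, `continent`, `geography`, `range_size`,
#'   `low_n_flag`.
#' @export
classify_range_geography <- function(records, index, config,
                                     lower_quantile = 1 / 3,
                                     upper_quantile = 2 / 3) {
  .assert_cols(records, c("species", "latitude", "period", "continent"),
               "records")
  hist <- records[records$period == "historical", , drop = FALSE]
  if (nrow(hist) == 0L) stop("no historical records", call. = FALSE)
  thr <- lapply(split(hist$latitude, hist$continent), quantile,
                probs = c(lower_quantile, upper_quantile), names = FALSE)
  q <- assign_quadrats(hist, index)
  range_size <- tapply(q$cell, q$species, function(z) length(unique(z)))

  sp_split <- split(hist[c("latitude", "continent")], hist$species)
  out <- data.frame(species = names(sp_split),
                    continent = vapply(sp_split, function(d) d$continent[1L],
                                       character(1)),
                    geography = NA_character_,
                    range_size = as.integer(range_size[names(sp_split)]),
                    low_n_flag = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sp_split)) {
    d <- sp_split[[i]]
    t2 <- thr[[d$continent[1L]]]
    if (nrow(d) < 10L) {
      band <- range(d$latitude)
      out$low_n_flag[i] <- TRUE
    } else {
      band <- quantile(d$latitude, c(0.1, 0.9), names = FALSE)
    }
    out$geography[i] <- if (band[1L] > t2[2L]) "northern"
    else if (band[2L] < t2[1L]) "southern"
    else "widespread"
  }
  if (any(out$low_n_flag))
    .msg("%d species classified from full min-max band (< 10 historical records)",
         sum(out$low_n_flag))
  rownames(out) <- NULL
  out
}

# cross-validated predictive power score of x -> y using an rpart tree;
# numeric targets: 1 - MAE/MAE(median baseline); categorical targets:
# weighted F1 normalized against the majority-class baseline; floored at 0
.pps <- function(x, y, folds = 4L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L * folds) return(NA_real_)
  if (is.character(x)) x <- factor(x)
  if (is.character(y)) y <- factor(y)
  if (length(unique(x)) < 2L) return(0)
  fold <- rep_len(seq_len(folds), n)
  numeric_target <- is.numeric(y)
  pred <- if (numeric_target) numeric(n) else
    factor(rep(levels(y)[1L], n), levels = levels(y))
  base_pred <- pred
  # an unpruned tree, as the cross-validation supplies the regularization
  ctrl <- rpart::rpart.control(cp = 0, maxdepth = 30, minsplit = 2,
                               minbucket = 1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  for (f in seq_len(folds)) {
    tr <- fold != f
    d_tr <- data.frame(x = x[tr], y = if (numeric_target) y[tr] else
      droplevels(y[tr]))
    d_te <- data.frame(x = x[!tr])
    if (numeric_target) {
      fit <- rpart::rpart(y ~ x, data = d_tr, method = "anova",
                          control = ctrl)
      pred[!tr] <- predict(fit, d_te)
      base_pred[!tr] <- median(y[tr])
    } else {
      maj <- names(which.max(table(y[tr])))
      if (nlevels(d_tr$y) < 2L) {
        pred[!tr] <- as.character(d_tr$y[1L])
      } else {
        fit <- rpart::rpart(y ~ x, data = d_tr, method = "class",
                            control = ctrl)
        pred[!tr] <- as.character(predict(fit, d_te, type = "class"))
      }
      base_pred[!tr] <- factor(maj, levels = levels(y))
    }
  }
  if (numeric_target) {
    mae_m <- mean(abs(pred - y))
    mae_b <- mean(abs(base_pred - y))
    if (mae_b == 0) return(if (mae_m == 0) 1 else 0)
    return(max(0, 1 - mae_m / mae_b))
  }
  wf1 <- function(p) {
    lev <- levels(y)
    f1 <- vapply(lev, function(l) {
      tp <- sum(p == l & y == l)
      if (tp == 0) return(0)
      prec <- tp / sum(p == l)
      rec <- tp / sum(y == l)
      2 * prec * rec / (prec + rec)
    }, numeric(1))
    sum(f1 * as.numeric(table(y)[lev])) / length(y)
  }
  f1_m <- wf1(pred)
  f1_b <- wf1(base_pred)
  if (f1_b >= 1) return(0)
  max(0, (f1_m - f1_b) / (1 - f1_b))
}

#' Collinearity screen: Pearson correlations and predictive power scores
#'
#' Pearson r for every numeric predictor pair and a predictive power score
#' (PPS) for every ordered pair. The PPS is a cross-validated decision-tree
#' skill score normalized against a naive baseline (median for numeric
#' targets, majority class for categorical ones) and floored at 0, so it is
#' asymmetric and captures nonlinear and mixed-type dependence. Pairs
#' exceeding the thresholds are flagged. Constant predictors yield `NA`
#' correlations, reported as such.
#'
#' @param predictor_table data.frame; a `species` column, if present, is
#'   ignored.
#' @param r_threshold flag threshold on `|r|`.
#' @param pps_threshold flag threshold on the PPS.
#' @param folds number of cross-validation folds (deterministic assignment in
#'   row order).
#' @return list with `pearson` (matrix), `pps` (matrix, rows = predictor,
#'   columns = target), `flagged` (data.frame of flagged pairs).
#' @export
correlation_screen <- function(predictor_table, r_threshold = 0.7,
                               pps_threshold = 0.5, folds = 4L) {
  df <- predictor_table[setdiff(names(predictor_table), "species")]
  if (ncol(df) < 2L) stop("need at least 2 predictors", call. = FALSE)
  if (nrow(df) < 5L) stop("need at least 5 species", call. = FALSE)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  pearson <- matrix(NA_real_, length(num), length(num),
                    dimnames = list(num, num))
  if (length(num) >= 2L) {
    constant <- vapply(df[num], function(z) sd(z, na.rm = TRUE) == 0,
                       logical(1))
    ok <- num[!constant]
    if (any(constant))
      .msg("constant predictor(s), correlation undefined: %s",
           paste(num[constant], collapse = ", "))
    if (length(ok) >= 2L)
      pearson[ok, ok] <- cor(df[ok], use = "pairwise.complete.obs")
  }
  vars <- names(df)
  pps <- matrix(NA_real_, length(vars), length(vars),
                dimnames = list(vars, vars))
  for (a in vars) for (b in vars) if (a != b)
    pps[a, b] <- .pps(df[[a]], df[[b]], folds = folds)

  flags <- list()
  for (a in vars) for (b in vars) {
    if (a < b && a %in% num && b %in% num &&
        is.finite(pearson[a, b]) && abs(pearson[a, b]) > r_threshold)
      flags[[length(flags) + 1L]] <- data.frame(
        predictor = a, target = b, statistic = "pearson_r",
        value = pearson[a, b])
    if (a != b && is.finite(pps[a, b]) && pps[a, b] > pps_threshold)
      flags[[length(flags) + 1L]] <- data.frame(
        predictor = a, target = b, statistic = "pps", value = pps[a, b])
  }
  flagged <- if (length(flags)) do.call(rbind, flags) else
    data.frame(predictor = character(0), target = character(0),
               statistic = character(0), value = numeric(0))
  list(pearson = pearson, pps = pps, flagged = flagged)
}

#' Assemble the per-species predictor table
#'
#' Merges functional traits, range geography/size, the temperature
#' variability change and (optionally) the two shift responses into one
#' species-level table. Merges are inner joins on `species`; species missing
#' from a component simply drop out of models that need it (listwise
#' deletion happens at model time).
#'
#' @param traits trait data.frame (see [simulate_tree_and_traits()]).
#' @param geography output of [classify_range_geography()].
#' @param delta_cv output of [species_delta_cv()].
#' @param range_shifts optional output of [compute_range_shifts()].
#' @param phenology_shifts optional output of [compute_phenology_shifts()].
#' @return merged data.frame, one row per species.
#' @export
assemble_predictors <- function(traits, geography, delta_cv,
                                range_shifts = NULL, phenology_shifts = NULL) {
  out <- merge(geography, delta_cv[c("species", "delta_cv")], by = "species")
  out <- merge(out, traits[setdiff(names(traits), "trait_bm")], by = "species")
  if (!is.null(range_shifts))
    out <- merge(out, range_shifts[c("species", "shift_km")], by = "species",
                 all.x = TRUE)
  if (!is.null(phenology_shifts))
    out <- merge(out, phenology_shifts[c("species", "mean_shift_days")],
                 by = "species", all.x = TRUE)
  rownames(out) <- NULL
  out
}
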