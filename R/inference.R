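#' Z-score a numeric vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n-1
#' denominator). Constant vectors are an error.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return the scaled vector.
#' @export
zscore <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2L)
    stop("zscore needs at least 2 distinct values", call. = FALSE)
  (values - mean(values, na.rm = TRUE)) / sd(values, na.rm = TRUE)
}

#' Prepare a species-level model frame
#'
#' Applies the reference levels used throughout the analysis (continent:
#' europe; breeding habitat: lotic; range geography: northern; egg laying:
#' exophytic; suborder: anisoptera) and Z-scores the requested continuous
#' columns.
#'
#' @param data species-level data.frame.
#' @param scale_continuous character vector of columns to Z-score.
#' @return the prepared data.frame.
#' @export
prepare_model_data <- function(data, scale_continuous = character(0)) {
  refs <- c(continent = "europe", breeding_habitat = "lotic",
            geography = "northern", egg_laying = "exophytic",
            suborder = "anisoptera")
  for (nm in names(refs)) {
    if (!is.null(data[[nm]])) {
      f <- factor(data[[nm]])
      if (refs[nm] %in% levels(f)) f <- stats::relevel(f, ref = refs[nm])
      data[[nm]] <- f
    }
  }
  for (nm in scale_continuous) {
    if (is.null(data[[nm]])) stop("no column '", nm, "' to scale", call. = FALSE)
    data[[nm]] <- zscore(data[[nm]])
  }
  data
}

# Nagelkerke-normalized likelihood-ratio pseudo-R2, in percent, clamped to
# [0, 100]
.pseudo_r2 <- function(ll_model, ll_null, n) {
  r2_cs <- 1 - exp(-(2 / n) * (ll_model - ll_null))
  r2_max <- 1 - exp((2 / n) * ll_null)
  100 * min(1, max(0, r2_cs / r2_max))
}

#' Gaussian GLM with the analysis' reporting conventions
#'
#' Fits an identity-link Gaussian linear model, reports per-term estimates,
#' standard errors and t-test p-values, the model and intercept-only AIC, and
#' a likelihood-ratio pseudo-R-squared normalized by its maximum (Nagelkerke
#' form), in percent. Rank-deficient designs are an error naming the aliased
#' terms.
#'
#' @param formula model formula.
#' @param data model frame (see [prepare_model_data()]).
#' @return object of class `odoshift_glm`: list with `fit`, `terms`
#'   (data.frame of term, estimate, se, statistic, p), `aic`,
#'   `null_model_criterion`, `pseudo_r2`, `n`.
#' @export
#' @examples
#' d <- simulate_species_responses(40, -0.5, 1, seed = 1)
#' fit_glm(phenology_shift_z ~ range_shift_z + continent, d)
fit_glm <- function(formula, data) {
  fit <- glm(formula, data = data, family = gaussian())
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- nobs(fit)
  if (n < length(coef(fit)) + 1L)
    stop("too few complete cases for the requested model", call. = FALSE)
  s <- summary(fit)$coefficients
  null_fit <- glm(stats::update(formula, . ~ 1), data = fit$model,
                  family = gaussian())
  ll <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(null_fit))
  structure(list(
    fit = fit,
    formula = formula,
    terms = data.frame(term = rownames(s), estimate = s[, 1L], se = s[, 2L],
                       statistic = s[, 3L], p = s[, 4L],
                       row.names = NULL, stringsAsFactors = FALSE),
    aic = stats::AIC(fit),
    null_model_criterion = stats::AIC(null_fit),
    pseudo_r2 = if (is.finite(ll)) .pseudo_r2(ll, ll0, n) else 100,
    n = n
  ), class = "odoshift_glm")
}

#' @export
print.odoshift_glm <- function(x, ...) {
  cat("Gaussian GLM:", deparse(x$formula), sprintf("(n = %d)\n", x$n))
  print(x$terms, digits = 3)
  cat(sprintf("AIC %.2f (null %.2f); pseudo-R2 %.2f%%\n", x$aic,
              x$null_model_criterion, x$pseudo_r2))
  invisible(x)
}

#' Backward elimination of non-significant removable terms
#'
#' Iteratively refits the model after removing the single highest-p removable
#' term (marginal F-tests via `drop1`) until every removable term is
#' significant at `alpha` or none remain. By default only functional traits
#' are removable; focal predictors (range geography, temperature-variability
#' change, shift responses) are protected.
#'
#' @param formula full model formula.
#' @param data model frame.
#' @param alpha significance threshold.
#' @param removable character vector of removable term labels.
#' @return list with `final` (an [fit_glm()] result), `dropped_terms`, `path`
#'   (data.frame of term and p at removal).
#' @export
backward_eliminate <- function(formula, data, alpha = 0.05,
                               removable = c("flight_duration",
                                             "breeding_habitat", "egg_laying",
                                             "body_size", "suborder")) {
  current <- formula
  dropped <- character(0)
  path <- data.frame(term = character(0), p = numeric(0))
  repeat {
    fit <- fit_glm(current, data)
    d1 <- drop1(fit$fit, test = "F")
    terms_here <- intersect(rownames(d1), removable)
    if (length(terms_here) == 0L) break
    pvals <- d1[terms_here, "Pr(>F)"]
    if (all(pvals < alpha, na.rm = TRUE)) break
    worst <- terms_here[which.max(pvals)]
    path <- rbind(path, data.frame(term = worst, p = max(pvals, na.rm = TRUE)))
    dropped <- c(dropped, worst)
    current <- stats::update(current, as.formula(paste(". ~ . -", worst)))
  }
  list(final = fit_glm(current, data), dropped_terms = dropped, path = path)
}
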