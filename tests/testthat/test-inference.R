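test_that("zscore has the standard properties", {
  z <- zscore(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  set.seed(41)
  x <- rnorm(30)
  expect_equal(zscore(zscore(x)), zscore(x), tolerance = 1e-12)
  expect_equal(zscore(3 * x - 7), zscore(x), tolerance = 1e-12)
  expect_equal(zscore(-2 * x), -zscore(x), tolerance = 1e-12)
  expect_error(zscore(rep(5, 4)), "distinct")
})

test_that("fit_glm reports estimates, AICs and the normalized pseudo-R2", {
  set.seed(42)
  d <- data.frame(y = rnorm(40), x = rnorm(40))
  d$y <- 0.8 * d$x + rnorm(40, 0, 0.5)

  # perfect fit: slope 1, pseudo-R2 pegged at 100%
  perfect <- data.frame(y = d$x, x = d$x)
  fp <- fit_glm(y ~ x, perfect)
  expect_equal(fp$terms$estimate[2], 1, tolerance = 1e-10)
  expect_equal(fp$pseudo_r2, 100)

  # z-scored simple regression: slope equals the Pearson correlation
  dz <- data.frame(y = zscore(d$y), x = zscore(d$x))
  fz <- fit_glm(y ~ x, dz)
  expect_equal(fz$terms$estimate[2], cor(d$x, d$y), tolerance = 1e-10)
  expect_lt(fz$null_model_criterion, Inf)
  expect_gt(fz$pseudo_r2, 0)

  # rank-deficient design errors with the aliased term named
  d$x2 <- d$x
  expect_error(fit_glm(y ~ x + x2, d), "x2")

  # pseudo-R2 grows with signal-to-noise
  set.seed(43)
  x <- rnorm(60)
  r2s <- vapply(c(2, 0.8, 0.2), function(s)
    fit_glm(y ~ x, data.frame(y = x + rnorm(60, 0, s), x = x))$pseudo_r2,
    numeric(1))
  expect_true(all(diff(r2s) > 0))
})

test_that("tree covariance matches shared path lengths and is PSD", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  expect_equal(tree_covariance(star), diag(6), ignore_attr = TRUE)

  sisters <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  A <- tree_covariance(sisters)
  expect_equal(A["A", "B"], 0.5)
  expect_equal(A["A", "C"], 0)
  expect_equal(diag(A), c(A = 1, B = 1, C = 1))

  for (s in 1:10) {
    tr <- simulate_tree_and_traits(15, "brownian", seed = s)$tree
    expect_silent(chol(tree_covariance(tr) + 1e-10 * diag(15)))
  }
  expect_error(tree_covariance(sisters, species = c("A", "Z")), "Z")
})

test_that("backward elimination removes only non-significant removable terms", {
  set.seed(44)
  n <- 80
  d <- data.frame(
    species = sprintf("s%02d", 1:n),
    geography = sample(c("northern", "southern", "widespread"), n, TRUE),
    delta_cv = rnorm(n),
    flight_duration = rnorm(n),
    body_size = rnorm(n))
  d$shift_km <- 1.2 * (d$geography == "southern") - 0.8 * d$delta_cv +
    rnorm(n, 0, 0.4)
  out <- backward_eliminate(
    shift_km ~ geography + delta_cv + flight_duration + body_size, d)
  expect_setequal(out$dropped_terms, c("flight_duration", "body_size"))
  final_terms <- attr(terms(out$final$formula), "term.labels")
  expect_setequal(final_terms, c("geography", "delta_cv"))

  # all terms significant: no-op, and the path is deterministic
  d2 <- d
  d2$flight_duration <- 0.9 * d$shift_km + rnorm(n, 0, 0.2)
  out2 <- backward_eliminate(shift_km ~ delta_cv + flight_duration, d2)
  expect_length(out2$dropped_terms, 0)
  rep2 <- backward_eliminate(shift_km ~ delta_cv + flight_duration, d2)
  expect_identical(out2$dropped_terms, rep2$dropped_terms)
  expect_equal(out2$final$terms, rep2$final$terms)
})

test_that("Pagel's lambda maximizes the profile likelihood (grid oracle) and matches phytools", {
  tt <- simulate_tree_and_traits(40, "brownian", seed = 45)
  x <- setNames(tt$traits$trait_bm, tt$traits$species)
  est <- pagels_lambda(x, tt$tree)
  expect_gte(est$lambda, 0)
  expect_lte(est$lambda, 1)

  # grid oracle: no lambda on a 21-point grid beats the returned optimum
  A <- tree_covariance(tt$tree, names(x))
  grid_ll <- vapply(seq(0, 1, length.out = 21),
                    function(l) odoshift:::.lambda_loglik(l, x, A), numeric(1))
  expect_gte(est$loglik + 1e-6, max(grid_ll))

  # independent implementation agreement (phytools)
  ph <- phytools::phylosig(tt$tree, x, method = "lambda", test = TRUE)
  expect_equal(est$lambda, ph$lambda, tolerance = 0.01)
  expect_equal(est$p, ph$P, tolerance = 0.05)
})

test_that("Blomberg's K matches phytools and its permutation p is bounded", {
  tt <- simulate_tree_and_traits(35, "brownian", seed = 46)
  x <- setNames(tt$traits$trait_bm, tt$traits$species)
  est <- blombergs_k(x, tt$tree, n_perm = 499, seed = 1)
  ph <- phytools::phylosig(tt$tree, x, method = "K")
  k_ph <- if (is.list(ph)) ph$K else as.numeric(ph)
  expect_equal(est$k, k_ph, tolerance = 1e-6)
  expect_gte(est$p, 1 / 500)
  expect_lte(est$p, 1)
})

test_that("the Gibbs sampler agrees with OLS on a star tree and is reproducible", {
  set.seed(47)
  n <- 40
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- sprintf("s%02d", 1:n)
  d <- data.frame(species = star$tip.label, x = rnorm(n))
  d$y <- 0.6 * d$x + rnorm(n, 0, 0.6)
  fit <- fit_phylo_mixed(y ~ x, d, star, n_iter = 6000, burnin = 1000,
                         thin = 5, seed = 3)
  ols <- coef(lm(y ~ x, d))
  expect_lt(max(abs(fit$terms$post_mean - ols)), 0.05)
  expect_true(all(fit$terms$pmcmc > 0 & fit$terms$pmcmc <= 1))
  expect_true(is.finite(fit$dic))

  fit2 <- fit_phylo_mixed(y ~ x, d, star, n_iter = 6000, burnin = 1000,
                          thin = 5, seed = 3)
  expect_identical(fit$chains, fit2$chains)
  expect_error(fit_phylo_mixed(y ~ x, d[1:2, ], star), "too few")
})

test_that("the GLM slope test holds its nominal type-I error (quick check)", {
  set.seed(48)
  p <- vapply(1:300, function(i) {
    d <- simulate_species_responses(66, 0, 1, seed = 10000 + i)
    fit_glm(phenology_shift_z ~ range_shift_z, d)$terms$p[2]
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})
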