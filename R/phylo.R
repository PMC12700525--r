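#' Phylogenetic covariance matrix from a tree
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j, scaled
#' so the tree height (maximum root-to-tip distance) is 1. The matrix is
#' symmetric positive semidefinite by construction.
#'
#' @param phylogeny an `ape` phylo object with positive branch lengths.
#' @param species optional character vector; the matrix is checked against
#'   and reordered to these tips, with an error listing any species missing
#'   from the tree.
#' @return species x species covariance matrix.
#' @export
tree_covariance <- function(phylogeny, species = NULL) {
  stopifnot(inherits(phylogeny, "phylo"))
  if (is.null(phylogeny$edge.length) || any(phylogeny$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  A <- ape::vcv(phylogeny)
  A <- A / max(diag(A))
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(A))
    if (length(miss) > 0L)
      stop("species missing from the tree: ", paste(miss, collapse = ", "),
           call. = FALSE)
    A <- A[species, species, drop = FALSE]
  }
  A
}

# GLS profile log-likelihood of a Brownian model with off-diagonal
# covariances multiplied by lambda
.lambda_loglik <- function(lambda, y, A) {
  n <- length(y)
  V <- lambda * A
  diag(V) <- diag(A)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  logdet <- 2 * sum(log(diag(L)))
  one <- rep(1, n)
  Vi_y <- backsolve(L, forwardsolve(t(L), y))
  Vi_1 <- backsolve(L, forwardsolve(t(L), one))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- backsolve(L, forwardsolve(t(L), r))
  s2 <- sum(r * Vi_r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda phylogenetic signal
#'
#' Maximum-likelihood lambda in \[0, 1\] for a continuous trait under a
#' Brownian model whose off-diagonal covariances are multiplied by lambda,
#' with a likelihood-ratio test (chi-squared, 1 df) against lambda = 0.
#'
#' @param x named numeric vector of trait values (names = tip labels).
#' @param phylogeny an `ape` phylo object.
#' @return list with `lambda`, `p`, `loglik`, `loglik0`.
#' @export
pagels_lambda <- function(x, phylogeny) {
  if (is.null(names(x)))
    stop("trait values must be named by species", call. = FALSE)
  A <- tree_covariance(phylogeny, species = names(x))
  if (length(x) < 10L)
    warning("fewer than 10 tips: lambda estimates are unreliable",
            call. = FALSE)
  f <- function(l) .lambda_loglik(l, x, A)
  opt <- tryCatch(optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8),
                  error = function(e)
                    stop("lambda optimization failed: ", conditionMessage(e),
                         call. = FALSE))
  # optimize() can miss a boundary optimum; compare against both endpoints
  cand <- c(0, opt$maximum, 1)
  ll <- vapply(cand, f, numeric(1))
  best <- which.max(ll)
  lambda <- cand[best]
  ll_hat <- ll[best]
  ll0 <- ll[1L]
  p <- pchisq(2 * max(0, ll_hat - ll0), df = 1, lower.tail = FALSE)
  list(lambda = lambda, p = min(1, p), loglik = ll_hat, loglik0 = ll0)
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' K is the observed ratio of the mean squared error around the
#' phylogenetically corrected mean (MSE0) to the GLS mean squared error
#' (MSE), divided by the expectation of that ratio under Brownian motion on
#' the tree. The p-value is the proportion of tip permutations whose ratio is
#' at least the observed one (with a +1 correction), so it is always at least
#' `1 / (n_perm + 1)`.
#'
#' @param x named numeric vector of trait values.
#' @param phylogeny an `ape` phylo object.
#' @param n_perm number of tip permutations.
#' @param seed integer seed for the permutations.
#' @return list with `k`, `p`, `n_perm`.
#' @export
blombergs_k <- function(x, phylogeny, n_perm = 999L, seed = 1L) {
  if (is.null(names(x)))
    stop("trait values must be named by species", call. = FALSE)
  A <- tree_covariance(phylogeny, species = names(x))
  n <- length(x)
  Vi <- solve(A)
  one <- rep(1, n)
  Vi1 <- Vi %*% one
  sum_Vi <- sum(Vi)
  ratio <- function(y) {
    ahat <- sum(crossprod(y, Vi1)) / sum_Vi
    r <- y - ahat
    mse0 <- sum(r^2) / (n - 1)
    mse <- as.numeric(crossprod(r, Vi %*% r)) / (n - 1)
    mse0 / mse
  }
  expected <- (sum(diag(A)) - n / sum_Vi) / (n - 1)
  obs <- ratio(x)
  k <- obs / expected
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) ratio(sample(x)), numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(k = k, p = p, n_perm = as.integer(n_perm))
}
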