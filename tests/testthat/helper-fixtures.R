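# Small-scale fixtures and independent oracles used across the test files.

# A small genome that still has many independent linkage blocks: 2 Morgan
# on 5 Mb, mu chosen so theta = 4 Ne mu G = 100 at ne_small = 50.
small_genome <- function() genome_spec(map_length = 2, bp_per_cM = 25000,
                                       mutation_rate = 1e-7)
ne_small <- 50L

# A population with standing variation for drift/LD tests (cached per
# session: the burn-in is the slow part).
.fixture_env <- new.env(parent = emptyenv())
small_base <- function() {
  if (is.null(.fixture_env$base)) {
    set.seed(101)
    .fixture_env$base <- run_base_population(small_genome(), ne_small, 400L)
  }
  .fixture_env$base
}

# Dense closed-form ridge oracle: unpenalized intercept, penalty lambda on
# every marker effect.  Solves the full (m+1) normal equations directly.
ridge_oracle <- function(y, X, lambda) {
  Z <- cbind(1, X)
  A <- crossprod(Z)
  diag(A) <- diag(A) + c(0, rep(lambda, ncol(X)))
  sol <- solve(A, crossprod(Z, y))
  list(mu = sol[1L], b = drop(sol[-1L]))
}

# Single-site Gibbs sampler for the two-component normal-mixture marker
# model; an independent MCMC oracle for the ICE solver.
gibbs_mixture_oracle <- function(y, X, pi1, s1, s2, se, n_iter = 3000,
                                 burn = 500) {
  n <- nrow(X); m <- ncol(X)
  xtx <- colSums(X^2)
  b <- numeric(m)
  mu <- mean(y)
  r <- y - mu
  bsum <- numeric(m)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    mu_new <- rnorm(1, mu + mean(r), sqrt(se / n))
    r <- r - (mu_new - mu)
    mu <- mu_new
    for (j in seq_len(m)) {
      rhs <- sum(X[, j] * r) + xtx[j] * b[j]
      v1 <- xtx[j]^2 * s1 + xtx[j] * se
      v2 <- xtx[j]^2 * s2 + xtx[j] * se
      ll1 <- log(pi1) - 0.5 * log(v1) - 0.5 * rhs^2 / v1
      ll2 <- log(1 - pi1) - 0.5 * log(v2) - 0.5 * rhs^2 / v2
      w <- 1 / (1 + exp(ll2 - ll1))
      sc <- if (runif(1) < w) s1 else s2
      cj <- xtx[j] + se / sc
      bj <- rnorm(1, rhs / cj, sqrt(se / cj))
      r <- r - X[, j] * (bj - b[j])
      b[j] <- bj
    }
    if (it > burn) { bsum <- bsum + b; kept <- kept + 1L }
  }
  list(b = bsum / kept)
}

# Random standardized genotype-like design matrix.
random_design <- function(n, m) {
  G <- matrix(rbinom(n * m, 2L, 0.5), n, m)
  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  standardize_genotypes(G[, keep, drop = FALSE], p[keep])
}
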