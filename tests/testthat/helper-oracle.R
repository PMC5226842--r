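# Independent numerical oracles used across the suite.
#
# Everything here goes through stats::integrate / direct convolution on the
# closed-form Rasch posterior density, never through the package's samplers,
# so chain output is checked against an independent route.

# unnormalized Rasch posterior density pi(theta | x+) for item difficulties
# delta and a normal(mu, sd) prior: exp(x+ * theta) / prod(1 + exp(theta -
# delta)) * dnorm(theta)
rasch_post_unnorm <- function(theta, score, delta, mu = 0, sd = 1) {
  loglik <- score * theta -
    vapply(theta, function(th) sum(log1p(exp(th - delta))), numeric(1))
  exp(loglik) * dnorm(theta, mu, sd)
}

# posterior mean and variance by adaptive quadrature
rasch_post_moments <- function(score, delta, mu = 0, sd = 1) {
  m0 <- integrate(rasch_post_unnorm, -Inf, Inf, score = score,
                  delta = delta, mu = mu, sd = sd)$value
  m1 <- integrate(function(t) t * rasch_post_unnorm(t, score, delta, mu, sd),
                  -Inf, Inf)$value / m0
  m2 <- integrate(function(t) t^2 * rasch_post_unnorm(t, score, delta, mu, sd),
                  -Inf, Inf)$value / m0
  c(mean = m1, var = m2 - m1^2)
}

# posterior CDF evaluated pointwise by quadrature (for KS tests)
rasch_post_cdf <- function(q, score, delta, mu = 0, sd = 1) {
  m0 <- integrate(rasch_post_unnorm, -Inf, Inf, score = score,
                  delta = delta, mu = mu, sd = sd)$value
  vapply(q, function(x)
    integrate(rasch_post_unnorm, -Inf, x, score = score, delta = delta,
              mu = mu, sd = sd)$value / m0, numeric(1))
}

# prior-predictive score distribution P(x+ = s), s = 0..k, by integrating
# the Poisson-binomial score law over the prior on a fine grid
score_prior_predictive <- function(delta, mu = 0, sd = 1, grid_n = 201) {
  th <- seq(mu - 8 * sd, mu + 8 * sd, length.out = grid_n)
  w <- dnorm(th, mu, sd)
  w <- w / sum(w)
  k <- length(delta)
  mass <- numeric(k + 1)
  for (j in seq_along(th)) {
    p <- plogis(th[j] - delta)
    f <- 1
    for (i in seq_len(k)) f <- c(f * (1 - p[i]), 0) + c(0, f * p[i])
    mass <- mass + w[j] * f
  }
  mass
}

# Monte-Carlo standard error of a chain mean, using the package-independent
# batch-means estimator (so oracle comparisons do not lean on the package's
# own ESS routine)
batch_se <- function(chain, n_batches = 50) {
  n <- length(chain)
  b <- floor(n / n_batches)
  means <- colMeans(matrix(chain[seq_len(b * n_batches)], b, n_batches))
  sd(means) / sqrt(n_batches)
}
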