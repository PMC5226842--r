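test_that("exchange acceptance probability follows the exponential-family ratio", {
  expect_equal(accept_probability(0.3, 1.7, 9, 9), 1)
  expect_equal(accept_probability(1.1, 1.1, 2, 17), 1)
  expect_equal(accept_probability(0, 1, 9, 11), exp(-2))
  expect_error(accept_probability(0, Inf, 1, 1), "finite")
  set.seed(5)
  phi <- accept_probability(rnorm(500), rnorm(500),
                            sample(0:20, 500, TRUE), sample(0:20, 500, TRUE))
  expect_true(all(phi >= 0 & phi <= 1))
})

test_that("cross-prior acceptance includes the prior ratio and matches its closed form", {
  # identical priors: ratio cancels
  pr <- normal_prior(0.3, 1.2)
  expect_equal(
    accept_probability_cross_prior(0.1, 0.9, 7, 5, pr, 1L, 2L),
    accept_probability(0.1, 0.9, 7, 5))
  # latent regression with equal covariate shifts reduces to the plain ratio
  lp_eq <- latent_regression_prior(matrix(c(1, 1), 2, 1), 0.8, 1.5)
  expect_equal(
    accept_probability_cross_prior(0, 1.4, 9, 12, lp_eq, 1L, 2L),
    accept_probability(0, 1.4, 9, 12))
  # worked cross-prior case: shifts 1 and 0, equal scores, exp(+1) -> 1
  lp <- latent_regression_prior(matrix(c(1, 0), 2, 1), 1, 1)
  expect_equal(
    accept_probability_cross_prior(0, 1, 9, 9, lp, 1L, 2L), 1)
  # general identity: exact prior-ratio route equals the shifted-statistic form
  set.seed(8)
  lp2 <- latent_regression_prior(matrix(rnorm(6), 3, 2), c(0.7, -0.4), 0.8)
  for (i in 1:20) {
    p <- sample(3, 1); q <- sample(3, 1)
    tc <- rnorm(1); ts <- rnorm(1)
    so <- sample(0:20, 1); ss <- sample(0:20, 1)
    shift <- as.numeric(lp2$covariates %*% lp2$weights) / 0.8
    closed <- exp(min(0, (ts - tc) * ((so + shift[p]) - (ss + shift[q]))))
    expect_equal(
      accept_probability_cross_prior(tc, ts, so, ss, lp2, p, q),
      closed, tolerance = 1e-10)
  }
})

test_that("composite-sampling proposals follow the mixing distribution", {
  set.seed(21)
  delta <- c(-1, -0.5, 0, 0.5, 1)
  model <- rasch_model(delta)
  prior <- normal_prior()
  stat <- replicate(4e4, generate_proposal(model, prior)$stat_star)
  expected <- score_prior_predictive(delta)
  freq <- tabulate(stat + 1L, nbins = 6) / 4e4
  se <- sqrt(expected * (1 - expected) / 4e4)
  expect_true(all(abs(freq - expected) < 3 * se + 1e-4))
  # degenerate: saturated items give a deterministic statistic
  sat <- rasch_model(c(-50, 50))
  expect_identical(generate_proposal(sat, prior)$stat_star, 1)
  set.seed(3); p1 <- generate_proposal(model, prior)
  set.seed(3); p2 <- generate_proposal(model, prior)
  expect_identical(p1, p2)
})

test_that("closest-statistic selection picks exact matches and breaks ties fairly", {
  expect_identical(svexchange:::select_closest(c(5, 9, 12), 9), 2L)
  set.seed(2)
  picks <- replicate(2000, svexchange:::select_closest(c(8, 10, 3), 9))
  expect_setequal(unique(picks), c(1L, 2L))
  expect_equal(mean(picks == 1L), 0.5, tolerance = 0.05)
})

test_that("one-step updates have the stated rejection and acceptance semantics", {
  model <- rasch_model(rep(0, 5))
  prior <- normal_prior()
  # an exactly-matching proposal is always accepted
  set.seed(9)
  for (r in 1:200) {
    st <- chain_state(thetas = rnorm(1), observed_stats = 2)
    st2 <- sve_step(st, 1L, model, prior)
    if (tail(st2$hit_history, 1)) expect_true(tail(st2$accept_history, 1))
    if (!tail(st2$accept_history, 1))
      expect_identical(st2$thetas, st$thetas)  # rejection keeps theta
  }
})

test_that("oversampling with m = 1 reproduces the original update exactly", {
  model <- rasch_model(rep(0, 6))
  prior <- normal_prior()
  run <- function(stepfun) {
    set.seed(33)
    st <- chain_state(0, 3)
    for (i in 1:150) st <- stepfun(st)
    st
  }
  a <- run(function(s) sve_step(s, 1L, model, prior))
  b <- run(function(s) oversampled_sve_step(s, 1L, model, prior, m = 1L))
  expect_identical(a, b)
  expect_error(oversampled_sve_step(chain_state(0, 3), 1L, model, prior, 0),
               "positive")
})

test_that("oversampled minimum statistic distance is non-increasing in m", {
  set.seed(14)
  model <- rasch_model(seq(-1.5, 1.5, length.out = 20))
  prior <- normal_prior()
  stats <- replicate(50, {
    p <- replicate(30, generate_proposal(model, prior)$stat_star)
    d <- cummin(abs(p - 9))
    expect_true(all(diff(d) <= 0))
  })
})

test_that("rank matching pairs sorted statistics and beats the identity pairing", {
  set.seed(4)
  pairing <- svexchange:::match_by_rank(c(3, 1, 2), c(2, 3, 1))
  t_sorted <- c(3, 1, 2)[pairing$target]
  p_sorted <- c(2, 3, 1)[pairing$proposal]
  expect_identical(t_sorted, c(1, 2, 3))
  expect_identical(p_sorted, c(1, 2, 3))
  expect_true(all(accept_probability(rep(0, 3), rnorm(3),
                                     t_sorted, p_sorted) == 1))
  # rearrangement inequality, brute force over all 4! pairings
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(z) length(unique(z)) == 4), ]
  for (r in 1:20) {
    a <- sample(0:20, 4, TRUE)
    b <- sample(0:20, 4, TRUE)
    sorted_cost <- sum(abs(sort(a) - sort(b)))
    all_costs <- apply(perms, 1, function(pp) sum(abs(a - b[pp])))
    expect_lte(sorted_cost, min(all_costs))
    expect_lte(sorted_cost, sum(abs(a - b)))
  }
})

test_that("matched sweeps use every proposal at most once and record n flags", {
  model <- rasch_model(rep(0, 8))
  prior <- normal_prior()
  set.seed(19)
  st <- chain_state(rnorm(5), c(1, 4, 2, 7, 5))
  st2 <- matched_multistep(st, model, prior)
  expect_length(st2$accept_history, 5)
  expect_length(st2$hit_history, 5)
  expect_identical(st2$observed_stats, st$observed_stats)
  # n = 1 reduces to a single pairing
  st1 <- matched_multistep(chain_state(0, 3), model, prior)
  expect_length(st1$accept_history, 1)
})

test_that("binned proposals land in the open interval and wait geometrically", {
  model <- rasch_model(seq(-1.5, 1.5, length.out = 20))
  prior <- normal_prior()
  set.seed(6)
  bp_inf <- binned_proposal(model, prior, 9, Inf)
  expect_identical(bp_inf$tries, 1L)
  for (r in 1:50) {
    bp <- binned_proposal(model, prior, 19, 2)
    expect_false(bp$capped)
    expect_true(bp$proposal$stat_star > 17 && bp$proposal$stat_star < 21)
  }
  # expected tries = 1 / P(stat in bin): geometric waiting time
  set.seed(61)
  mass <- mean(abs(replicate(2e4, generate_proposal(model, prior)$stat_star)
                   - 9) < 2)
  tries <- replicate(500, binned_proposal(model, prior, 9, 2)$tries)
  se <- sd(tries) / sqrt(500)
  expect_equal(mean(tries), 1 / mass, tolerance = 3 * se / (1 / mass) + 0.02)
  # unreachable bin is capped and surfaced, never an infinite loop
  capped <- binned_proposal(model, prior, 9.5, 0.4, max_tries = 25)
  expect_true(capped$capped)
  expect_identical(capped$tries, 25L)
  expect_error(binned_proposal(model, prior, 9, 0), "half_width")
})

test_that("recycling consumes the proposal stream exactly as specified", {
  counts <- score_counts(9, k = 20)
  tr <- svexchange:::recycle_stream(c(7, 12, 9), c(0.1, 0.2, 0.3), counts)
  expect_identical(tr$used, 3L)
  expect_identical(tr$draws[["9"]], 0.3)
  expect_true(all(tr$remaining == 0L))
  # score_counts validates support
  expect_error(score_counts(21, k = 20), "support")
  expect_error(score_counts(-1, k = 20), "support")
})

test_that("single-score recycling waits 1/p proposals on average", {
  set.seed(77)
  delta <- rep(0, 6)
  model <- rasch_model(delta)
  prior <- normal_prior()
  s <- 2
  p <- score_prior_predictive(delta)[s + 1]
  waits <- replicate(400, recycling_rejection(score_counts(s, 6), model,
                                              prior)$proposals_generated)
  se <- sd(waits) / sqrt(400)
  expect_equal(mean(waits), 1 / p, tolerance = (3 * se + 0.05) / (1 / p))
})

test_that("binned recycling fills bins and applies the exchange correction", {
  set.seed(55)
  model <- rasch_model(rep(0, 10))
  prior <- normal_prior()
  st <- chain_state(rnorm(4), c(2, 3, 6, 7))
  st2 <- binned_recycling_sweep(st, model, prior, breaks = c(0, 5, 10.5))
  expect_length(st2$accept_history, 4)
  expect_gte(attr(st2, "proposals_generated"), 4L)
  expect_error(binned_recycling_sweep(st, model, prior, breaks = c(4, 5)),
               "cover")
})

test_that("identical seeds yield bit-identical chains for every kernel", {
  model <- rasch_model(seq(-1, 1, length.out = 10))
  twice <- function(...) {
    f1 <- sve(..., seed = 123)
    f2 <- sve(..., seed = 123)
    expect_identical(f1$draws, f2$draws)
    expect_identical(f1$accept, f2$accept)
  }
  twice(observed_stats = 4, model = model, iterations = 300)
  twice(observed_stats = 4, model = model, kernel = "oversample", m = 5,
        iterations = 300)
  twice(observed_stats = c(2, 4, 7), model = model, kernel = "match",
        iterations = 300)
  twice(observed_stats = 4, model = model, kernel = "bin", half_width = 2,
        iterations = 300)
  twice(observed_stats = 4, model = model, kernel = "augment",
        iterations = 300)
  twice(observed_stats = c(4, 4, 6), model = model, kernel = "recycle",
        iterations = 50)
})
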