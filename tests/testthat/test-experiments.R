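test_that("fixtures are reproducible draws from the composite scheme", {
  cfg <- experiment_config("custom", k = 20, n = 1000, seed = 5,
                           difficulties = rep(0, 20))
  fx <- generate_fixture(cfg)
  expect_identical(dim(fx$responses), c(1000L, 20L))
  expect_true(all(fx$responses %in% 0:1))
  expect_identical(fx$stats, rowSums(fx$responses))
  # symmetric design: mean prior-predictive score is k/2
  expect_lt(abs(mean(fx$stats) - 10), 3 * sd(fx$stats) / sqrt(1000))
  expect_identical(generate_fixture(cfg), fx)
  # saturated difficulties give an all-zero matrix
  hard <- experiment_config("custom", k = 5, n = 20, seed = 1,
                            difficulties = rep(50, 5))
  expect_true(all(generate_fixture(hard)$responses == 0L))
})

test_that("the reference 2PL design is fixed and its observed pattern hits the target score", {
  a1 <- reference_discriminations(20)
  a2 <- reference_discriminations(20)
  expect_identical(a1, a2)
  expect_true(all(a1 > 0 & a1 < 4))
  m2 <- twopl_model(a1, rep(0, 20))
  x <- observed_pattern_2pl(m2, raw_score = 9, target = 19)
  expect_equal(sum(x), 9)
  expect_lt(abs(sufficient_statistic(m2, x) - 19), 0.5)
  # drawing reference discriminations must not disturb the RNG stream
  set.seed(42); u1 <- runif(1)
  set.seed(42); invisible(reference_discriminations(20)); u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("scenario reductions hold: m = 1 oversampling is plain SVE, n = 1 matching is independent", {
  cfg2 <- experiment_config("fig2", m = c(1L, 5L), iterations = 6000,
                            seed = 3)
  r2 <- run_scenario(cfg2)
  cfg1 <- experiment_config("fig1", iterations = 6000, seed = 3)
  r1 <- run_scenario(cfg1)
  expect_lt(abs(r2$oversampling$acceptance[1] - r1$summary$acceptance),
            0.05)
  expect_gt(r2$oversampling$acceptance[2], r2$oversampling$acceptance[1])

  cfg3 <- experiment_config("fig3", n_grid = 1L, iterations = 6000,
                            seed = 4)
  r3 <- run_scenario(cfg3)
  expect_lt(abs(r3$matching$matched - r3$matching$independent), 0.06)
})

test_that("recycling at n = 1 equals the classical rejection cost", {
  cfg <- experiment_config("fig4", n_grid = 1L, replicates = 300,
                           seed = 6, k = 10)
  r <- run_scenario(cfg)
  expect_lt(abs(r$rejection_cost$recycled - r$rejection_cost$independent) /
              r$rejection_cost$independent, 0.25)
})

test_that("scenario outputs are deterministic given the configuration and written as CSV", {
  cfg <- experiment_config("fig2", m = c(1L, 3L), iterations = 1000,
                           seed = 11)
  expect_identical(run_scenario(cfg), run_scenario(cfg))
  out <- file.path(tempdir(), "svx_scenario")
  cfg$out <- out
  run_scenario(cfg)
  expect_true(file.exists(file.path(out, "fig2_oversampling.csv")))
  meta <- read_config(file.path(out, "fig2_meta.txt"))
  expect_equal(meta$seed, 11)
  unlink(out, recursive = TRUE)
  bad <- experiment_config("fig1")
  bad$scenario <- "nope"
  expect_error(run_scenario(bad), "scenario")
})

test_that("response matrices and config files round-trip through disk", {
  x <- matrix(rbinom(30, 1, 0.5), 5, 6,
              dimnames = list(paste0("p", 1:5), paste0("item", 1:6)))
  f <- tempfile(fileext = ".csv")
  write_responses(x, f)
  y <- read_responses(f)
  expect_identical(unname(y), unname(x))
  expect_identical(rownames(y), paste0("p", 1:5))
  unlink(f)

  cf <- tempfile()
  write_config(list(k = 20, a = c(Inf, 5, 3, 2), scenario = "fig5"), cf)
  back <- read_config(cf)
  expect_equal(back$k, 20)
  expect_equal(back$a, c(Inf, 5, 3, 2))
  expect_identical(back$scenario, "fig5")
  unlink(cf)
})

test_that("the fitted object supports the standard modelling methods", {
  set.seed(8)
  model <- rasch_model(rep(0, 12))
  fx <- generate_fixture(experiment_config("custom", k = 12, n = 6,
                                           difficulties = rep(0, 12),
                                           seed = 2))
  fit <- sve(responses = fx$responses, model = model, iterations = 3000,
             seed = 9)
  expect_s3_class(fit, "sve_fit")
  expect_output(print(fit), "kernel")
  s <- summary(fit)
  expect_s3_class(s, "summary.sve_fit")
  expect_identical(nrow(s$per_person), 6L)
  expect_output(print(s), "person")
  expect_length(coef(fit), 6)
  # higher observed scores give higher posterior means
  ord <- order(fx$stats)
  expect_true(cor(fx$stats, coef(fit)) > 0.8)
  p <- predict(fit)
  expect_identical(dim(p), c(6L, 12L))
  expect_true(all(p > 0 & p < 1))
  expect_length(residuals(fit), 6)
  expect_lt(max(abs(residuals(fit))), 4)
  sims <- simulate(fit, nsim = 2, seed = 10)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), c(6L, 12L))
  expect_true(all(sims[[1]] %in% 0:1))
  pdf(NULL)
  expect_invisible(plot(fit, person = 1))
  dev.off()
  # chain draws round-trip to the draws CSV contract
  f <- tempfile(fileext = ".csv")
  write_draws(fit, f)
  d <- utils::read.csv(f)
  expect_identical(names(d), c("iteration", "person_id", "theta", "accepted"))
  expect_identical(nrow(d), 3000L * 6L)
  unlink(f)
})

test_that("the sampler validates its inputs", {
  model <- rasch_model(rep(0, 4))
  expect_error(sve(model = model), "observed_stats")
  expect_error(sve(responses = matrix(0, 2, 3), model = model), "items")
  expect_error(sve(observed_stats = 2, model = model, iterations = 0),
               "iterations")
  expect_error(sve(observed_stats = 2, model = "x"), "irt_model")
  expect_error(sve(observed_stats = 2.5, model = model,
                   kernel = "recycle"), "support")
  expect_error(sve(observed_stats = 2, model = twopl_model(c(1, 2), c(0, 0)),
                   kernel = "augment"), "Rasch")
})
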