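test_that("the production schedule retains exactly 18,750 draws", {
  cfg <- mcmc_config()
  expect_equal(retained_draws(cfg), 18750)
  expect_equal(cfg$n_chains, 3L)
  expect_equal(cfg$n_sampling, 25000L)
  expect_equal(cfg$thin, 4L)
})

test_that("thinning must divide the sampling run evenly", {
  expect_error(mcmc_config(n_sampling = 1001, thin = 4), "evenly")
})

test_that("identical data, config and seed give identical retained draws", {
  sim <- tiny_dataset(n_cells = 25, seed = 3)
  data <- build_occu_data(sim$detections, sim$covariates,
                          "Forest", character())
  cfg <- fast_config(seed = 77, n_burnin = 100, n_sampling = 200)
  f1 <- fit_occu_mcmc(data, cfg)
  f2 <- fit_occu_mcmc(data, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$z, f2$z)
  f3 <- fit_occu_mcmc(data, fast_config(seed = 78, n_burnin = 100,
                                        n_sampling = 200))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("sampled latent states are 1 wherever a cell-year has a detection", {
  sim <- tiny_dataset(n_cells = 30, seed = 5)
  data <- build_occu_data(sim$detections, sim$covariates,
                          "Forest", character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 9, n_burnin = 100,
                                         n_sampling = 200))
  det <- sim$detections[sim$detections$y == 1, ]
  for (r in seq_len(nrow(det))) {
    i <- match(det$cell_id[r], data$cells)
    t <- match(det$year[r], data$years)
    col <- (i - 1) * data$T + t
    expect_true(all(fit$z[, col] == 1L))
  }
})

test_that("fit agrees with the conjugate Beta posterior under perfect detection", {
  # Perfect detection and intercept-only occupancy, one season: z is observed,
  # so psi has the closed-form Beta(1+k, 1+n-k) posterior under a flat prior.
  d <- build_survey_design(300, n_years = 1, seed = 21)
  cov <- simulate_covariate_table(d, seed = 22)
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 0.2),
                             gamma = 0.5, epsilon = 0.5, seed = 23)
  det <- simulate_detections(truth, d, alpha = c(`(Intercept)` = 30), seed = 24)
  data <- build_occu_data(det, cov, character(), character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 25, n_chains = 3,
                                         n_burnin = 500, n_sampling = 2000,
                                         thin = 2))
  k <- sum(tapply(det$y, det$cell_id, max))
  n <- 300
  beta_mean <- (1 + k) / (2 + n)
  psi_draws <- plogis(fit$draws[, "beta:(Intercept)"])
  mcse <- sd(psi_draws) / sqrt(ess(psi_draws, fit$chain))
  expect_lt(abs(mean(psi_draws) - beta_mean), 3 * mcse + 1e-12)
})

test_that("rhat is near 1 for iid chains and large for separated chains", {
  set.seed(6)
  iid <- lapply(1:3, function(i) rnorm(10000))
  r <- rhat(iid)
  expect_gte(r, 0.99)
  expect_lte(r, 1.02)
  apart <- list(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  expect_gt(rhat(apart), 1.1 * 3)
  const <- list(rep(1, 100), rep(1, 100))
  expect_true(is.na(rhat(const)))
  expect_true(attr(rhat(const), "degenerate"))
})

test_that("posterior summaries match an order-statistic quantile oracle", {
  sim <- tiny_dataset(n_cells = 20, seed = 31)
  data <- build_occu_data(sim$detections, sim$covariates,
                          character(), character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 32, n_burnin = 50,
                                         n_sampling = 40, thin = 2))
  s <- summarize_posterior(fit)
  draws <- fit$draws[, "gamma"]  # 40 pooled draws
  expect_length(draws, 40)
  sorted <- sort(draws)
  # type-7 empirical quantile at prob q over n draws: index 1 + (n-1) q
  q_or <- function(q) {
    h <- 1 + (length(sorted) - 1) * q
    lo <- floor(h); hi <- ceiling(h)
    sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
  }
  row <- s$parameters[s$parameters$parameter == "gamma", ]
  expect_equal(row$lower, q_or(0.025), tolerance = 1e-12)
  expect_equal(row$upper, q_or(0.975), tolerance = 1e-12)
  expect_equal(row$mean, mean(draws), tolerance = 1e-12)
})

test_that("significance flags follow the 95% CrI excluding zero", {
  sim <- tiny_dataset(n_cells = 20, seed = 41)
  data <- build_occu_data(sim$detections, sim$covariates,
                          character(), character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 42, n_burnin = 50,
                                         n_sampling = 100))
  fit$draws[, "beta:(Intercept)"] <- abs(fit$draws[, "beta:(Intercept)"]) + 0.1
  s1 <- summarize_posterior(fit)
  expect_true(s1$parameters$significant[
    s1$parameters$parameter == "beta:(Intercept)"])
  fit$draws[, "beta:(Intercept)"] <-
    fit$draws[, "beta:(Intercept)"] * rep(c(1, -1), length.out = nrow(fit$draws))
  s2 <- summarize_posterior(fit)
  expect_false(s2$parameters$significant[
    s2$parameters$parameter == "beta:(Intercept)"])
})
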