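test_that("second-season occupancy follows the dynamics recursion", {
  expect_equal(derived_second_year_psi(1, gamma = 0.3, epsilon = 0), 1)
  expect_equal(derived_second_year_psi(0, gamma = 0.3, epsilon = 0.9), 0.3)
  expect_equal(derived_second_year_psi(0.5, gamma = 0.2, epsilon = 0.4), 0.40,
               tolerance = 1e-12)
  expect_error(derived_second_year_psi(1.2, 0.1, 0.1), "\\[0,1\\]")
  # convex combination: always a probability
  set.seed(2)
  psi1 <- runif(100); g <- runif(100); e <- runif(100)
  psi2 <- derived_second_year_psi(psi1, g, e)
  expect_true(all(psi2 >= 0 & psi2 <= 1))
})

test_that("all-zero coefficient draws predict psi = 0.5 everywhere in both years", {
  sim <- tiny_dataset(n_cells = 12, seed = 3)
  data <- build_occu_data(sim$detections, sim$covariates, "Forest", character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 4, n_burnin = 50,
                                         n_sampling = 20, thin = 1))
  fit$draws[, c("beta:(Intercept)", "beta:Forest")] <- 0
  fit$draws[, "gamma"] <- 0
  fit$draws[, "epsilon"] <- 0
  grid <- predict_occupancy_grid(fit, sim$covariates)
  expect_true(all(abs(grid$psi_mean - 0.5) < 1e-12))
  expect_true(all(grid$psi_lo <= grid$psi_hi))
})

test_that("a positive slope makes predicted psi1 increase in that covariate", {
  sim <- tiny_dataset(n_cells = 20, seed = 7)
  data <- build_occu_data(sim$detections, sim$covariates, "Forest", character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 8, n_burnin = 50,
                                         n_sampling = 20, thin = 1))
  fit$draws[, "beta:Forest"] <- abs(fit$draws[, "beta:Forest"]) + 0.5
  newcov <- sim$covariates[rep(1, 5), ]
  newcov$cell_id <- paste0("g", 1:5)
  newcov$Forest <- seq(10, 90, length.out = 5)
  grid <- predict_occupancy_grid(fit, newcov)
  y1 <- grid[grid$year == 1, ]
  expect_true(all(diff(y1$psi_mean[match(paste0("g", 1:5), y1$cell_id)]) > 0))
})

test_that("a single-draw posterior reduces the grid to plug-in evaluation", {
  sim <- tiny_dataset(n_cells = 10, seed = 9)
  data <- build_occu_data(sim$detections, sim$covariates, "Forest", character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 10, n_burnin = 50,
                                         n_sampling = 20, thin = 1))
  fit$draws <- fit$draws[5, , drop = FALSE]
  fit$chain <- fit$chain[5]
  fit$z <- fit$z[5, , drop = FALSE]
  grid <- predict_occupancy_grid(fit, sim$covariates)
  beta <- fit$draws[1, c("beta:(Intercept)", "beta:Forest")]
  std <- standardize_covariates(sim$covariates,
                                standardization = list(
                                  center = data$occ_standardization$center,
                                  scale = data$occ_standardization$scale))
  psi1 <- plogis(beta[1] + beta[2] * std$table$Forest)
  got1 <- grid$psi_mean[grid$year == 1]
  expect_equal(got1, unname(psi1), tolerance = 1e-12)
  psi2 <- derived_second_year_psi(psi1, fit$draws[1, "gamma"],
                                  fit$draws[1, "epsilon"])
  expect_equal(grid$psi_mean[grid$year == 2], unname(psi2), tolerance = 1e-12)
  expect_equal(grid$psi_lo[grid$year == 1], unname(psi1), tolerance = 1e-12)
})

test_that("grid means always lie inside the per-draw envelope", {
  sim <- tiny_dataset(n_cells = 15, seed = 11)
  data <- build_occu_data(sim$detections, sim$covariates, "Forest", character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 12, n_burnin = 100,
                                         n_sampling = 100))
  grid <- predict_occupancy_grid(fit, sim$covariates)
  expect_true(all(grid$psi_mean >= 0 & grid$psi_mean <= 1))
  expect_true(all(grid$psi_lo <= grid$psi_hi))
})

test_that("prediction fails loudly when a model covariate is missing from the grid", {
  sim <- tiny_dataset(n_cells = 10, seed = 13)
  data <- build_occu_data(sim$detections, sim$covariates, "Forest", character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 14, n_burnin = 50,
                                         n_sampling = 20, thin = 1))
  bad <- sim$covariates[, setdiff(names(sim$covariates), "Forest")]
  expect_error(predict_occupancy_grid(fit, bad), "Forest")
})

test_that("turnover equals the per-draw fraction of state changes", {
  sim <- tiny_dataset(n_cells = 20, seed = 15)
  data <- build_occu_data(sim$detections, sim$covariates, character(), character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 16, n_burnin = 100,
                                         n_sampling = 100))
  tu <- turnover_summary(fit)
  expect_setequal(tu$quantity, c("gamma", "epsilon", "turnover"))
  expect_true(all(tu$mean >= 0 & tu$mean <= 1))
  expect_true(all(tu$lower <= tu$upper))
  # recompute tau directly from the sampled latent states
  n <- data$n; T <- data$T
  z1 <- fit$z[, (seq_len(n) - 1) * T + 1, drop = FALSE]
  z2 <- fit$z[, (seq_len(n) - 1) * T + 2, drop = FALSE]
  tau <- rowMeans(abs(z2 - z1))
  expect_equal(tu$mean[tu$quantity == "turnover"], mean(tau), tolerance = 1e-12)
})

test_that("frozen latent dynamics give zero turnover", {
  sim <- tiny_dataset(n_cells = 10, seed = 17)
  data <- build_occu_data(sim$detections, sim$covariates, character(), character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 18, n_burnin = 50,
                                         n_sampling = 20, thin = 1))
  n <- data$n; T <- data$T
  fit$z[, (seq_len(n) - 1) * T + 2] <- fit$z[, (seq_len(n) - 1) * T + 1]
  tu <- turnover_summary(fit)
  row <- tu[tu$quantity == "turnover", ]
  expect_equal(row$mean, 0)
  expect_equal(c(row$lower, row$upper), c(0, 0))
})

test_that("single-season fits cannot report turnover", {
  d <- build_survey_design(12, n_years = 1, seed = 19)
  cov <- simulate_covariate_table(d, seed = 20)
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 0.5),
                             gamma = 0.3, epsilon = 0.3, seed = 21)
  det <- simulate_detections(truth, d, alpha = c(`(Intercept)` = 1), seed = 22)
  data <- build_occu_data(det, cov, character(), character())
  fit <- fit_occu_mcmc(data, fast_config(seed = 23, n_burnin = 50,
                                         n_sampling = 20, thin = 1))
  expect_error(turnover_summary(fit), "single-season")
})

test_that("parameter recovery: gamma and epsilon credible intervals cover the truth", {
  # scaled-down recovery check on the dynamics parameters (the full-factor
  # replicate study lives in the acceptance suite)
  covered <- c(gamma = 0L, epsilon = 0L)
  n_rep <- 6
  for (r in seq_len(n_rep)) {
    sim <- simulate_occu_dataset(
      n_cells = 150, seed = 900 + r,
      beta = c(`(Intercept)` = 0.4),
      alpha = c(`(Intercept)` = 1.2), gamma = 0.3, epsilon = 0.2)
    data <- build_occu_data(sim$detections, sim$covariates,
                            character(), character())
    fit <- fit_occu_mcmc(data, fast_config(seed = 300 + r, n_chains = 2,
                                           n_burnin = 300, n_sampling = 800))
    s <- summarize_posterior(fit)$parameters
    g <- s[s$parameter == "gamma", ]
    e <- s[s$parameter == "epsilon", ]
    covered["gamma"] <- covered["gamma"] + (g$lower <= 0.3 && 0.3 <= g$upper)
    covered["epsilon"] <- covered["epsilon"] + (e$lower <= 0.2 && 0.2 <= e$upper)
  }
  expect_gte(covered[["gamma"]], n_rep - 1)
  expect_gte(covered[["epsilon"]], n_rep - 1)
})
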