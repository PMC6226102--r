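test_that("frozen dynamics keep the latent state constant across years", {
  d <- build_survey_design(25, seed = 1)
  cov <- simulate_covariate_table(d, seed = 2)
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 0.4),
                             gamma = 0, epsilon = 0, seed = 3)
  expect_identical(truth$z[, 1], truth$z[, 2])
})

test_that("certain extinction with no colonization empties year 2", {
  d <- build_survey_design(25, seed = 1)
  cov <- simulate_covariate_table(d, seed = 2)
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 2),
                             gamma = 0, epsilon = 1, seed = 3)
  expect_true(all(truth$z[, 2] == 0))
})

test_that("intercept-only occupancy at logit 0 gives about half the cells occupied", {
  d <- build_survey_design(10000, n_years = 1, seed = 5)
  cov <- simulate_covariate_table(d, seed = 6)
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 0),
                             gamma = 0.5, epsilon = 0.5, seed = 7)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(truth$z[, 1]) - 0.5), 3 * se)
})

test_that("year-2 occupancy matches psi2 = psi1(1-eps) + (1-psi1)gamma", {
  d <- build_survey_design(8000, seed = 8)
  cov <- simulate_covariate_table(d, seed = 9)
  gamma <- 0.3; epsilon <- 0.2
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 0.5),
                             gamma = gamma, epsilon = epsilon, seed = 10)
  psi1 <- mean(truth$psi1)
  psi2 <- psi1 * (1 - epsilon) + (1 - psi1) * gamma
  se <- sqrt(psi2 * (1 - psi2) / 8000)
  expect_lt(abs(mean(truth$z[, 2]) - psi2), 4 * se)
})

test_that("unmatched occupancy coefficient names are reported", {
  d <- build_survey_design(10, seed = 1)
  cov <- simulate_covariate_table(d, seed = 2)
  expect_error(
    simulate_dynamics(d, cov, beta = c(`(Intercept)` = 0, Bogus = 1),
                      gamma = 0.1, epsilon = 0.1),
    "Bogus")
})

test_that("no detections ever occur where the latent state is 0", {
  sim <- tiny_dataset(n_cells = 60, seed = 13)
  z <- sim$truth$z[cbind(match(sim$detections$cell_id, sim$design$cells),
                         sim$detections$year)]
  expect_true(all(sim$detections$y[z == 0] == 0))
})

test_that("perfect detection of occupied cells detects on every occasion", {
  d <- build_survey_design(40, seed = 20)
  cov <- simulate_covariate_table(d, seed = 21)
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 10),
                             gamma = 0.5, epsilon = 0, seed = 22)
  det <- simulate_detections(truth, d, alpha = c(`(Intercept)` = 30), seed = 23)
  expect_true(all(truth$z == 1L))
  expect_true(all(det$y == 1L))
})

test_that("constant p = 0.5 over 4 occasions detects occupied cell-years at the binomial rate", {
  d <- build_survey_design(5000, n_years = 2, n_stationary = 4, n_mobile = 0,
                           seed = 30)
  cov <- simulate_covariate_table(d, seed = 31)
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 10),
                             gamma = 0.5, epsilon = 0, seed = 32)
  det <- simulate_detections(truth, d, alpha = c(`(Intercept)` = 0), seed = 33)
  hit <- tapply(det$y, list(det$cell_id, det$year), max)
  p_expect <- 1 - 0.5^4
  n_cy <- length(hit)
  se <- sqrt(p_expect * (1 - p_expect) / n_cy)
  expect_lt(abs(mean(hit) - p_expect), 3 * se)
})

test_that("detection simulation is reproducible and distinct seeds diverge", {
  sim1 <- tiny_dataset(seed = 99)
  sim2 <- tiny_dataset(seed = 99)
  sim3 <- tiny_dataset(seed = 100)
  expect_identical(sim1$detections, sim2$detections)
  expect_false(identical(sim1$truth$z, sim3$truth$z))
})

test_that("covariate generator reproduces the requested correlation structure", {
  d <- build_survey_design(400, seed = 40)
  cov <- simulate_covariate_table(d, seed = 41)
  r <- cor(cov$Dev, cov$Pri)
  expect_gt(r, 0.6)  # generated at 0.75 before range clipping
  expect_gt(cor(cov$F.Wet, cov$F.Wet.ED), 0.65)
  expect_true(all(cov$Ag >= 0 & cov$Ag <= 100))
  expect_true(all(cov$Stream >= 0))
})

test_that("occasion missingness drops records but never a whole cell-year", {
  d <- build_survey_design(50, seed = 50)
  cov <- simulate_covariate_table(d, seed = 51)
  truth <- simulate_dynamics(d, cov, beta = c(`(Intercept)` = 0),
                             gamma = 0.2, epsilon = 0.2, seed = 52)
  det <- simulate_detections(truth, d, alpha = c(`(Intercept)` = 0),
                             missingness = 0.3, seed = 53)
  expect_lt(nrow(det), nrow(d$occasions))
  expect_equal(nrow(unique(det[, c("cell_id", "year")])), 50 * 2)
})
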