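test_that("WAIC matches hand arithmetic on the two-draw single-cell case", {
  ll <- matrix(c(log(0.5), log(0.25)), ncol = 1)
  w <- waic(ll)
  expect_equal(w$lppd, log(0.375), tolerance = 1e-12)
  # printed 5-decimal reference values
  expect_equal(w$lppd, -0.98083, tolerance = 1e-4)
  expect_equal(w$p_waic, 0.24023, tolerance = 1e-4)
  expect_equal(w$waic, 2.44212, tolerance = 1e-4)
})

test_that("identical draws give zero penalty and WAIC = -2 log-likelihood", {
  ll <- matrix(log(0.5), nrow = 10, ncol = 1)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * log(0.5), tolerance = 1e-12)
})

test_that("vectorized WAIC equals the double-loop reference on random matrices", {
  set.seed(5)
  for (rep in 1:5) {
    ll <- matrix(log(runif(100 * 20, 0.01, 1)), 100, 20)
    got <- waic(ll)
    want <- double_loop_waic(ll)
    expect_equal(got$waic, want$waic, tolerance = 1e-10)
    expect_equal(got$lppd, want$lppd, tolerance = 1e-10)
    expect_equal(got$p_waic, want$p_waic, tolerance = 1e-10)
  }
})

test_that("WAIC is invariant to reordering draws or cells", {
  set.seed(6)
  ll <- matrix(rnorm(50 * 8, -2), 50, 8)
  base <- waic(ll)$waic
  expect_equal(waic(ll[sample(50), ])$waic, base, tolerance = 1e-12)
  expect_equal(waic(ll[, sample(8)])$waic, base, tolerance = 1e-12)
})

test_that("a single draw cannot support the variance penalty", {
  expect_error(waic(matrix(-1, 1, 3)), "at least 2 draws")
})

test_that("ranking arithmetic: WAICs {100, 102}", {
  cmp <- rank_models(c(a = 100, b = 102))
  expect_equal(cmp$delta_waic, c(0, 2))
  expect_equal(cmp$rel_likelihood, c(1, exp(-1)), tolerance = 1e-5)
  expect_equal(cmp$rel_likelihood[2], 0.36788, tolerance = 1e-5)
  expect_equal(cmp$weight, c(0.73106, 0.26894), tolerance = 1e-5)
  expect_true(all(cmp$competing))  # both within the <= 2.0 margin
})

test_that("ranking degenerate cases: ties and single model", {
  tie <- rank_models(c(m1 = 50, m2 = 50))
  expect_equal(tie$weight, c(0.5, 0.5))
  expect_equal(tie$model, c("m1", "m2"))  # ties keep input order
  one <- rank_models(c(only = 10))
  expect_equal(one$weight, 1)
  expect_equal(one$delta_waic, 0)
})

test_that("weights always sum to 1 and the top relative likelihood is exactly 1", {
  set.seed(8)
  for (rep in 1:20) {
    cmp <- rank_models(runif(sample(2:10, 1), 100, 300))
    expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
    expect_identical(cmp$rel_likelihood[1], 1)
    expect_equal(cmp$rank, seq_len(nrow(cmp)))
  }
})

test_that("pointwise log-likelihood matrix is consistent with the scalar marginal", {
  sim <- tiny_dataset(n_cells = 8, seed = 12)
  data <- build_occu_data(sim$detections, sim$covariates,
                          "Forest", "duration")
  fit <- fit_occu_mcmc(data, fast_config(seed = 13, n_burnin = 50,
                                         n_sampling = 20, thin = 1))
  ll_cached <- pointwise_loglik_matrix(fit)
  ll_re <- pointwise_loglik_matrix(fit, recompute = TRUE)
  expect_equal(ll_cached, ll_re, tolerance = 1e-12)
  # every entry equals the enumeration oracle at that draw's parameters
  P <- ncol(data$X); Q <- ncol(data$W)
  for (s in c(1, 7, 20)) {
    beta <- fit$draws[s, seq_len(P)]
    alpha <- fit$draws[s, P + seq_len(Q)]
    p <- plogis(as.vector(data$W %*% alpha))
    psi <- plogis(as.vector(data$X %*% beta))
    for (i in seq_len(data$n)) {
      sel <- data$cell == i
      want <- enumerate_marginal_loglik(
        data$y[sel], data$year_idx[sel], p[sel], unname(psi[i]),
        fit$draws[s, "gamma"], fit$draws[s, "epsilon"], data$T)
      expect_equal(unname(ll_cached[s, i]), unname(want), tolerance = 1e-10)
    }
  }
})

test_that("the generating model usually attains the lowest WAIC", {
  wins <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    sim <- simulate_occu_dataset(
      n_cells = 80, seed = 7000 + r,
      beta = c(`(Intercept)` = 0, Forest = 1.6),
      alpha = c(`(Intercept)` = 1), gamma = 0.2, epsilon = 0.15)
    cfg <- fast_config(seed = 100 + r, n_burnin = 300, n_sampling = 600)
    cands <- list(Forest = "Forest", Contagion = "Contagion",
                  null = character(0))
    waics <- vapply(cands, function(cv) {
      data <- build_occu_data(sim$detections, sim$covariates, cv, character())
      waic(fit_occu_mcmc(data, cfg))$waic
    }, numeric(1))
    wins <- wins + (names(which.min(waics)) == "Forest")
  }
  expect_gt(wins / n_rep, 0.5)
})
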