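# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Marginal likelihood by explicit enumeration over all latent paths
# (z_1, ..., z_T) in {0,1}^T, on the probability scale.
enumerate_marginal_loglik <- function(y, year_idx, p, psi, gamma, epsilon, T) {
  p <- rep_len(p, length(y))
  total <- 0
  for (code in 0:(2^T - 1)) {
    z <- as.integer(intToBits(code))[1:T]
    pr <- if (z[1] == 1) psi else 1 - psi
    if (T > 1) {
      for (t in 2:T) {
        pr <- pr * if (z[t - 1] == 1) {
          if (z[t] == 1) 1 - epsilon else epsilon
        } else {
          if (z[t] == 1) gamma else 1 - gamma
        }
      }
    }
    for (j in seq_along(y)) {
      pj <- z[year_idx[j]] * p[j]
      pr <- pr * if (y[j] == 1) pj else 1 - pj
    }
    total <- total + pr
  }
  log(total)
}

# Edge length (pixel units) by enumerating every pixel pair.
enumerate_edge_count <- function(grid, focal, nodata = -9999L) {
  nr <- nrow(grid); nc <- ncol(grid)
  edges <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (grid[i, j] == nodata) next
      for (d in list(c(1, 0), c(0, 1))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (i2 > nr || j2 > nc || grid[i2, j2] == nodata) next
        a <- grid[i, j] %in% focal
        b <- grid[i2, j2] %in% focal
        if (a != b) edges <- edges + 1L
      }
    }
  }
  edges
}

# Contagion by direct evaluation of the formula from pairwise-enumerated
# adjacency counts (double-count convention, boundary excluded).
enumerate_contagion <- function(grid, nodata = -9999L) {
  v <- grid[grid != nodata]
  classes <- sort(unique(v))
  m <- length(classes)
  if (m < 2) return(NA_real_)
  g <- matrix(0, m, m)
  nr <- nrow(grid); nc <- ncol(grid)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (grid[i, j] == nodata) next
      for (d in list(c(1, 0), c(0, 1))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (i2 > nr || j2 > nc || grid[i2, j2] == nodata) next
        a <- match(grid[i, j], classes); b <- match(grid[i2, j2], classes)
        g[a, b] <- g[a, b] + 1
        g[b, a] <- g[b, a] + 1
      }
    }
  }
  P <- as.vector(table(factor(v, levels = classes))) / length(v)
  s <- 0
  for (a in seq_len(m)) {
    rs <- sum(g[a, ])
    for (b in seq_len(m)) {
      q <- if (rs > 0) P[a] * g[a, b] / rs else 0
      if (q > 0) s <- s + q * log(q)
    }
  }
  (1 + s / (2 * log(m))) * 100
}

# WAIC by unvectorized double loops.
double_loop_waic <- function(ll) {
  S <- nrow(ll); N <- ncol(ll)
  lppd <- 0; p_waic <- 0
  for (i in seq_len(N)) {
    mean_lik <- 0
    for (s in seq_len(S)) mean_lik <- mean_lik + exp(ll[s, i]) / S
    lppd <- lppd + log(mean_lik)
    mbar <- 0
    for (s in seq_len(S)) mbar <- mbar + ll[s, i] / S
    v <- 0
    for (s in seq_len(S)) v <- v + (ll[s, i] - mbar)^2 / (S - 1)
    p_waic <- p_waic + v
  }
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

# AUC by all-pairs concordance counting with half-credit ties.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Small complete data set for fast model-level tests.
tiny_dataset <- function(n_cells = 30, seed = 42, gamma = 0.2, epsilon = 0.15,
                         beta = c(`(Intercept)` = 0.3, Forest = 1),
                         alpha = c(`(Intercept)` = 0.7)) {
  simulate_occu_dataset(n_cells = n_cells, seed = seed, beta = beta,
                        alpha = alpha, gamma = gamma, epsilon = epsilon)
}

fast_config <- function(seed = 1, n_chains = 2, n_burnin = 300,
                        n_sampling = 600, thin = 2) {
  mcmc_config(n_chains = n_chains, n_burnin = n_burnin,
              n_sampling = n_sampling, thin = thin, seed = seed)
}

# Effective sample size from initial positive autocorrelations, summed over
# chains; used to form Monte-Carlo standard errors in checks.
ess <- function(draws, chain) {
  sum(vapply(split(draws, chain), function(x) {
    n <- length(x)
    rho <- as.vector(stats::acf(x, lag.max = min(100, n - 2),
                                plot = FALSE)$acf)[-1]
    neg <- which(rho < 0)
    if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
    n / (1 + 2 * sum(rho))
  }, numeric(1)))
}
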