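#' MCMC schedule configuration
#'
#' Defaults follow the production schedule: 3 independent chains, 5,000
#' burn-in iterations, 25,000 post-burn-in sampling iterations per chain,
#' thinning by 4 — retaining 6,250 draws per chain, 18,750 in total.
#'
#' @param n_chains Number of independent chains.
#' @param n_burnin Burn-in iterations per chain (discarded; proposal scales
#'   adapt only here).
#' @param n_sampling Post-burn-in iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in iteration; must divide
#'   `n_sampling` evenly.
#' @param seed Integer seed; chain seeds derive from it.
#' @param prior_sd Prior standard deviation of the Normal(0, sd) priors on
#'   all logit-scale coefficients (default 10, a vague prior).
#' @param init_scale Initial random-walk proposal standard deviation.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 3, n_burnin = 5000, n_sampling = 25000,
                        thin = 4, seed = 1, prior_sd = 10, init_scale = 0.5) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_sampling >= 1, thin >= 1,
            prior_sd > 0, init_scale > 0)
  if (n_sampling %% thin != 0) {
    stop("thin (", thin, ") must divide n_sampling (", n_sampling, ") evenly")
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_sampling = as.integer(n_sampling),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 prior_sd = prior_sd,
                 init_scale = init_scale),
            class = "mcmc_config")
}

#' Retained posterior draws implied by a schedule
#'
#' @param config An `mcmc_config`.
#' @return Total retained draws across chains:
#'   `n_chains * n_sampling / thin`.
#' @export
retained_draws <- function(config) {
  config$n_chains * (config$n_sampling %/% config$thin)
}

#' Fit the multi-season occupancy model by MCMC
#'
#' Metropolis-within-Gibbs: latent occupancy states are updated by their
#' exact Bernoulli full conditionals (forced to occupied wherever the
#' cell-year has a detection), logit-scale occupancy and detection
#' coefficients by per-coordinate adaptive random-walk Metropolis under
#' Normal(0, `prior_sd`) priors, and the colonization/extinction constants
#' by conjugate Beta full-conditional draws under Uniform(0,1) priors.
#' Chains start from overdispersed initial values drawn per chain.
#'
#' @param data An `occu_data` from [build_occu_data()], or a list with
#'   `detections` and `covariates` plus `occ_covariates`/`det_covariates`
#'   passed through.
#' @param config An [mcmc_config()].
#' @param occ_covariates,det_covariates Model terms, used when `data` is a
#'   pair of raw tables.
#' @return An `occu_fit`: parameter draws (matrix draws x parameters with a
#'   chain index), latent-state draws, per-draw pointwise marginal
#'   log-likelihood by cell, acceptance rates, and the input data object.
#' @export
fit_occu_mcmc <- function(data, config = mcmc_config(),
                          occ_covariates = NULL, det_covariates = NULL) {
  if (!inherits(data, "occu_data")) {
    data <- build_occu_data(data$detections, data$covariates,
                            occ_covariates %||% character(),
                            det_covariates %||% character())
  }
  P <- ncol(data$X); Q <- ncol(data$W)
  S_chain <- config$n_sampling %/% config$thin
  chain_seeds <- withr_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L,
                                       config$n_chains))
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chains[[ch]] <- withr_seed(chain_seeds[ch], {
      beta0 <- stats::rnorm(P, 0, 1)
      alpha0 <- stats::rnorm(Q, 0, 1)
      gamma0 <- stats::runif(1, 0.2, 0.8)
      eps0 <- stats::runif(1, 0.2, 0.8)
      occu_chain_cpp(data$y, data$cell - 1L, data$year_idx - 1L,
                     data$W, data$X, data$n, data$T,
                     config$n_sampling, config$n_burnin, config$thin,
                     config$prior_sd, beta0, alpha0, gamma0, eps0,
                     config$init_scale)
    })
  }
  par_names <- c(paste0("beta:", colnames(data$X)),
                 paste0("alpha:", colnames(data$W)),
                 "gamma", "epsilon")
  draws <- do.call(rbind, lapply(chains, function(cc) {
    cbind(cc$beta, cc$alpha, cc$gamma, cc$epsilon)
  }))
  colnames(draws) <- par_names
  z_draws <- do.call(rbind, lapply(chains, `[[`, "z"))
  loglik <- do.call(rbind, lapply(chains, `[[`, "loglik"))
  colnames(loglik) <- data$cells
  structure(list(
    draws = draws,
    chain = rep(seq_len(config$n_chains), each = S_chain),
    z = z_draws,
    loglik = loglik,
    accept = list(
      beta = rowMeans(vapply(chains, `[[`, numeric(P), "accept_beta")
                      |> matrix(nrow = P)),
      alpha = rowMeans(vapply(chains, `[[`, numeric(Q), "accept_alpha")
                       |> matrix(nrow = Q))),
    data = data,
    config = config,
    n_retained = config$n_chains * S_chain
  ), class = "occu_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occu_fit <- function(x, ...) {
  cat("Multi-season occupancy fit:", x$data$n, "cells,", x$data$T,
      "season(s),", x$n_retained, "retained draws in",
      x$config$n_chains, "chains\n")
  cat("Occupancy terms:",
      paste(x$data$occ_covariates %||% "(intercept only)", collapse = " + "),
      "\n")
  invisible(x)
}

#' Posterior draws of a single parameter split by chain
#'
#' @param fit An `occu_fit`.
#' @param parameter Parameter name (a column of `fit$draws`).
#' @return List of per-chain numeric vectors of retained draws.
#' @export
chain_draws <- function(fit, parameter) {
  if (!parameter %in% colnames(fit$draws)) {
    stop("unknown parameter: ", parameter)
  }
  split(fit$draws[, parameter], fit$chain)
}
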