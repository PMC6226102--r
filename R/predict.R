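#' Second-season occupancy from dynamics
#'
#' The one-step occupancy recursion of the dynamic model:
#' psi2 = psi1 (1 - epsilon) + (1 - psi1) gamma — a convex combination, so
#' the result is always a probability.
#'
#' @param psi1 Initial-season occupancy probability (vectorized).
#' @param gamma,epsilon Colonization and extinction probabilities.
#' @return psi2, same shape as `psi1`.
#' @export
derived_second_year_psi <- function(psi1, gamma, epsilon) {
  if (any(psi1 < 0 | psi1 > 1, na.rm = FALSE) ||
      any(gamma < 0 | gamma > 1) || any(epsilon < 0 | epsilon > 1)) {
    stop("psi1, gamma and epsilon must all lie in [0,1]")
  }
  psi1 * (1 - epsilon) + (1 - psi1) * gamma
}

#' Predicted occupancy over a cell grid
#'
#' Evaluates the fitted model over any covariate table (for example the full
#' statewide grid of cells): per draw and cell, initial-season occupancy is
#' the inverse-logit of the linear predictor and later seasons follow the
#' colonization/extinction recursion. Grid covariates are standardized with
#' the fitting set's stored location/scale, never their own.
#'
#' @param fit An `occu_fit`.
#' @param grid_covariates Covariate table covering every term of the fitted
#'   model (missing columns raise an error naming them).
#' @return A `prediction_grid` data.frame: cell_id, year, psi_mean, psi_lo,
#'   psi_hi (posterior mean and 95% CrI over draws).
#' @export
predict_occupancy_grid <- function(fit, grid_covariates) {
  stopifnot(inherits(fit, "occu_fit"))
  data <- fit$data
  des <- build_occupancy_design(grid_covariates, data$occ_covariates,
                                standardization = data$occ_standardization,
                                region_levels = data$region_levels)
  if (!identical(colnames(des$X), colnames(data$X))) {
    stop("grid design columns (", paste(colnames(des$X), collapse = ", "),
         ") do not match the fitted design (",
         paste(colnames(data$X), collapse = ", "), ")")
  }
  P <- ncol(data$X)
  beta <- fit$draws[, seq_len(P), drop = FALSE]
  gam <- fit$draws[, "gamma"]
  eps <- fit$draws[, "epsilon"]
  psi <- stats::plogis(des$X %*% t(beta))  # cells x draws
  out <- list()
  for (t in seq_len(data$T)) {
    if (t > 1) {
      psi <- sweep(psi, 2, 1 - eps, `*`) + sweep(1 - psi, 2, gam, `*`)
    }
    out[[t]] <- data.frame(
      cell_id = grid_covariates$cell_id,
      year = data$years[t],
      psi_mean = rowMeans(psi),
      psi_lo = apply(psi, 1, stats::quantile, 0.025, names = FALSE),
      psi_hi = apply(psi, 1, stats::quantile, 0.975, names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("prediction_grid", "data.frame")
  res
}

#' Posterior turnover, colonization and extinction summaries
#'
#' Colonization gamma and extinction epsilon are model parameters; turnover
#' tau is derived per draw as the fraction of cells whose sampled latent
#' state changed between consecutive seasons. Each is summarized by its
#' posterior mean and 95% credible interval.
#'
#' @param fit An `occu_fit` on at least two seasons.
#' @return A `turnover_estimate` data.frame: quantity (gamma, epsilon,
#'   turnover), mean, lower, upper.
#' @export
turnover_summary <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  data <- fit$data
  if (data$T < 2) stop("turnover undefined for single-season data")
  n <- data$n; T <- data$T
  # z columns are cell-major: cell i, season t at (i-1)*T + t
  idx <- function(t) (seq_len(n) - 1) * T + t
  changed <- matrix(0, nrow(fit$z), T - 1)
  for (t in seq_len(T - 1)) {
    changed[, t] <- rowMeans(abs(fit$z[, idx(t + 1), drop = FALSE] -
                                   fit$z[, idx(t), drop = FALSE]))
  }
  tau <- rowMeans(changed)  # per-draw fraction of cells changing state
  summ <- function(x) c(mean = mean(x),
                        lower = stats::quantile(x, 0.025, names = FALSE),
                        upper = stats::quantile(x, 0.975, names = FALSE))
  out <- rbind(gamma = summ(fit$draws[, "gamma"]),
               epsilon = summ(fit$draws[, "epsilon"]),
               turnover = summ(tau))
  res <- data.frame(quantity = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("turnover_estimate", "data.frame")
  res
}
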