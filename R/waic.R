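#' Pointwise marginal log-likelihood matrix
#'
#' One row per retained posterior draw, one column per cell (the independent
#' sampling unit; both seasons of a cell pool into one pointwise term).
#' Latent occupancy states are marginalized analytically at each draw, never
#' conditioned on the sampled states.
#'
#' @param fit An `occu_fit`.
#' @param recompute Recompute from the stored draws (default uses the matrix
#'   cached at sampling time; recomputation is the cross-check path).
#' @return draws x cells matrix of log-likelihoods.
#' @export
pointwise_loglik_matrix <- function(fit, recompute = FALSE) {
  stopifnot(inherits(fit, "occu_fit"))
  if (!recompute) return(fit$loglik)
  data <- fit$data
  P <- ncol(data$X); Q <- ncol(data$W)
  out <- pointwise_loglik_cpp(
    fit$draws[, seq_len(P), drop = FALSE],
    fit$draws[, P + seq_len(Q), drop = FALSE],
    fit$draws[, "gamma"], fit$draws[, "epsilon"],
    data$X, data$W, data$y, data$cell - 1L, data$year_idx - 1L,
    data$n, data$T)
  colnames(out) <- data$cells
  out
}

#' Widely Applicable Information Criterion
#'
#' From a draws x units pointwise log-likelihood matrix:
#' lppd = sum over units of log mean exp(loglik) (computed stably),
#' p_waic = sum over units of the sample variance (n-1 denominator) of
#' loglik across draws, and WAIC = -2 (lppd - p_waic).
#'
#' @param loglik draws x units matrix, or an `occu_fit` (its cached matrix
#'   is used).
#' @return List with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(loglik) {
  if (inherits(loglik, "occu_fit")) loglik <- pointwise_loglik_matrix(loglik)
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) stop("need at least 2 draws to compute p_waic")
  if (!all(is.finite(loglik))) stop("non-finite pointwise log-likelihoods")
  # log mean exp per column, stable against large negative log-likelihoods
  mx <- apply(loglik, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(loglik, 2, mx))))
  p_i <- apply(loglik, 2, stats::var)
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Rank candidate models by WAIC
#'
#' Computes Delta WAIC from the top model, relative likelihoods
#' exp(-Delta/2), normalized model weights, and the competing-model flag
#' (Delta <= margin). Ties keep input order.
#'
#' @param waics Named (or unnamed) numeric vector of per-model WAIC values.
#' @param competing_margin Delta-WAIC margin for "closely competing" models
#'   (default 2.0).
#' @return A `model_comparison` data.frame: model, waic, delta_waic,
#'   rel_likelihood, weight, competing, rank — ordered by ascending WAIC.
#' @export
rank_models <- function(waics, competing_margin = 2.0) {
  stopifnot(length(waics) >= 1, all(is.finite(waics)))
  nm <- names(waics) %||% paste0("model", seq_along(waics))
  delta <- waics - min(waics)
  rel <- exp(-delta / 2)
  wt <- rel / sum(rel)
  out <- data.frame(model = nm, waic = as.numeric(waics),
                    delta_waic = as.numeric(delta),
                    rel_likelihood = as.numeric(rel),
                    weight = as.numeric(wt),
                    competing = as.numeric(delta) <= competing_margin,
                    stringsAsFactors = FALSE)
  ord <- order(out$delta_waic)  # stable: ties keep input order
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}
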