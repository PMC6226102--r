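#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Compares between- and within-chain variance of retained draws:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \cdot W + B/n}{W}}}
#' where W is the mean within-chain variance and B/n the variance of the
#' chain means. Convergence is conventionally declared when every monitored
#' parameter has R-hat < 1.1.
#'
#' @param chains List of per-chain numeric vectors (same length each), or a
#'   matrix with one column per chain.
#' @return R-hat (scalar), or `NA` with a "degenerate" attribute when all
#'   chains have zero within-chain variance.
#' @export
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains")
  len <- lengths(chains)
  if (any(len < 2)) stop("each chain needs at least 2 draws")
  if (length(unique(len)) != 1) stop("chains must have equal length")
  n <- len[1]
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  if (W == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  B_over_n <- stats::var(means)  # = B/n in the classic notation
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Summarize a posterior fit
#'
#' Pooled posterior means, 95% credible intervals (2.5% / 97.5% empirical
#' quantiles across chains), per-parameter R-hat, and the significance flag:
#' an effect is called significant when its 95% CrI excludes zero. Also
#' derives the per-season mean occupancy probability (posterior distribution
#' of the cell-average of psi) with its CrI.
#'
#' @param fit An `occu_fit`.
#' @param rhat_threshold Convergence threshold (default 1.1).
#' @return A `fit_summary`: list with `parameters` (data.frame parameter,
#'   mean, lower, upper, rhat, significant), `mean_occupancy` (data.frame
#'   year, mean, lower, upper), `converged`, `nonconverged_parameters`.
#' @export
summarize_posterior <- function(fit, rhat_threshold = 1.1) {
  stopifnot(inherits(fit, "occu_fit"))
  draws <- fit$draws
  if (nrow(draws) == 0) stop("fit contains no retained draws")
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  rh <- vapply(colnames(draws), function(p) {
    r <- rhat(chain_draws(fit, p))
    as.numeric(r)
  }, numeric(1))
  params <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    lower = qs[1, ],
    upper = qs[2, ],
    rhat = rh,
    significant = qs[1, ] > 0 | qs[2, ] < 0,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  psi <- posterior_psi(fit)  # draws x years matrix of cell-average psi
  mean_occ <- data.frame(
    year = fit$data$years,
    mean = colMeans(psi),
    lower = apply(psi, 2, stats::quantile, 0.025, names = FALSE),
    upper = apply(psi, 2, stats::quantile, 0.975, names = FALSE)
  )
  bad <- params$parameter[!is.na(params$rhat) & params$rhat >= rhat_threshold]
  structure(list(parameters = params,
                 mean_occupancy = mean_occ,
                 converged = length(bad) == 0,
                 nonconverged_parameters = bad),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, digits = 3, ...) {
  df <- x$parameters
  df[, c("mean", "lower", "upper", "rhat")] <-
    round(df[, c("mean", "lower", "upper", "rhat")], digits)
  print(df, row.names = FALSE)
  cat("\nMean occupancy by season:\n")
  print(within(x$mean_occupancy, {
    mean <- round(mean, digits); lower <- round(lower, digits)
    upper <- round(upper, digits)
  }), row.names = FALSE)
  if (!x$converged) {
    cat("\nWARNING: R-hat >= 1.1 for:",
        paste(x$nonconverged_parameters, collapse = ", "), "\n")
  }
  invisible(x)
}

# Per-draw cell-average occupancy probability for each season:
# psi_1 = plogis(X beta); psi_{t+1} = psi_t (1 - epsilon) + (1 - psi_t) gamma.
# Returns draws x seasons matrix.
posterior_psi <- function(fit) {
  data <- fit$data
  P <- ncol(data$X)
  beta <- fit$draws[, seq_len(P), drop = FALSE]
  gam <- fit$draws[, "gamma"]
  eps <- fit$draws[, "epsilon"]
  psi_cells <- stats::plogis(data$X %*% t(beta))  # n x S
  out <- matrix(NA_real_, nrow(fit$draws), data$T)
  out[, 1] <- colMeans(psi_cells)
  if (data$T > 1) {
    cur <- psi_cells
    for (t in 2:data$T) {
      cur <- sweep(cur, 2, 1 - eps, `*`) + sweep(1 - cur, 2, gam, `*`)
      out[, t] <- colMeans(cur)
    }
  }
  out
}
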