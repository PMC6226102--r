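#' Region-constrained random train/test partitions
#'
#' Draws `n_partitions` independent random splits of the cells into training
#' and testing sets, constrained so every training set contains at least one
#' cell from each region. The training size is round-half-up of
#' `train_fraction * n` (25 of 38 cells at the default 66%). The same
#' partitions are reused for every species and model within a run.
#'
#' @param cells Character vector of cell ids.
#' @param regions Region label per cell.
#' @param n_partitions Number of random partitions (default 5).
#' @param train_fraction Fraction of cells used for training (default 0.66).
#' @param seed Integer seed.
#' @return A `fold_partition`: list of `folds` (each with `train`, `test`
#'   cell-id vectors) plus the seed.
#' @export
partition_folds <- function(cells, regions, n_partitions = 5,
                            train_fraction = 0.66, seed = 1) {
  stopifnot(length(cells) == length(regions), n_partitions >= 1,
            train_fraction > 0, train_fraction < 1)
  if (length(cells) == 0) stop("infeasible constraint: no cells to partition")
  regions <- as.character(regions)
  tab <- table(regions)
  if (any(tab == 0)) stop("infeasible constraint: empty region")
  n <- length(cells)
  n_train <- floor(train_fraction * n + 0.5)  # round half up
  if (n_train < length(unique(regions))) {
    stop("infeasible constraint: training size ", n_train,
         " cannot cover ", length(unique(regions)), " regions")
  }
  withr_seed(seed, {
    folds <- vector("list", n_partitions)
    for (k in seq_len(n_partitions)) {
      repeat {
        tr <- sample(n, n_train)
        if (all(unique(regions) %in% regions[tr])) break
      }
      folds[[k]] <- list(train = cells[sort(tr)], test = cells[sort(setdiff(seq_len(n), tr))])
    }
    structure(list(folds = folds, seed = seed,
                   n_train = n_train, n_test = n - n_train),
              class = "fold_partition")
  })
}

#' Rank-based AUC (Mann-Whitney with tie half-credit)
#'
#' Area under the receiver-operating curve computed from the rank statistic:
#' the probability that a random positive scores above a random negative,
#' ties counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) observed labels; both classes must occur.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: labels contain a single class")
  }
  r <- rank(scores)  # midranks give tie half-credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' k-fold cross-validated AUC for one model
#'
#' For each partition: refits the model on the training cells only
#' (re-standardizing covariates on the training set and carrying that
#' location/scale to the test cells), scores each testing cell-year by its
#' posterior-mean occupancy probability, and labels it by whether at least
#' one detection occurred there (naive occupancy — the only observable
#' label). Reports per-fold AUC and the mean over folds; a fold whose test
#' labels are single-class is recorded as NA and excluded from the mean
#' with a warning.
#'
#' @param detections,covariates Full data tables.
#' @param occ_covariates,det_covariates Model terms.
#' @param partition A [partition_folds()] result.
#' @param config An [mcmc_config()]; cross-validation typically uses a
#'   reduced schedule.
#' @param pool_years Pool both seasons into one label/score set (default);
#'   otherwise AUC is also reported per season.
#' @return A `crossval_result`: per-fold AUC, `mean_auc`, and per-year AUCs.
#' @export
kfold_auc <- function(detections, covariates, occ_covariates, det_covariates,
                      partition, config = mcmc_config(), pool_years = TRUE) {
  stopifnot(inherits(partition, "fold_partition"))
  fold_auc <- rep(NA_real_, length(partition$folds))
  fold_seeds <- withr_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L,
                                      length(partition$folds)))
  year_auc <- list()
  for (k in seq_along(partition$folds)) {
    fold <- partition$folds[[k]]
    tr_cov <- covariates[covariates$cell_id %in% fold$train, , drop = FALSE]
    tr_det <- detections[detections$cell_id %in% fold$train, , drop = FALSE]
    te_cov <- covariates[covariates$cell_id %in% fold$test, , drop = FALSE]
    te_det <- detections[detections$cell_id %in% fold$test, , drop = FALSE]
    tr_data <- build_occu_data(tr_det, tr_cov, occ_covariates, det_covariates)
    cfg <- config
    cfg$seed <- fold_seeds[k]  # distinct chains per fold, reproducible
    fit <- fit_occu_mcmc(tr_data, cfg)
    grid <- predict_occupancy_grid(fit, te_cov)
    obs <- stats::aggregate(y ~ cell_id + year, data = te_det, FUN = max)
    merged <- merge(grid, obs, by = c("cell_id", "year"))
    if (pool_years) {
      if (length(unique(merged$y)) < 2) {
        warning("fold ", k, ": single-class test labels; AUC undefined")
      } else {
        fold_auc[k] <- auc(merged$psi_mean, merged$y)
      }
    }
    year_auc[[k]] <- vapply(split(merged, merged$year), function(d) {
      if (length(unique(d$y)) < 2) NA_real_ else auc(d$psi_mean, d$y)
    }, numeric(1))
  }
  structure(list(fold_auc = fold_auc,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 year_auc = do.call(rbind, year_auc)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat("Cross-validated AUC:", round(x$mean_auc, 3),
      "( folds:", paste(round(x$fold_auc, 3), collapse = " "), ")\n")
  invisible(x)
}
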