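#' Build the occupancy design matrix
#'
#' Intercept, optional Region dummies (coded against the first factor level,
#' alphabetically Blue Ridge by default), and standardized continuous
#' covariates. The standardization location/scale is computed from the table
#' unless a stored one is supplied (as when scoring held-out or statewide
#' cells with the fitting set's parameters).
#'
#' @param covariates Cell covariate table (one row per cell).
#' @param occ_covariates Character vector of covariate names, possibly
#'   including "Region"; empty for an intercept-only model.
#' @param standardization Optional stored standardization to reuse.
#' @param region_levels Region level set fixing the dummy coding; defaults
#'   to the table's factor levels (or sorted unique values). Pass the
#'   fitting set's levels when building a prediction design so dummies line
#'   up even if the new table lacks some regions.
#' @return List with `X` (matrix, rownames = cell ids), `standardization`,
#'   `region_levels`.
#' @export
build_occupancy_design <- function(covariates, occ_covariates = character(),
                                   standardization = NULL,
                                   region_levels = NULL) {
  cont <- setdiff(occ_covariates, "Region")
  missing_cols <- setdiff(cont, names(covariates))
  if (length(missing_cols)) {
    stop("covariate column(s) missing from the table: ",
         paste(missing_cols, collapse = ", "))
  }
  X <- matrix(1, nrow(covariates), 1, dimnames = list(covariates$cell_id, "(Intercept)"))
  if ("Region" %in% occ_covariates) {
    if (is.null(region_levels)) {
      region_levels <- if (is.factor(covariates$region)) {
        levels(covariates$region)
      } else {
        sort(unique(as.character(covariates$region)))
      }
    }
    reg <- factor(covariates$region, levels = region_levels)
    if (anyNA(reg)) {
      stop("region value(s) outside the fitted level set: ",
           paste(unique(covariates$region[is.na(reg)]), collapse = ", "))
    }
    if (nlevels(reg) > 1) {
      dummies <- stats::model.matrix(~reg)[, -1, drop = FALSE]
      colnames(dummies) <- paste0("Region", levels(reg)[-1])
      X <- cbind(X, dummies)
    }
  }
  if (length(cont)) {
    if (is.null(standardization)) {
      std <- standardize_covariates(covariates, columns = cont)
    } else {
      std <- standardize_covariates(covariates, standardization = standardization)
    }
    X <- cbind(X, as.matrix(std$table[, cont, drop = FALSE]))
    standardization <- list(center = std$center[cont], scale = std$scale[cont])
  } else {
    standardization <- list(center = numeric(0), scale = numeric(0))
  }
  list(X = X, standardization = standardization,
       region_levels = region_levels)
}

DET_CONTINUOUS <- c("duration", "date", "temperature", "humidity", "wind")

#' Build the detection (survey-level) design matrix
#'
#' Expands the nine survey covariates: `type` becomes a mobile-survey dummy,
#' `clutter` two dummies against the no-clutter level, `issue` and `rain`
#' enter as 0/1, and the continuous covariates (duration, date, temperature,
#' humidity, wind) are standardized with stored or freshly computed
#' location/scale.
#'
#' @param detections Detection table (one row per survey occasion).
#' @param det_covariates Survey covariate names from [SURVEY_COVARIATES];
#'   empty for an intercept-only detection model.
#' @param standardization Optional stored standardization to reuse.
#' @return List with `W` (matrix), `standardization`.
#' @export
build_detection_design <- function(detections, det_covariates = character(),
                                   standardization = NULL) {
  unknown <- setdiff(det_covariates, SURVEY_COVARIATES)
  if (length(unknown)) {
    stop("unknown survey covariate(s): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(detections)
  W <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  raw_cols <- intersect(c(det_covariates, "method"[("type" %in% det_covariates)]),
                        names(detections))
  na_cols <- raw_cols[vapply(detections[raw_cols], anyNA, logical(1))]
  if (length(na_cols)) {
    stop("detection records with missing covariate values in: ",
         paste(na_cols, collapse = ", "))
  }
  cont <- intersect(det_covariates, DET_CONTINUOUS)
  if (length(cont)) {
    if (is.null(standardization)) {
      std <- standardize_covariates(detections, columns = cont)
    } else {
      std <- standardize_covariates(detections, standardization = standardization)
    }
    cont_mat <- as.matrix(std$table[, cont, drop = FALSE])
    standardization <- list(center = std$center[cont], scale = std$scale[cont])
  } else {
    cont_mat <- NULL
    standardization <- list(center = numeric(0), scale = numeric(0))
  }
  if ("type" %in% det_covariates) {
    W <- cbind(W, type_mobile = as.numeric(detections$method == "mobile"))
  }
  if ("clutter" %in% det_covariates) {
    W <- cbind(W,
               clutter_medium = as.numeric(detections$clutter == "medium"),
               clutter_high = as.numeric(detections$clutter == "high"))
  }
  if (!is.null(cont_mat)) W <- cbind(W, cont_mat)
  for (bin in intersect(det_covariates, c("issue", "rain"))) {
    W <- cbind(W, as.numeric(detections[[bin]]))
    colnames(W)[ncol(W)] <- bin
  }
  if (anyNA(W)) {
    bad <- which(apply(W, 1, anyNA))
    stop("detection records with missing covariate values at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  list(W = W, standardization = standardization)
}

#' Assemble model-ready data from detection and covariate tables
#'
#' Orders detection records by cell and year, builds both design matrices,
#' and indexes occasions into cell-years for the closed-form likelihood and
#' the sampler.
#'
#' @param detections Detection table.
#' @param covariates Cell covariate table; its row order fixes the cell
#'   indexing.
#' @param occ_covariates,det_covariates Model terms (see
#'   [build_occupancy_design()], [build_detection_design()]).
#' @param occ_standardization,det_standardization Stored standardizations to
#'   reuse (training-set parameters when scoring held-out cells).
#' @return An `occu_data` list: `X`, `W`, `y`, `cell` (1-based cell index
#'   per record), `year_idx` (1-based season index), `n`, `T`, `cells`,
#'   `years`, standardizations.
#' @export
build_occu_data <- function(detections, covariates,
                            occ_covariates = character(),
                            det_covariates = character(),
                            occ_standardization = NULL,
                            det_standardization = NULL) {
  cells <- covariates$cell_id
  if (anyDuplicated(cells)) stop("covariate table has duplicated cell ids")
  unknown <- setdiff(unique(detections$cell_id), cells)
  if (length(unknown)) {
    stop("detection records for cells absent from the covariate table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  years <- sort(unique(detections$year))
  ord <- order(match(detections$cell_id, cells), detections$year,
               detections$occasion)
  det <- detections[ord, , drop = FALSE]
  occ_des <- build_occupancy_design(covariates, occ_covariates,
                                    occ_standardization)
  det_des <- build_detection_design(det, det_covariates, det_standardization)
  structure(list(
    X = occ_des$X,
    W = det_des$W,
    y = as.integer(det$y),
    cell = match(det$cell_id, cells),
    year_idx = match(det$year, years),
    n = length(cells),
    T = length(years),
    cells = cells,
    years = years,
    occ_covariates = occ_covariates,
    det_covariates = det_covariates,
    occ_standardization = occ_des$standardization,
    det_standardization = det_des$standardization,
    region_levels = occ_des$region_levels
  ), class = "occu_data")
}

#' Closed-form marginal log-likelihood of one cell's detection history
#'
#' Sums the complete-data likelihood over every latent occupancy path
#' (z_1, ..., z_T) by a forward recursion: populations are closed within
#' years and evolve between years by colonization gamma and extinction
#' epsilon. Exact; no latent-state sampling.
#'
#' @param y 0/1 detections over the cell's survey occasions.
#' @param year_idx 1-based season index of each occasion (same length as
#'   `y`); seasons with no occasions contribute only dynamics terms.
#' @param p Detection probability per occasion given presence.
#' @param psi Initial-season occupancy probability of the cell.
#' @param gamma,epsilon Colonization and extinction probabilities.
#' @param n_years Number of seasons T (default `max(year_idx)`).
#' @return Log marginal likelihood (scalar).
#' @export
marginal_cell_loglik <- function(y, year_idx, p, psi, gamma = 0, epsilon = 0,
                                 n_years = max(year_idx, 1)) {
  stopifnot(length(y) == length(year_idx), length(p) %in% c(1L, length(y)),
            psi >= 0, psi <= 1, gamma >= 0, gamma <= 1,
            epsilon >= 0, epsilon <= 1)
  if (!all(is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("detection probabilities must be finite and in [0,1]")
  }
  p <- rep_len(p, length(y))
  # per-season detection log-likelihood given presence, and any-detection flag
  ll1 <- numeric(n_years)
  anydet <- logical(n_years)
  for (t in seq_len(n_years)) {
    sel <- year_idx == t
    ll1[t] <- sum(ifelse(y[sel] == 1, log(p[sel]), log1p(-p[sel])))
    anydet[t] <- any(y[sel] == 1)
  }
  f1 <- log(psi) + ll1[1]
  f0 <- log1p(-psi) + if (anydet[1]) -Inf else 0
  if (n_years > 1) {
    for (t in 2:n_years) {
      g1 <- logsumexp2(f1 + log1p(-epsilon), f0 + log(gamma)) + ll1[t]
      g0 <- logsumexp2(f1 + log(epsilon), f0 + log1p(-gamma)) +
        if (anydet[t]) -Inf else 0
      f1 <- g1
      f0 <- g0
    }
  }
  logsumexp2(f1, f0)
}

logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}
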