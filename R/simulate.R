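#' Default correlation structure for synthetic landscape covariates
#'
#' Correlation matrix over the twelve continuous landscape covariates,
#' encoding the dependence structure the correlation screen must handle:
#' development strongly correlated with primary/secondary/tertiary road
#' length, secondary with tertiary roads, and forested-wetland cover with
#' forested-wetland edge density; agriculture trades off against forest.
#'
#' @return A 12x12 positive-definite correlation matrix with dimnames.
#' @export
default_covariate_correlation <- function() {
  vars <- COVARIATE_COLUMNS
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("Dev", "Pri", 0.75)
  set_r("Dev", "Sec", 0.75)
  set_r("Dev", "Ter", 0.75)
  set_r("Sec", "Ter", 0.75)
  set_r("Pri", "Sec", 0.6)
  set_r("Pri", "Ter", 0.6)
  set_r("F.Wet", "F.Wet.ED", 0.8)
  set_r("Ag", "Forest", -0.45)
  set_r("Forest", "F.ED", 0.3)
  set_r("Forest", "Contagion", 0.25)
  R
}

#' Continuous landscape covariate columns
#' @export
COVARIATE_COLUMNS <- c("Ag", "Dev", "Forest", "F.Wet", "Contagion",
                       "F.ED", "F.Wet.ED", "Stream", "Pri", "Sec",
                       "Ter", "Qua")

# marginal location/scale used to map correlated standard normals onto
# plausible covariate ranges (percents, index, m/ha, km)
covariate_margins <- function() {
  data.frame(
    var = COVARIATE_COLUMNS,
    mean = c(20, 12, 40, 15, 55, 60, 30, 120, 8, 35, 80, 25),
    sd = c(10, 7, 15, 8, 12, 18, 12, 35, 5, 12, 22, 10),
    lo = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    hi = c(100, 100, 100, 100, 100, Inf, Inf, Inf, Inf, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

#' Simulate a per-cell landscape covariate table
#'
#' Draws correlated Gaussian covariates for every cell of a survey design
#' and maps them onto realistic ranges (percent cover clipped to \[0,100\],
#' lengths and edge densities to non-negative values). The correlation
#' matrix is configurable so the Pearson screen can be exercised under any
#' dependence structure.
#'
#' @param design A `survey_design`.
#' @param correlation Covariate correlation matrix (default
#'   [default_covariate_correlation()]). Row/column names must match
#'   [COVARIATE_COLUMNS] (any subset allowed; missing columns are drawn
#'   independently).
#' @param seed Integer seed.
#' @return A data.frame with cell_id, region and the columns of
#'   [COVARIATE_COLUMNS].
#' @export
simulate_covariate_table <- function(design,
                                     correlation = default_covariate_correlation(),
                                     seed = 1) {
  stopifnot(inherits(design, "survey_design"))
  vars <- COVARIATE_COLUMNS
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  shared <- intersect(rownames(correlation), vars)
  R[shared, shared] <- correlation[shared, shared]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) stop("correlation matrix is not positive definite")
  n <- length(design$cells)
  withr_seed(seed, {
    z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = R)
    m <- covariate_margins()
    out <- data.frame(cell_id = design$cells,
                      region = design$regions,
                      stringsAsFactors = FALSE)
    for (j in seq_along(vars)) {
      x <- m$mean[j] + m$sd[j] * z[, j]
      out[[vars[j]]] <- pmin(pmax(x, m$lo[j]), m$hi[j])
    }
    out
  })
}

#' Simulate latent occupancy dynamics
#'
#' Draws the latent occupancy state of every cell in every year. First-year
#' occupancy follows a logistic regression on the (standardized) landscape
#' covariates; later years evolve by constant colonization and extinction:
#' an occupied cell stays occupied with probability 1 - epsilon, an empty
#' cell becomes occupied with probability gamma.
#'
#' @param design A `survey_design`.
#' @param covariates Cell covariate table (one row per cell).
#' @param beta Named numeric vector of occupancy coefficients on the logit
#'   scale. Names must be `(Intercept)`, optional `Region<level>` dummies,
#'   and continuous covariate names; covariates are standardized before the
#'   linear predictor is formed, so slopes are per-SD effects.
#' @param gamma,epsilon Colonization and extinction probabilities in \[0,1\].
#' @param seed Integer seed.
#' @return A `simulation_truth`: list with `z` (cells x years 0/1 matrix),
#'   `psi1` (per-cell initial occupancy probability), `beta`, `gamma`,
#'   `epsilon`, and the standardization used.
#' @export
simulate_dynamics <- function(design, covariates, beta, gamma, epsilon, seed = 1) {
  stopifnot(inherits(design, "survey_design"))
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0,1]")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0,1]")
  occ_cov <- infer_covariates_from_coefs(names(beta), covariates)
  des <- build_occupancy_design(covariates, occ_cov)
  missing_terms <- setdiff(names(beta), colnames(des$X))
  if (length(missing_terms)) {
    stop("coefficients with no matching design column: ",
         paste(missing_terms, collapse = ", "))
  }
  b <- structure(numeric(ncol(des$X)), names = colnames(des$X))
  b[names(beta)] <- beta
  eta <- as.vector(des$X %*% b)
  psi1 <- stats::plogis(eta)
  n <- length(design$cells)
  T <- length(design$years)
  withr_seed(seed, {
    z <- matrix(0L, n, T, dimnames = list(design$cells, NULL))
    z[, 1] <- stats::rbinom(n, 1, psi1)
    if (T > 1) {
      for (t in 2:T) {
        pr <- z[, t - 1] * (1 - epsilon) + (1 - z[, t - 1]) * gamma
        z[, t] <- stats::rbinom(n, 1, pr)
      }
    }
    structure(list(z = z, psi1 = psi1, beta = b, gamma = gamma,
                   epsilon = epsilon, standardization = des$standardization),
              class = "simulation_truth")
  })
}

# Map coefficient names back to covariate-table columns ("RegionPiedmont"
# style dummies collapse to "Region").
infer_covariates_from_coefs <- function(coef_names, covariates) {
  nm <- setdiff(coef_names, "(Intercept)")
  region_levels <- levels(factor(covariates$region))
  is_region <- nm %in% paste0("Region", region_levels)
  cols <- unique(c(if (any(is_region)) "Region", nm[!is_region]))
  unknown <- setdiff(setdiff(cols, "Region"), names(covariates))
  if (length(unknown)) {
    stop("coefficient names not found in the covariate table: ",
         paste(unknown, collapse = ", "))
  }
  cols
}

#' The nine survey-level detection covariates
#' @export
SURVEY_COVARIATES <- c("type", "duration", "clutter", "date", "issue",
                       "temperature", "humidity", "wind", "rain")

#' Default generating distributions for survey covariates
#'
#' Clutter is a 3-level categorical (none/medium/high vegetation within 5 m
#' of the detector); rain and survey issue (detector malfunction or
#' incomplete mobile survey) are Bernoulli; temperature, humidity and wind
#' are standard normal before standardization; duration is method-specific
#' (a full stationary night vs a 25-48 km transect); date is a day of year
#' in the mid-May to mid-July window.
#'
#' @param clutter_probs Probabilities of none/medium/high clutter.
#' @param p_rain,p_issue Bernoulli rates for rain and survey issues.
#' @export
survey_covariate_defaults <- function(clutter_probs = c(0.5, 0.3, 0.2),
                                      p_rain = 0.15, p_issue = 0.05) {
  stopifnot(length(clutter_probs) == 3, all(clutter_probs >= 0),
            p_rain >= 0, p_rain <= 1, p_issue >= 0, p_issue <= 1)
  list(clutter_probs = clutter_probs / sum(clutter_probs),
       p_rain = p_rain, p_issue = p_issue,
       duration_mean = c(stationary = 11, mobile = 1.2),
       duration_sd = c(stationary = 0.5, mobile = 0.3),
       date_range = c(135L, 196L))
}

#' Simulate night-by-night detection histories
#'
#' Draws survey covariates for every occasion of the design, forms detection
#' probabilities from a logistic model on the (standardized) covariates, and
#' draws Bernoulli detections conditional on the latent occupancy state:
#' a cell that is unoccupied in a year yields no detections in that year.
#'
#' @param truth A `simulation_truth` from [simulate_dynamics()].
#' @param design The `survey_design` the truth was simulated on.
#' @param alpha Named detection coefficients on the logit scale. Names must
#'   be `(Intercept)` and any of the expanded survey covariate columns:
#'   `type_mobile`, `duration`, `clutter_medium`, `clutter_high`, `date`,
#'   `issue`, `temperature`, `humidity`, `wind`, `rain`. Continuous
#'   covariates are standardized before the linear predictor, so slopes are
#'   per-SD effects.
#' @param covariate_model Distributions for the survey covariates, from
#'   [survey_covariate_defaults()].
#' @param missingness Probability an occasion is lost entirely (weather or
#'   malfunction) and dropped from the table.
#' @param seed Integer seed.
#' @return A detection table: data.frame with cell_id, year, occasion,
#'   method, y, and the nine survey covariates.
#' @export
simulate_detections <- function(truth, design, alpha,
                                covariate_model = survey_covariate_defaults(),
                                missingness = 0, seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(design, "survey_design"),
            missingness >= 0, missingness < 1)
  occ <- design$occasions
  withr_seed(seed, {
    n <- nrow(occ)
    cm <- covariate_model
    tab <- occ
    tab$duration <- stats::rnorm(n, cm$duration_mean[tab$method],
                                 cm$duration_sd[tab$method])
    tab$clutter <- sample(c("none", "medium", "high"), n, replace = TRUE,
                          prob = cm$clutter_probs)
    tab$date <- as.integer(sample(seq(cm$date_range[1], cm$date_range[2]),
                                  n, replace = TRUE))
    tab$issue <- stats::rbinom(n, 1, cm$p_issue)
    tab$temperature <- stats::rnorm(n)
    tab$humidity <- stats::rnorm(n)
    tab$wind <- stats::rnorm(n)
    tab$rain <- stats::rbinom(n, 1, cm$p_rain)

    det_cov <- infer_survey_covariates(names(alpha))
    des <- build_detection_design(tab, det_cov)
    missing_terms <- setdiff(names(alpha), colnames(des$W))
    if (length(missing_terms)) {
      stop("coefficients with no matching design column: ",
           paste(missing_terms, collapse = ", "))
    }
    a <- structure(numeric(ncol(des$W)), names = colnames(des$W))
    a[names(alpha)] <- alpha
    p <- stats::plogis(as.vector(des$W %*% a))
    zyt <- truth$z[cbind(match(tab$cell_id, design$cells), tab$year)]
    tab$y <- stats::rbinom(n, 1, zyt * p)
    if (missingness > 0) {
      keep <- stats::runif(n) >= missingness
      # never drop a cell-year entirely: keep the first occasion of each
      first <- !duplicated(tab[, c("cell_id", "year")])
      keep <- keep | first
      tab <- tab[keep, , drop = FALSE]
    }
    rownames(tab) <- NULL
    tab[, c("cell_id", "year", "occasion", "method", "y", "duration",
            "clutter", "date", "issue", "temperature", "humidity",
            "wind", "rain")]
  })
}

# Expanded coefficient names -> survey covariate names
infer_survey_covariates <- function(coef_names) {
  nm <- setdiff(coef_names, "(Intercept)")
  map <- c(type_mobile = "type", clutter_medium = "clutter",
           clutter_high = "clutter")
  base <- ifelse(nm %in% names(map), map[nm], nm)
  unknown <- setdiff(base, SURVEY_COVARIATES)
  if (length(unknown)) {
    stop("unknown detection coefficient names: ", paste(unknown, collapse = ", "))
  }
  unique(base)
}

#' Simulate a complete synthetic occupancy data set
#'
#' Convenience wrapper: builds a survey design, simulates landscape
#' covariates, latent dynamics and detection histories with one seed.
#'
#' @param n_cells,n_years Design size (defaults 38 cells, 2 years).
#' @param beta,alpha Generating occupancy and detection coefficients (see
#'   [simulate_dynamics()] and [simulate_detections()]).
#' @param gamma,epsilon Colonization and extinction probabilities.
#' @param seed Integer seed driving every stage.
#' @param ... Passed to [build_survey_design()].
#' @return List with `design`, `covariates`, `truth`, `detections`.
#' @export
simulate_occu_dataset <- function(n_cells = 38, n_years = 2,
                                  beta = c(`(Intercept)` = 0.3, Forest = 0.8),
                                  alpha = c(`(Intercept)` = 0.5, duration = 0.4),
                                  gamma = 0.2, epsilon = 0.1, seed = 1, ...) {
  seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, 4))
  design <- build_survey_design(n_cells, n_years = n_years, seed = seeds[1], ...)
  covariates <- simulate_covariate_table(design, seed = seeds[2])
  truth <- simulate_dynamics(design, covariates, beta, gamma, epsilon,
                             seed = seeds[3])
  detections <- simulate_detections(truth, design, alpha, seed = seeds[4])
  list(design = design, covariates = covariates, truth = truth,
       detections = detections)
}
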