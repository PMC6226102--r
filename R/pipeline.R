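#' A priori occupancy candidate model set
#'
#' The eleven hypothesis-driven occupancy models plus the null
#' (intercept-only) and global models. Wetland-associated species substitute
#' bottomland-forest cover (F.Wet) and its edge density (F.Wet.ED) for
#' upland Forest and F.ED throughout, and omit F.Wet.ED from the global
#' model because it is correlated with F.Wet. The global model additionally
#' drops any covariate flagged against an already-included one by the
#' correlation screen (tertiary roads are never included, being correlated
#' with development and secondary roads).
#'
#' @param wetland Use the forested-wetland substitution (default FALSE).
#' @param screen Optional `correlation_report`; flagged pairs are resolved
#'   in the global model by dropping the later-listed member.
#' @return Named list of character vectors of occupancy covariates (empty
#'   vector = null model).
#' @export
occupancy_candidate_set <- function(wetland = FALSE, screen = NULL) {
  forest <- if (wetland) "F.Wet" else "Forest"
  fed <- if (wetland) "F.Wet.ED" else "F.ED"
  cands <- list(
    c("Region"),
    c("Ag", "Dev", forest),
    c("Region", "Ag", "Dev", forest),
    c("Contagion"),
    c(fed),
    c(forest, "Contagion"),
    c("Stream"),
    c("Stream", fed),
    c("Stream", "Ag", "Dev", forest),
    c("Pri", "Sec", "Qua"),
    c("Ag", "Dev", forest, "Qua")
  )
  global <- c("Region", "Ag", "Dev", forest, "Contagion", fed,
              "Stream", "Pri", "Sec", "Qua")
  if (wetland) global <- setdiff(global, "F.Wet.ED")
  if (!is.null(screen)) {
    keep <- character()
    for (v in global) {
      clash <- nrow(screen_violations(c(keep, v), screen)) > 0
      if (!clash) keep <- c(keep, v)
    }
    global <- keep
    bad <- vapply(cands, function(cv) nrow(screen_violations(cv, screen)) > 0,
                  logical(1))
    if (any(bad)) {
      stop("candidate model(s) violate the correlation screen: ",
           paste(vapply(cands[bad], paste, "", collapse = " + "),
                 collapse = "; "))
    }
  }
  cands <- c(cands, list(character(0)), list(global))
  names(cands) <- vapply(cands, model_label, "")
  cands
}

model_label <- function(covs) if (length(covs) == 0) "." else paste(covs, collapse = " + ")

#' Default detection candidate model set
#'
#' The null detection model plus one single-term model per survey variable.
#' The exact candidate list is configurable; this default spans all nine
#' survey variables.
#'
#' @param variables Survey variables to include (default
#'   [SURVEY_COVARIATES]).
#' @return Named list of character vectors of detection covariates.
#' @export
detection_candidate_set <- function(variables = SURVEY_COVARIATES) {
  cands <- c(list(character(0)), lapply(variables, identity))
  names(cands) <- vapply(cands, model_label, "")
  cands
}

#' Stage one: select the detection model
#'
#' Fits every detection candidate with intercept-only occupancy, ranks the
#' candidates by WAIC, and returns the top model's covariates — these are
#' carried into every occupancy model for the species. A non-convergent top
#' model is carried forward with a logged R-hat warning rather than
#' aborting.
#'
#' @param detections,covariates Data tables.
#' @param candidates Detection candidates (default
#'   [detection_candidate_set()]).
#' @param config An [mcmc_config()].
#' @param quiet Suppress progress messages.
#' @return List with `det_covariates` (winning set), `comparison`
#'   (model_comparison), `fits` (per-candidate summaries), `warnings`.
#' @export
select_detection_model <- function(detections, covariates,
                                   candidates = detection_candidate_set(),
                                   config = mcmc_config(), quiet = FALSE) {
  stopifnot(length(candidates) >= 1)
  waics <- numeric(length(candidates))
  summaries <- vector("list", length(candidates))
  for (j in seq_along(candidates)) {
    if (!quiet) message("detection candidate: p(", names(candidates)[j], ")")
    data <- build_occu_data(detections, covariates,
                            occ_covariates = character(),
                            det_covariates = candidates[[j]])
    fit <- fit_occu_mcmc(data, config)
    waics[j] <- waic(fit)$waic
    summaries[[j]] <- summarize_posterior(fit)
  }
  names(waics) <- names(candidates)
  comparison <- rank_models(waics)
  top <- comparison$model[1]
  warn <- character()
  if (!summaries[[match(top, names(candidates))]]$converged) {
    warn <- paste0("top detection model '", top,
                   "' has non-converged parameters (R-hat >= 1.1): ",
                   paste(summaries[[match(top, names(candidates))]]$nonconverged_parameters,
                         collapse = ", "))
    warning(warn)
  }
  list(det_covariates = candidates[[match(top, names(candidates))]],
       comparison = comparison,
       summaries = stats::setNames(summaries, names(candidates)),
       warnings = warn)
}

#' Stage two: fit and rank the occupancy candidate set
#'
#' Fits every occupancy candidate with the detection covariates fixed from
#' stage one, ranks by WAIC with relative likelihoods and weights, flags
#' closely competing models (Delta WAIC <= 2), computes cross-validated AUC
#' for every model ranking at or better than the null, and emits the
#' prediction grid and turnover estimate from the top-ranked model.
#'
#' @param detections,covariates Data tables.
#' @param candidate_set Occupancy candidates (default
#'   [occupancy_candidate_set()]).
#' @param det_covariates Detection covariates fixed from
#'   [select_detection_model()].
#' @param config An [mcmc_config()].
#' @param partition Optional [partition_folds()] result; defaults to 5
#'   region-constrained 66% partitions drawn under `config$seed`.
#' @param cv_config Reduced schedule for cross-validation refits (defaults
#'   to `config`).
#' @param grid_covariates Optional covariate table for statewide prediction
#'   (defaults to the fitting cells).
#' @param cv Run cross-validation (default TRUE); disable for quick ranking
#'   studies.
#' @param quiet Suppress progress messages.
#' @return A `pipeline_result`: `comparison` (with mean_auc column),
#'   `summaries`, `top_model`, `top_fit`, `predictions`, `turnover`,
#'   `partition`, `warnings`.
#' @export
run_candidate_set <- function(detections, covariates,
                              candidate_set = occupancy_candidate_set(),
                              det_covariates = character(),
                              config = mcmc_config(),
                              partition = NULL,
                              cv_config = config,
                              grid_covariates = NULL,
                              cv = TRUE,
                              quiet = FALSE) {
  resolvable <- unique(unlist(candidate_set))
  missing_cols <- setdiff(setdiff(resolvable, "Region"), names(covariates))
  if (length(missing_cols)) {
    stop("unresolvable covariate(s) in the candidate set: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(partition)) {
    partition <- partition_folds(covariates$cell_id, covariates$region,
                                 seed = config$seed)
  }
  waics <- numeric(length(candidate_set))
  fits <- vector("list", length(candidate_set))
  summaries <- vector("list", length(candidate_set))
  for (j in seq_along(candidate_set)) {
    if (!quiet) message("occupancy candidate: psi(", names(candidate_set)[j], ")")
    data <- build_occu_data(detections, covariates,
                            occ_covariates = candidate_set[[j]],
                            det_covariates = det_covariates)
    fits[[j]] <- fit_occu_mcmc(data, config)
    waics[j] <- waic(fits[[j]])$waic
    summaries[[j]] <- summarize_posterior(fits[[j]])
  }
  names(waics) <- names(candidate_set)
  comparison <- rank_models(waics)

  # CV AUC only for models at or above the null, per the reporting rule
  null_waic <- waics[["."]]
  comparison$mean_auc <- NA_real_
  warns <- character()
  for (r in seq_len(nrow(comparison))) {
    if (!cv || comparison$waic[r] > null_waic) next
    mod <- comparison$model[r]
    if (!quiet) message("cross-validating: psi(", mod, ")")
    cv_res <- withCallingHandlers(
      kfold_auc(detections, covariates,
                occ_covariates = candidate_set[[match(mod, names(candidate_set))]],
                det_covariates = det_covariates,
                partition = partition, config = cv_config),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    comparison$mean_auc[r] <- cv_res$mean_auc
  }

  top <- comparison$model[1]
  top_fit <- fits[[match(top, names(candidate_set))]]
  top_summary <- summaries[[match(top, names(candidate_set))]]
  if (!top_summary$converged) {
    msg <- paste0("top occupancy model '", top,
                  "' has non-converged parameters (R-hat >= 1.1): ",
                  paste(top_summary$nonconverged_parameters, collapse = ", "))
    warns <- c(warns, msg)
    warning(msg)
  }
  predictions <- predict_occupancy_grid(
    top_fit, grid_covariates %||% covariates)
  turnover <- if (top_fit$data$T > 1) turnover_summary(top_fit) else NULL
  structure(list(comparison = comparison,
                 summaries = stats::setNames(summaries, names(candidate_set)),
                 top_model = top,
                 top_fit = top_fit,
                 predictions = predictions,
                 turnover = turnover,
                 partition = partition,
                 warnings = warns),
            class = "pipeline_result")
}

#' Run the full two-stage selection for one species
#'
#' Stage one selects the detection covariates (occupancy intercept-only);
#' stage two fixes them and runs the occupancy candidate set, cross-
#' validation, prediction and turnover.
#'
#' @param detections,covariates Data tables.
#' @param wetland Use the forested-wetland candidate substitution.
#' @param config,cv_config MCMC schedules for fitting and CV refits.
#' @param detection_candidates,screen,partition,grid_covariates,quiet Passed
#'   through to the stages; `screen` defaults to [pearson_screen()] on the
#'   covariate table.
#' @return List with `detection` (stage-one result), `occupancy` (stage-two
#'   `pipeline_result`), and `screen`.
#' @export
run_pipeline <- function(detections, covariates, wetland = FALSE,
                         config = mcmc_config(), cv_config = config,
                         detection_candidates = detection_candidate_set(),
                         screen = NULL, partition = NULL,
                         grid_covariates = NULL, quiet = FALSE) {
  screen <- screen %||% pearson_screen(covariates)
  stage1 <- select_detection_model(detections, covariates,
                                   candidates = detection_candidates,
                                   config = config, quiet = quiet)
  cands <- occupancy_candidate_set(wetland = wetland, screen = screen)
  stage2 <- run_candidate_set(detections, covariates,
                              candidate_set = cands,
                              det_covariates = stage1$det_covariates,
                              config = config, partition = partition,
                              cv_config = cv_config,
                              grid_covariates = grid_covariates,
                              quiet = quiet)
  list(detection = stage1, occupancy = stage2, screen = screen)
}
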