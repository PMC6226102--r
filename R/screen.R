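#' Pearson correlation screen over continuous covariates
#'
#' Computes the pairwise Pearson correlation matrix of the continuous
#' covariate columns and flags every pair with |r| above the threshold.
#' Flagged pairs may not co-occur in one occupancy model; candidate model
#' construction consults this report.
#'
#' @param table Cell covariate table.
#' @param threshold Absolute correlation above which a pair is flagged
#'   (default 0.7).
#' @param columns Continuous columns to screen; defaults to every numeric
#'   column except identifiers.
#' @return A `correlation_report`: list with `r` (correlation matrix),
#'   `flagged` (data.frame var1, var2, r), `threshold`.
#' @export
pearson_screen <- function(table, threshold = 0.7, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
    columns <- setdiff(columns, c("cell_id", "year", "occasion"))
  }
  if (nrow(table) < 3) stop("need at least 3 cells to screen correlations")
  X <- as.matrix(table[, columns, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate (constant) covariate column(s): ",
         paste(columns[sds == 0], collapse = ", "))
  }
  r <- stats::cor(X)
  ut <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = colnames(r)[ut[, 1]],
                        var2 = colnames(r)[ut[, 2]],
                        r = r[ut],
                        stringsAsFactors = FALSE)
  structure(list(r = r, flagged = flagged, threshold = threshold),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Correlation screen (|r| >", x$threshold, "):",
      nrow(x$flagged), "flagged pair(s)\n")
  if (nrow(x$flagged)) print(x$flagged, row.names = FALSE)
  cat("Rule: flagged pairs may not co-occur in one model\n")
  invisible(x)
}

#' Does a covariate set violate the correlation screen?
#'
#' @param covariates Character vector of covariate names (Region and other
#'   non-screened terms are ignored).
#' @param report A `correlation_report`.
#' @return Character matrix of offending pairs (0 rows if none).
#' @export
screen_violations <- function(covariates, report) {
  fl <- report$flagged
  hit <- fl$var1 %in% covariates & fl$var2 %in% covariates
  as.matrix(fl[hit, c("var1", "var2"), drop = FALSE])
}

#' Standardize continuous covariates to mean 0, SD 1
#'
#' Uses the sample (n-1) standard deviation and stores the location/scale so
#' prediction-grid covariates can be transformed with the fitting set's
#' parameters rather than their own.
#'
#' @param table Cell covariate table.
#' @param columns Columns to standardize; defaults to every numeric column
#'   except identifiers.
#' @param standardization Optional stored standardization (from a previous
#'   call) to apply instead of computing fresh location/scale.
#' @return List with `table` (standardized), `center`, `scale` (named
#'   vectors), class `standardized_covariates`.
#' @export
standardize_covariates <- function(table, columns = NULL, standardization = NULL) {
  if (!is.null(standardization)) {
    columns <- names(standardization$center)
    missing_cols <- setdiff(columns, names(table))
    if (length(missing_cols)) {
      stop("table lacks column(s) required by the stored standardization: ",
           paste(missing_cols, collapse = ", "))
    }
    center <- standardization$center
    scale <- standardization$scale
  } else {
    if (is.null(columns)) {
      columns <- names(table)[vapply(table, is.numeric, logical(1))]
      columns <- setdiff(columns, c("cell_id", "year", "occasion"))
    }
    center <- vapply(table[columns], mean, numeric(1))
    scale <- vapply(table[columns], stats::sd, numeric(1))
    if (any(scale == 0)) {
      stop("cannot standardize constant column(s): ",
           paste(columns[scale == 0], collapse = ", "))
    }
  }
  for (cl in columns) table[[cl]] <- (table[[cl]] - center[[cl]]) / scale[[cl]]
  structure(list(table = table, center = center, scale = scale),
            class = "standardized_covariates")
}
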