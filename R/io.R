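#' Write / read the detection and covariate tables as delimited text
#'
#' Tab-separated with a header row; the exact column layouts produced by
#' [simulate_detections()] and [simulate_covariate_table()].
#'
#' @param table Data frame to write.
#' @param path File path.
#' @name table_io
#' @export
write_delim_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_delim_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write posterior summaries as delimited text
#'
#' Columns: parameter, mean, lower, upper, rhat, significant.
#'
#' @param summary A `fit_summary`.
#' @param path File path.
#' @export
write_fit_summary <- function(summary, path) {
  stopifnot(inherits(summary, "fit_summary"))
  write_delim_table(summary$parameters, path)
}

#' Write retained draws in long columnar text form
#'
#' Columns: chain, iteration (within chain), parameter, value.
#'
#' @param fit An `occu_fit`.
#' @param path File path.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "occu_fit"))
  S <- nrow(fit$draws)
  iter <- stats::ave(seq_len(S), fit$chain, FUN = seq_along)
  long <- data.frame(
    chain = rep(fit$chain, times = ncol(fit$draws)),
    iteration = rep(iter, times = ncol(fit$draws)),
    parameter = rep(colnames(fit$draws), each = S),
    value = as.vector(fit$draws),
    stringsAsFactors = FALSE
  )
  write_delim_table(long, path)
}

#' Write the model comparison table
#'
#' Columns mirror the published comparison layout: model, waic, delta_waic,
#' rel_likelihood, weight, mean_auc, competing_flag.
#'
#' @param comparison A `model_comparison` (with or without a mean_auc
#'   column).
#' @param path File path.
#' @export
write_model_comparison <- function(comparison, path) {
  df <- as.data.frame(comparison)
  if (!"mean_auc" %in% names(df)) df$mean_auc <- NA_real_
  df <- df[, c("model", "waic", "delta_waic", "rel_likelihood", "weight",
               "mean_auc", "competing")]
  names(df)[names(df) == "competing"] <- "competing_flag"
  write_delim_table(df, path)
}

#' Write a run manifest
#'
#' Records inputs, seed, package version and timestamp for one pipeline
#' invocation, as key-value text.
#'
#' @param path Output file.
#' @param inputs Named character vector/list of input descriptions.
#' @param seed Seed used.
#' @param timestamp Included for the record; set it explicitly (e.g. a fixed
#'   string) when byte-identical reruns are required.
#' @export
write_manifest <- function(path, inputs = character(), seed = NA,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  lines <- c(
    paste0("package: dynocc ", as.character(utils::packageVersion("dynocc"))),
    paste0("seed: ", seed),
    paste0("timestamp: ", timestamp),
    if (length(inputs)) paste0("input ", names(inputs), ": ", unlist(inputs))
  )
  writeLines(lines, path)
  invisible(path)
}
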