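#' Five Level III ecoregions used as the default regional stratification
#'
#' South Carolina's primary physiographic regions, alphabetically ordered so
#' that dummy coding always uses the same reference level (Blue Ridge).
#' @export
DEFAULT_REGIONS <- c("BlueRidge", "CoastalPlainMiddle", "CoastalPlainSouthern",
                     "Piedmont", "Sandhills")

#' Build a grid-cell survey design
#'
#' Creates the cell-by-year-by-occasion skeleton of an acoustic monitoring
#' campaign: cells assigned to regions, and per cell-year a set of survey
#' occasions split between stationary point nights (up to 4 consecutive
#' nights) and mobile transect nights (up to 2, driven on nights when a
#' stationary detector is also out, where both methods are used).
#'
#' @param n_cells Number of grid cells. Must be at least the number of
#'   requested regions so every region receives a cell.
#' @param regions Character vector of region labels (default the five
#'   ecoregions in [DEFAULT_REGIONS]).
#' @param region_weights Sampling weights for assigning cells to regions
#'   beyond the one guaranteed cell per region; recycled/normalized.
#' @param n_years Number of consecutive survey seasons (years).
#' @param n_stationary,n_mobile Occasions per cell-year by method
#'   (defaults 4 and 2).
#' @param method_mix Proportions of cells surveyed with `both` methods,
#'   `stationary` only, or `mobile` only (named numeric, normalized).
#'   Defaults to both methods everywhere.
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A `survey_design` object: list with `cells` (ids), `regions`
#'   (factor per cell, levels fixed to `regions`), `years`, and `occasions`,
#'   a data.frame with columns cell_id, year, occasion, method.
#' @export
build_survey_design <- function(n_cells,
                                regions = DEFAULT_REGIONS,
                                region_weights = NULL,
                                n_years = 2,
                                n_stationary = 4,
                                n_mobile = 2,
                                method_mix = c(both = 1, stationary = 0, mobile = 0),
                                seed = 1) {
  stopifnot(n_cells >= 1, n_years >= 1, n_stationary >= 0, n_mobile >= 0,
            n_stationary <= 4, n_mobile <= 2, n_stationary + n_mobile >= 1)
  regions <- as.character(regions)
  if (n_cells < length(regions)) {
    stop("design infeasible: n_cells (", n_cells,
         ") is smaller than the number of requested regions (",
         length(regions), ")")
  }
  if (is.null(region_weights)) region_weights <- rep(1, length(regions))
  if (length(region_weights) != length(regions)) {
    stop("region_weights must have one weight per region")
  }
  mix <- method_mix[c("both", "stationary", "mobile")]
  mix[is.na(mix)] <- 0
  if (sum(mix) <= 0) stop("method_mix must have positive total weight")
  mix <- mix / sum(mix)

  withr_seed(seed, {
    cells <- sprintf("cell%03d", seq_len(n_cells))
    # one guaranteed cell per region, remainder sampled by weight
    reg <- character(n_cells)
    reg[seq_along(regions)] <- regions
    extra <- n_cells - length(regions)
    if (extra > 0) {
      reg[(length(regions) + 1):n_cells] <-
        sample(regions, extra, replace = TRUE, prob = region_weights)
    }
    reg <- sample(reg)  # shuffle so region is not confounded with cell index
    cell_method <- sample(names(mix), n_cells, replace = TRUE, prob = mix)

    occ <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      ns <- if (cell_method[i] == "mobile") 0L else n_stationary
      nm <- if (cell_method[i] == "stationary") 0L else n_mobile
      if (ns + nm == 0L) ns <- max(1L, n_stationary)  # every cell surveyed
      do.call(rbind, lapply(seq_len(n_years), function(t) {
        data.frame(
          cell_id = cells[i],
          year = t,
          occasion = seq_len(ns + nm),
          method = c(rep("stationary", ns), rep("mobile", nm)),
          stringsAsFactors = FALSE
        )
      }))
    }))
    rownames(occ) <- NULL
    structure(
      list(cells = cells,
           regions = factor(reg, levels = regions),
           years = seq_len(n_years),
           occasions = occ),
      class = "survey_design"
    )
  })
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", length(x$cells), "cells,",
      length(x$years), "year(s),",
      nrow(x$occasions), "occasions\n")
  print(table(region = x$regions))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
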