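#' Default aggregation of raw land-cover codes into analysis classes
#'
#' Mirrors the usual reclassification of NLCD-style codes: pasture/hay and
#' cultivated crops aggregate to Ag, all development intensities to Dev,
#' upland forest types to Forest, and woody wetlands to F.Wet. Codes not
#' covered by the map fall into "other".
#' @export
default_class_map <- function() {
  list(Ag = c(81L, 82L),
       Dev = c(21L, 22L, 23L, 24L),
       Forest = c(41L, 42L, 43L),
       F.Wet = 90L)
}

raster_values <- function(raster) {
  v <- as.vector(raster$grid)
  v[v != raster$nodata]
}

#' Percent cover per aggregated land-cover class
#'
#' @param raster A `landscape_raster`.
#' @param class_map Named list mapping analysis classes to raw code vectors;
#'   unmapped codes are reported as `other`.
#' @return Named numeric vector of percentages over non-NODATA pixels
#'   (classes in `class_map` order, then `other`); sums to 100.
#' @export
percent_cover <- function(raster, class_map = default_class_map()) {
  v <- raster_values(raster)
  if (length(v) == 0) stop("raster has no data pixels")
  out <- vapply(class_map, function(codes) 100 * mean(v %in% codes), numeric(1))
  mapped <- unlist(class_map, use.names = FALSE)
  out <- c(out, other = 100 * mean(!(v %in% mapped)))
  out
}

#' Class adjacency structure of a categorical raster
#'
#' Counts adjacencies between pixel classes under the 4-neighbourhood
#' double-count convention (each adjacent unordered pixel pair contributes
#' one count in each direction, so `g` is symmetric and like-class pairs
#' count twice on the diagonal); the landscape boundary is excluded.
#' NODATA pixels contribute neither to adjacencies nor to proportions.
#'
#' @param raster A `landscape_raster`.
#' @return A `class_adjacency`: list with `classes` (codes present), `P`
#'   (landscape proportion per class) and symmetric count matrix `g`.
#' @export
class_adjacency <- function(raster) {
  g0 <- raster$grid
  v <- raster_values(raster)
  if (length(v) == 0) stop("raster has no data pixels")
  classes <- sort(unique(v))
  m <- length(classes)
  idx <- matrix(match(g0, classes), nrow(g0), ncol(g0))  # NODATA -> NA
  g <- matrix(0, m, m, dimnames = list(classes, classes))
  tally <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return()
    t2 <- table(factor(a[ok], levels = seq_len(m)),
                factor(b[ok], levels = seq_len(m)))
    g <<- g + t2 + t(t2)
  }
  if (nrow(g0) > 1) tally(idx[-nrow(g0), , drop = FALSE], idx[-1, , drop = FALSE])
  if (ncol(g0) > 1) tally(idx[, -ncol(g0), drop = FALSE], idx[, -1, drop = FALSE])
  structure(list(classes = classes, P = as.vector(table(factor(v, levels = classes))) / length(v),
                 g = g),
            class = "class_adjacency")
}

#' Contagion index of a categorical landscape
#'
#' Aggregation/interspersion index on a 0-100 scale: 100 when the landscape
#' is maximally aggregated (each class one solid block), near 0 when classes
#' are maximally interspersed. Computed as
#' \deqn{CONTAG = \left[1 + \frac{\sum_i \sum_k q_{ik} \ln q_{ik}}{2 \ln m}\right] \times 100}
#' with \eqn{q_{ik} = P_i \, g_{ik} / \sum_k g_{ik}}, where \eqn{P_i} is the
#' proportion of the landscape in class i and \eqn{g_{ik}} the adjacency
#' counts of [class_adjacency()]; terms with \eqn{q_{ik} = 0} contribute 0.
#' Undefined for single-class landscapes.
#'
#' @param x A `landscape_raster` or `class_adjacency`.
#' @return Contagion in \[0, 100\].
#' @export
contagion <- function(x) {
  adj <- if (inherits(x, "class_adjacency")) x else class_adjacency(x)
  m <- length(adj$classes)
  if (m < 2) {
    stop(undefined_metric_error(
      "contagion is undefined for a single-class landscape"))
  }
  row_tot <- rowSums(adj$g)
  frac <- adj$g
  pos <- row_tot > 0
  frac[pos, ] <- adj$g[pos, , drop = FALSE] / row_tot[pos]
  frac[!pos, ] <- 0
  q <- adj$P * frac
  terms <- ifelse(q > 0, q * log(q), 0)
  (1 + sum(terms) / (2 * log(m))) * 100
}

undefined_metric_error <- function(msg) {
  structure(class = c("undefined_metric_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Edge density of focal classes
#'
#' Total length (m) of shared boundaries between a focal-class pixel and a
#' non-focal pixel (4-neighbourhood; the outer landscape boundary is not an
#' edge) divided by the landscape area in hectares.
#'
#' @param raster A `landscape_raster`.
#' @param focal_classes Raw class codes forming the focal class, or a name
#'   in `class_map`.
#' @param class_map Optional class map used when `focal_classes` is a name.
#' @return Edge density in m/ha.
#' @export
edge_density <- function(raster, focal_classes, class_map = default_class_map()) {
  if (is.character(focal_classes)) {
    if (!all(focal_classes %in% names(class_map))) {
      stop("focal class name(s) not in class_map: ",
           paste(setdiff(focal_classes, names(class_map)), collapse = ", "))
    }
    focal_classes <- unlist(class_map[focal_classes], use.names = FALSE)
  }
  g0 <- raster$grid
  v <- raster_values(raster)
  if (length(v) == 0) stop("raster has no data pixels")
  foc <- matrix(g0 %in% focal_classes & g0 != raster$nodata, nrow(g0), ncol(g0))
  valid <- g0 != raster$nodata
  n_edges <- 0L
  if (nrow(g0) > 1) {
    a <- seq_len(nrow(g0) - 1)
    ok <- valid[a, , drop = FALSE] & valid[-1, , drop = FALSE]
    n_edges <- n_edges +
      sum(ok & (foc[a, , drop = FALSE] != foc[-1, , drop = FALSE]))
  }
  if (ncol(g0) > 1) {
    b <- seq_len(ncol(g0) - 1)
    ok <- valid[, b, drop = FALSE] & valid[, -1, drop = FALSE]
    n_edges <- n_edges +
      sum(ok & (foc[, b, drop = FALSE] != foc[, -1, drop = FALSE]))
  }
  area_ha <- length(v) * raster$pixel_size^2 / 1e4
  n_edges * raster$pixel_size / area_ha
}

#' Compute the full landscape covariate block for one cell raster
#'
#' Percent cover for the aggregated classes plus contagion and forest /
#' forested-wetland edge densities — the raster-derived columns of the cell
#' covariate table.
#'
#' @param raster A `landscape_raster` for one (buffered) cell.
#' @param class_map Aggregation map; must contain `Forest` and `F.Wet` for
#'   the edge-density columns.
#' @return One-row data.frame: Ag, Dev, Forest, F.Wet, Contagion, F.ED,
#'   F.Wet.ED. Contagion is NA for single-class landscapes.
#' @export
cell_landscape_metrics <- function(raster, class_map = default_class_map()) {
  pc <- percent_cover(raster, class_map)
  contag <- tryCatch(contagion(raster),
                     undefined_metric_error = function(e) NA_real_)
  data.frame(Ag = pc[["Ag"]], Dev = pc[["Dev"]], Forest = pc[["Forest"]],
             F.Wet = pc[["F.Wet"]], Contagion = contag,
             F.ED = edge_density(raster, "Forest", class_map),
             F.Wet.ED = edge_density(raster, "F.Wet", class_map),
             check.names = FALSE)
}
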