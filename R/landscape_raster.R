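#' Generate a synthetic categorical land-cover raster
#'
#' Emulates a reclassified land-cover grid for one (already buffered) survey
#' cell. Pixels start as a uniform-random categorical field; `clustering`
#' iterations of 4-neighbour majority smoothing aggregate pixels of the same
#' class into patches. More smoothing passes produce larger same-class
#' patches and hence higher contagion on average.
#'
#' @param dim Pixels per side (square raster), at least 2.
#' @param n_classes Number of land-cover classes (integer codes 1..n).
#' @param clustering Number of majority-smoothing passes (0 = fully
#'   interspersed noise).
#' @param pixel_size Pixel edge length in meters (default 30, the NLCD
#'   resolution).
#' @param seed Integer seed.
#' @return A `landscape_raster`: list with integer matrix `grid`,
#'   `pixel_size`, and `nodata` code.
#' @export
generate_landscape_raster <- function(dim, n_classes, clustering = 0,
                                      pixel_size = 30, seed = 1) {
  stopifnot(dim >= 2, n_classes >= 1, clustering >= 0, pixel_size > 0)
  if (n_classes > dim^2) {
    stop("n_classes (", n_classes, ") exceeds the number of pixels (", dim^2, ")")
  }
  withr_seed(seed, {
    g <- matrix(sample.int(n_classes, dim * dim, replace = TRUE), dim, dim)
    for (pass in seq_len(clustering)) g <- majority_smooth(g, n_classes)
    landscape_raster(g, pixel_size = pixel_size)
  })
}

#' Construct a landscape raster from a class-code matrix
#'
#' @param grid Integer matrix of class codes; `nodata` marks missing pixels.
#' @param pixel_size Pixel edge length, meters.
#' @param nodata Code used for missing pixels (default -9999).
#' @export
landscape_raster <- function(grid, pixel_size = 30, nodata = -9999L) {
  stopifnot(is.matrix(grid), nrow(grid) >= 1, ncol(grid) >= 1, pixel_size > 0)
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, pixel_size = pixel_size, nodata = as.integer(nodata)),
            class = "landscape_raster")
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat("Landscape raster:", nrow(x$grid), "x", ncol(x$grid), "pixels,",
      x$pixel_size, "m resolution,",
      length(setdiff(unique(as.vector(x$grid)), x$nodata)), "classes\n")
  invisible(x)
}

# One pass of 4-neighbour majority smoothing. Each pixel takes the modal
# class among itself and its rook neighbours; ties keep the current class.
majority_smooth <- function(g, n_classes) {
  nr <- nrow(g); nc <- ncol(g)
  counts <- array(0L, c(nr, nc, n_classes))
  add <- function(m) {
    for (k in seq_len(n_classes)) {
      counts[, , k] <<- counts[, , k] + (m == k)
    }
  }
  add(g)
  up <- g[c(1, seq_len(nr - 1)), , drop = FALSE]
  down <- g[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
  left <- g[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- g[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
  # edge pixels replicate themselves instead of a missing neighbour
  add(up); add(down); add(left); add(right)
  cur <- matrix(counts[cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr),
                             as.vector(g))], nr, nc)
  best <- g
  best_n <- matrix(0L, nr, nc)
  for (k in seq_len(n_classes)) {
    ck <- counts[, , k]
    take <- ck > best_n & ck > cur  # strictly better than current class & best so far
    best[take] <- k
    best_n[take] <- ck[take]
  }
  best
}

#' Write a raster as an ESRI ASCII grid
#'
#' Standard 6-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows of integer class codes, top row first.
#'
#' @param raster A `landscape_raster`.
#' @param path Output file path.
#' @param xllcorner,yllcorner Lower-left corner coordinates.
#' @export
write_ascii_grid <- function(raster, path, xllcorner = 0, yllcorner = 0) {
  g <- raster$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(g)),
    paste("nrows", nrow(g)),
    paste("xllcorner", xllcorner),
    paste("yllcorner", yllcorner),
    paste("cellsize", raster$pixel_size),
    paste("NODATA_value", raster$nodata)
  ), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File path to an ASCII grid written by [write_ascii_grid()] or
#'   any standard GIS export.
#' @return A `landscape_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (req in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[req]])) stop("malformed ASCII grid header: missing ", req)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values; expected ", nr * nc)
  }
  g <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (is.null(hdr$nodata_value)) -9999L else as.integer(hdr$nodata_value)
  landscape_raster(g, pixel_size = hdr$cellsize, nodata = nodata)
}
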