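#' Gridded raster container
#'
#' Minimal single-band raster used for NDVI input maps and LAI output
#' maps: a numeric matrix (row 1 = northernmost row, matching the ESRI
#' ASCII grid layout) plus cell size and lower-left origin. No-data cells
#' are `NA` in memory and written out as `nodata_value`.
#'
#' @param grid numeric matrix; `NA` marks no-data cells.
#' @param cellsize cell edge length in map units.
#' @param xll,yll coordinates of the lower-left corner.
#' @param nodata_value sentinel used on disk (default -9999).
#' @param range optional length-2 valid range; finite cells outside it are
#'   rejected (NDVI grids use `c(-1, 1)`).
#' @return An object of class `lai_grid`.
#' @export
lai_grid <- function(grid, cellsize = 1, xll = 0, yll = 0,
                     nodata_value = -9999, range = NULL) {
  if (!is.matrix(grid) || !is.numeric(grid))
    vinelai_input_error("'grid' must be a numeric matrix")
  if (cellsize <= 0) vinelai_input_error("'cellsize' must be positive")
  if (!is.null(range)) {
    v <- grid[!is.na(grid)]
    if (length(v) && (min(v) < range[1] || max(v) > range[2]))
      vinelai_input_error(sprintf("cell values outside [%g, %g]",
                                  range[1], range[2]))
  }
  structure(list(grid = grid, cellsize = cellsize, xll = xll, yll = yll,
                 nodata_value = nodata_value),
            class = "lai_grid")
}

#' @export
print.lai_grid <- function(x, ...) {
  v <- x$grid[!is.na(x$grid)]
  cat(sprintf("<lai_grid> %d x %d cells (cellsize %g), %d valid",
              nrow(x$grid), ncol(x$grid), x$cellsize, length(v)))
  if (length(v)) cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster interchange format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed
#' by rows of whitespace-separated cell values, north row first.
#'
#' @param path file path.
#' @return A [lai_grid()]; no-data cells become `NA`.
#' @export
read_asc_grid <- function(path) {
  if (!file.exists(path))
    vinelai_input_error(sprintf("raster file not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[a-zA-Z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    vinelai_input_error("malformed ASCII grid header (need ncols, nrows, cellsize)")
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    vinelai_input_error(sprintf("expected %d cell values, found %d",
                                nr * nc, length(vals)))
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  grid[grid == nodata] <- NA
  lai_grid(grid, cellsize = hdr$cellsize,
           xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
           yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
           nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param x a [lai_grid()].
#' @param path output path.
#' @param digits significant digits for cell values (default 15, enough
#'   for a bit-faithful double round trip).
#' @return `path`, invisibly.
#' @export
write_asc_grid <- function(x, path, digits = 15) {
  if (!inherits(x, "lai_grid"))
    vinelai_input_error("'x' must be a lai_grid")
  g <- x$grid
  g[is.na(g)] <- x$nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", x$xll),
    sprintf("yllcorner %.10g", x$yll),
    sprintf("cellsize %.10g", x$cellsize),
    sprintf("nodata_value %.10g", x$nodata_value)
  )
  rows <- apply(g, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Classify an NDVI raster into vigor classes
#'
#' Partitions the valid cells of an NDVI map into `k` ordered classes
#' (five by default, the usual vigor-zoning choice). Methods:
#' \describe{
#'   \item{`"equal"`}{equal-interval breaks between the min and max of the
#'     valid cells (default; deterministic).}
#'   \item{`"quantile"`}{breaks at the `k`-quantiles, giving classes of
#'     roughly equal cell count.}
#'   \item{`"kmeans"`}{1-D k-means with deterministic quantile-based
#'     initialisation; breaks midway between adjacent cluster edges
#'     (a natural-breaks style classification).}
#' }
#'
#' @param raster a [lai_grid()] of NDVI values (or a bare matrix).
#' @param k number of classes.
#' @param method classification method.
#' @return An object of class `classified_raster`: integer `labels` matrix
#'   (`NA` preserved), `class_bounds` (k + 1 increasing breakpoints),
#'   `class_means` (mean NDVI per class) and `class_counts`.
#' @export
classify_ndvi <- function(raster, k = 5,
                          method = c("equal", "quantile", "kmeans")) {
  method <- match.arg(method)
  if (!inherits(raster, "lai_grid")) raster <- lai_grid(as.matrix(raster))
  g <- raster$grid
  v <- g[!is.na(g)]
  k <- as.integer(k)
  if (k < 1L) vinelai_input_error("'k' must be >= 1")
  if (length(unique(v)) < k)
    vinelai_input_error(sprintf(
      "cannot form %d classes from %d distinct valid values",
      k, length(unique(v))))

  if (k == 1L) {
    bounds <- range(v)
  } else if (method == "equal") {
    bounds <- seq(min(v), max(v), length.out = k + 1L)
  } else if (method == "quantile") {
    bounds <- unname(quantile(v, probs = seq(0, 1, length.out = k + 1L)))
    if (any(diff(bounds) <= 0))
      vinelai_input_error("quantile breaks are not strictly increasing; use fewer classes or method = 'equal'")
  } else {                                       # kmeans
    centers <- unname(quantile(unique(v), probs = seq(0, 1, length.out = k)))
    km <- kmeans(v, centers = matrix(centers, ncol = 1))
    ord <- order(km$centers)
    lab <- match(km$cluster, ord)
    edges <- vapply(seq_len(k - 1L), function(i)
      (max(v[lab == i]) + min(v[lab == i + 1L])) / 2, numeric(1))
    bounds <- c(min(v), edges, max(v))
  }

  lab_of <- function(x) {
    out <- findInterval(x, bounds, rightmost.closed = TRUE, all.inside = TRUE)
    out[is.na(x)] <- NA_integer_
    out
  }
  labels <- matrix(lab_of(as.vector(g)), nrow(g), ncol(g))
  means <- vapply(seq_len(k), function(i) mean(g[which(labels == i)]),
                  numeric(1))
  counts <- vapply(seq_len(k), function(i) sum(labels == i, na.rm = TRUE),
                   integer(1))
  structure(
    list(labels = labels, k = k, method = method, class_bounds = bounds,
         class_means = means, class_counts = counts, raster = raster),
    class = "classified_raster"
  )
}

#' @export
print.classified_raster <- function(x, ...) {
  cat(sprintf("<classified_raster> %d classes (%s)\n", x$k, x$method))
  for (i in seq_len(x$k))
    cat(sprintf("  class %d: [%.4f, %.4f], mean %.4f, %d cells\n", i,
                x$class_bounds[i], x$class_bounds[i + 1L],
                x$class_means[i], x$class_counts[i]))
  invisible(x)
}

#' Calibrate a linear NDVI-to-LAI relationship
#'
#' Fits `laiv = a * ndvi + b` by ordinary least squares to the in-situ
#' calibration points - the "smart scouting" step, where a few ground LAI
#' estimates (one per vigor class) anchor the relative NDVI signal to
#' absolute LAI.
#'
#' @param ndvi NDVI values at the sampling areas, or a data frame / CSV
#'   path with columns `ndvi` and `laiv`.
#' @param laiv matching ground LAI estimates (omit when `ndvi` is a table).
#' @return An object of class `lai_calibration` with `slope`, `intercept`,
#'   `r2`, `n` and the underlying `lm` fit; supports `coef()`, `predict()`
#'   and `print()`.
#' @export
fit_calibration <- function(ndvi, laiv = NULL) {
  if (is.character(ndvi)) ndvi <- read.csv(ndvi, stringsAsFactors = FALSE)
  if (is.data.frame(ndvi)) {
    if (!all(c("ndvi", "laiv") %in% names(ndvi)))
      vinelai_input_error("calibration table needs 'ndvi' and 'laiv' columns")
    laiv <- ndvi$laiv
    ndvi <- ndvi$ndvi
  }
  if (length(ndvi) != length(laiv) || length(ndvi) < 2L)
    vinelai_input_error("need >= 2 paired (ndvi, laiv) points")
  if (sd(ndvi) < .Machine$double.eps)
    vinelai_input_error("'ndvi' is constant: slope is unidentifiable")
  fit <- lm(laiv ~ ndvi)
  # summary.lm warns on an exact fit; r2 = 1 is the intended answer there
  r2 <- if (length(ndvi) == 2L) 1 else
    suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, n = length(ndvi), fit = fit,
         points = data.frame(ndvi = ndvi, laiv = laiv)),
    class = "lai_calibration"
  )
}

#' @export
print.lai_calibration <- function(x, digits = 4, ...) {
  cat(sprintf("<lai_calibration> laiv = %.*f * ndvi + %.*f  (n = %d, R^2 = %.*f)\n",
              digits, x$slope, digits, x$intercept, x$n, digits, x$r2))
  invisible(x)
}

#' @export
coef.lai_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.lai_calibration <- function(object, ndvi, ...) {
  object$slope * ndvi + object$intercept
}

#' Reclassify an NDVI raster into an absolute LAI map
#'
#' Applies the calibration cell-wise, `lai = a * ndvi + b`, flooring
#' negative predictions at zero (LAI is non-negative) and preserving
#' no-data cells. The number of floored cells is recorded in the
#' `n_floored` attribute and raised as a warning when positive.
#'
#' @param raster a [lai_grid()] of NDVI values.
#' @param fit a [fit_calibration()] result.
#' @return A [lai_grid()] of LAI values with the source geometry.
#' @export
reclassify_to_lai <- function(raster, fit) {
  if (!inherits(raster, "lai_grid"))
    vinelai_input_error("'raster' must be a lai_grid")
  if (!inherits(fit, "lai_calibration"))
    vinelai_input_error("'fit' must be a lai_calibration")
  lai <- fit$slope * raster$grid + fit$intercept
  n_floored <- sum(lai < 0, na.rm = TRUE)
  lai[!is.na(lai) & lai < 0] <- 0
  out <- lai_grid(lai, cellsize = raster$cellsize, xll = raster$xll,
                  yll = raster$yll, nodata_value = raster$nodata_value)
  attr(out, "n_floored") <- n_floored
  if (n_floored > 0L)
    warning(sprintf("%d negative LAI prediction(s) floored to 0", n_floored),
            call. = FALSE)
  out
}
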