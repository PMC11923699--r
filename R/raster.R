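#' In-memory gridded raster
#'
#' Minimal planar raster used throughout the package: a numeric matrix of
#' cell values on a regular square grid in projected km. Conventions (fixed,
#' relied on by the extraction tests): cell-center registered, stored
#' row-major from the top-left (row 1 = northernmost row), cells are
#' half-open intervals `[x0, x0 + cellsize)` in both axes.
#'
#' @param values numeric matrix; row 1 is the top (largest y) row.
#' @param xll,yll coordinates of the lower-left corner of the grid, km.
#' @param cellsize cell edge length, km.
#' @return An object of class `"geo_raster"`.
#' @export
geo_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0,
            is.finite(xll), is.finite(yll))
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "geo_raster")
}

#' @export
print.geo_raster <- function(x, ...) {
  cat(sprintf("geo_raster: %d rows x %d cols, cellsize %g km\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] km\n",
              x$xll, x$xll + ncol(x$values) * x$cellsize,
              x$yll, x$yll + nrow(x$values) * x$cellsize))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize)
}

same_geometry <- function(a, b, tol = 1e-9) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Coordinates of all cell centers
#'
#' @param r a [geo_raster()].
#' @return data.frame with columns `x`, `y`, `row`, `col` in row-major order
#'   from the top-left, matching `as.vector(t(r$values))`.
#' @export
raster_cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), times = nr)
  row <- rep(seq_len(nr), each = nc)
  data.frame(
    x = r$xll + (col - 0.5) * r$cellsize,
    y = r$yll + (nr - row + 0.5) * r$cellsize,
    row = row, col = col)
}

#' Values of a raster in cell-center order
#'
#' @param r a [geo_raster()].
#' @return numeric vector aligned with [raster_cell_centers()].
#' @export
raster_values <- function(r) as.vector(t(r$values))

#' Extract raster values at point locations
#'
#' Pure nearest-cell lookup: each point gets the value of the cell that
#' contains it under the half-open `[x0, x0 + cellsize)` convention; no
#' interpolation. Points outside the raster extent yield `NA` and are
#' flagged in the `"outside"` attribute; if every point is outside, an
#' error is raised.
#'
#' @param r a [geo_raster()].
#' @param x,y point coordinates, km (same projected system as the raster).
#' @return numeric vector of cell values with attribute `outside`
#'   (logical, `TRUE` where the point fell off the raster).
#' @export
extract_at_points <- function(r, x, y) {
  stopifnot(inherits(r, "geo_raster"), length(x) == length(y))
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xll) / r$cellsize) + 1
  row_bottom <- floor((y - r$yll) / r$cellsize) + 1
  row <- nr - row_bottom + 1
  outside <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > nc | row < 1 | row > nr
  if (all(outside))
    stop("all points fall outside the raster extent", call. = FALSE)
  vals <- rep(NA_real_, length(x))
  idx <- which(!outside)
  vals[idx] <- r$values[cbind(row[idx], col[idx])]
  attr(vals, "outside") <- outside
  vals
}

#' Regrid a raster by bilinear interpolation
#'
#' Interpolates a (typically coarser) raster onto a finer target geometry,
#' the way coarse-resolution covariates are brought to a common analysis
#' grid. Interpolation is bilinear between source cell centers; beyond the
#' outermost centers values are clamped to the edge cell, so the output
#' never overshoots the source range.
#'
#' @param r source [geo_raster()].
#' @param target a [geo_raster()] (values ignored) or a list with elements
#'   `nrow`, `ncol`, `xll`, `yll`, `cellsize` giving the output geometry.
#' @return A [geo_raster()] on the target geometry.
#' @export
regrid_bilinear <- function(r, target) {
  stopifnot(inherits(r, "geo_raster"))
  if (inherits(target, "geo_raster")) {
    tg <- list(nrow = nrow(target$values), ncol = ncol(target$values),
               xll = target$xll, yll = target$yll,
               cellsize = target$cellsize)
  } else tg <- target
  if (tg$cellsize > r$cellsize + 1e-12)
    stop("target resolution must be finer than or equal to the source",
         call. = FALSE)
  ex <- raster_extent(r)
  t_xmax <- tg$xll + tg$ncol * tg$cellsize
  t_ymax <- tg$yll + tg$nrow * tg$cellsize
  if (t_xmax <= ex["xmin"] || tg$xll >= ex["xmax"] ||
      t_ymax <= ex["ymin"] || tg$yll >= ex["ymax"])
    stop("target extent does not overlap the source raster", call. = FALSE)

  nr <- nrow(r$values); nc <- ncol(r$values)
  # fractional (0-based) position of target centers among source centers
  tx <- tg$xll + (seq_len(tg$ncol) - 0.5) * tg$cellsize
  ty <- tg$yll + (tg$nrow - seq_len(tg$nrow) + 0.5) * tg$cellsize
  gx <- pmin(pmax((tx - (r$xll + r$cellsize / 2)) / r$cellsize, 0), nc - 1)
  # gy measured from the TOP row so it indexes the matrix directly
  gy <- pmin(pmax(((r$yll + (nr - 0.5) * r$cellsize) - ty) / r$cellsize, 0),
             nr - 1)
  cx0 <- pmin(floor(gx), nc - 2 + (nc == 1)); fx <- gx - cx0
  ry0 <- pmin(floor(gy), nr - 2 + (nr == 1)); fy <- gy - ry0
  out <- matrix(NA_real_, tg$nrow, tg$ncol)
  for (i in seq_len(tg$nrow)) {
    r0 <- ry0[i] + 1; r1 <- min(r0 + 1, nr)
    v00 <- r$values[r0, cx0 + 1]; v01 <- r$values[r0, pmin(cx0 + 2, nc)]
    v10 <- r$values[r1, cx0 + 1]; v11 <- r$values[r1, pmin(cx0 + 2, nc)]
    out[i, ] <- (1 - fy[i]) * ((1 - fx) * v00 + fx * v01) +
      fy[i] * ((1 - fx) * v10 + fx * v11)
  }
  geo_raster(out, xll = tg$xll, yll = tg$yll, cellsize = tg$cellsize)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header followed by rows top to bottom). Writes are atomic
#' (temp-file-and-rename).
#'
#' @param r a [geo_raster()].
#' @param path file path (conventionally `.asc`).
#' @param digits significant digits written.
#' @return `write_asc` returns `path` invisibly; `read_asc` a [geo_raster()].
#' @export
write_asc <- function(r, path, digits = 10) {
  stopifnot(inherits(r, "geo_raster"))
  vals <- r$values
  vals[!is.finite(vals)] <- -9999
  hdr <- c(paste("ncols", ncol(r$values)),
           paste("nrows", nrow(r$values)),
           paste("xllcorner", format(r$xll, digits = 15)),
           paste("yllcorner", format(r$yll, digits = 15)),
           paste("cellsize", format(r$cellsize, digits = 15)),
           "NODATA_value -9999")
  body <- apply(vals, 1, function(rw)
    paste(format(rw, digits = digits, trim = TRUE, scientific = NA),
          collapse = " "))
  atomic_write(path, function(p) writeLines(c(hdr, body), p))
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  ln <- readLines(path)
  hdr <- ln[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- do.call(rbind, lapply(ln[-(1:6)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  vals[vals == h[["nodata_value"]]] <- NA_real_
  stopifnot(nrow(vals) == h[["nrows"]], ncol(vals) == h[["ncols"]])
  geo_raster(vals, xll = h[["xllcorner"]], yll = h[["yllcorner"]],
             cellsize = h[["cellsize"]])
}
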