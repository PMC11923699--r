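#' Polygon layer for administrative aggregation
#'
#' Minimal polygon container: a named list of polygons, each a list of
#' rings (closed is optional; first ring outer, later rings holes under
#' the even-odd rule), each ring a 2-column coordinate matrix in km.
#'
#' @param polygons named list as described.
#' @return object of class `"geo_polygons"`.
#' @export
geo_polygons <- function(polygons) {
  stopifnot(is.list(polygons), length(polygons) >= 1)
  if (is.null(names(polygons)) || any(names(polygons) == ""))
    names(polygons) <- paste0("polygon_", seq_along(polygons))
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p) || is.data.frame(p)) p <- list(as.matrix(p))
    lapply(p, function(ring) {
      ring <- as.matrix(ring)
      stopifnot(ncol(ring) == 2, nrow(ring) >= 3)
      ring
    })
  })
  structure(polygons, class = "geo_polygons")
}

#' Read administrative polygons from GeoJSON
#'
#' Supports FeatureCollections of Polygon / MultiPolygon features;
#' feature ids come from the first of `id_property`, the feature `id`, or
#' a running index. Coordinates are taken as-is (the pipeline works in
#' projected km).
#'
#' @param path GeoJSON file.
#' @param id_property property name holding the polygon (district) id.
#' @return a [geo_polygons()].
#' @export
read_geojson_polygons <- function(path, id_property = "id") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  polys <- list()
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    id <- ft$properties[[id_property]] %||% ft$id %||% paste0("feature_", i)
    gtype <- ft$geometry$type
    ring_of <- function(r) do.call(rbind, lapply(r, function(pt)
      c(pt[[1]], pt[[2]])))
    rings <- switch(gtype,
      Polygon = lapply(ft$geometry$coordinates, ring_of),
      MultiPolygon = unlist(lapply(ft$geometry$coordinates,
                                   function(pp) lapply(pp, ring_of)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", gtype, call. = FALSE))
    polys[[as.character(id)]] <- rings
  }
  geo_polygons(polys)
}

# even-odd (ray casting) point-in-ring test; boundary points count as in
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Assign points to polygons by containment
#'
#' @param x,y point coordinates (cell centers), km.
#' @param polygons a [geo_polygons()].
#' @return integer index of the containing polygon per point (first match
#'   wins if polygons overlap), `NA` where no polygon contains the point.
#' @export
assign_polygons <- function(x, y, polygons) {
  stopifnot(inherits(polygons, "geo_polygons"))
  out <- rep(NA_integer_, length(x))
  for (k in seq_along(polygons)) {
    inside <- rep(FALSE, length(x))
    for (ring in polygons[[k]]) inside <- xor(inside,
                                              point_in_ring(x, y, ring))
    out[is.na(out) & inside] <- k
  }
  out
}

#' Aggregate prevalence and case counts over administrative polygons
#'
#' Cells are assigned to polygons by cell-center containment; per polygon
#' the expected cases are `sum(prevalence * population)` over member
#' cells and the prevalence is the population-weighted mean
#' `cases / population`. Cells outside every polygon are reported, not
#' silently dropped; a polygon capturing zero population has undefined
#' prevalence (NA, flagged).
#'
#' @param surface data.frame with coordinate columns (first two columns
#'   or `x`/`y`) and a `prevalence` column, typically from
#'   [predict.geofit()]; rows = grid cells.
#' @param polygons a [geo_polygons()].
#' @param population numeric vector of under-5 population per row of
#'   `surface`, or a [geo_raster()] to be extracted at the surface
#'   coordinates.
#' @return data.frame (class `"district_summary"`): `district`,
#'   `population`, `cases`, `prevalence`, `n_cells`; attributes
#'   `n_unassigned` (cells outside all polygons) and `unassigned_cases`.
#' @export
aggregate_polygons <- function(surface, polygons, population) {
  stopifnot(inherits(polygons, "geo_polygons"))
  xy_names <- if (all(c("x", "y") %in% names(surface))) c("x", "y")
              else names(surface)[1:2]
  px <- surface[[xy_names[1]]]; py <- surface[[xy_names[2]]]
  prev <- surface$prevalence
  if (is.null(prev)) stop("surface lacks a 'prevalence' column",
                          call. = FALSE)
  pop <- if (inherits(population, "geo_raster"))
    as.numeric(extract_at_points(population, px, py)) else population
  if (length(pop) != nrow(surface))
    stop("population does not align with the surface cells",
         call. = FALSE)
  idx <- assign_polygons(px, py, polygons)
  cases_cell <- prev * pop
  agg <- function(v, f) {
    out <- rep(NA_real_, length(polygons))
    s <- tapply(v, factor(idx, levels = seq_along(polygons)), f)
    out[!is.na(s)] <- s[!is.na(s)]
    out
  }
  pop_d <- agg(pop, function(v) sum(v, na.rm = TRUE))
  cases_d <- agg(cases_cell, function(v) sum(v, na.rm = TRUE))
  ncell_d <- agg(rep(1, length(idx)), sum)
  pop_d[is.na(pop_d)] <- 0; cases_d[is.na(cases_d)] <- 0
  ncell_d[is.na(ncell_d)] <- 0
  prev_d <- ifelse(pop_d > 0, cases_d / pop_d, NA_real_)
  out <- data.frame(district = names(polygons), population = pop_d,
                    cases = cases_d, prevalence = prev_d,
                    n_cells = as.integer(ncell_d), row.names = NULL)
  attr(out, "n_unassigned") <- sum(is.na(idx))
  attr(out, "unassigned_cases") <- sum(cases_cell[is.na(idx)], na.rm = TRUE)
  if (any(pop_d == 0))
    warning("polygon(s) with zero population: prevalence undefined",
            call. = FALSE)
  class(out) <- c("district_summary", class(out))
  out
}
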