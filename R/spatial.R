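# Kernel density surfaces and assignment of points to named regions.

#' Normal-reference bandwidth for one axis
#'
#' \eqn{h = 1.06 \cdot \min(\mathrm{sd}, \mathrm{IQR}/1.34) \cdot n^{-1/5}},
#' the classic rule-of-thumb for a Gaussian kernel.
#'
#' @param x numeric vector.
#' @return bandwidth in the units of `x` (0 when the data are degenerate).
#' @export
bandwidth_nrd <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x)
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  1.06 * spread * n^(-1 / 5)
}

#' Two-dimensional kernel density surface of collection effort
#'
#' Product-Gaussian KDE over longitude/latitude, the standard smoothed
#' picture of where collecting effort concentrated.  Coordinates are
#' treated as planar degrees (visualisation semantics); density units
#' are points per square degree and the surface integrates to ~1 when
#' the grid pads the data by several bandwidths.
#'
#' @param lon,lat coordinate vectors (>= 2 distinct points).
#' @param bandwidth optional `c(h_lon, h_lat)`; default per-axis
#'   normal-reference rule ([bandwidth_nrd()]).
#' @param grid_size `c(nx, ny)` grid dimensions (default 100 x 100).
#' @param pad grid padding beyond the data bounding box, in bandwidths
#'   (default 3).
#' @return object of class `density_surface`: list with ascending
#'   `grid_lon`, `grid_lat`, `density` matrix (`length(grid_lon)` rows x
#'   `length(grid_lat)` columns), and `bandwidth`.
#' @export
kde2d_surface <- function(lon, lat, bandwidth = NULL, grid_size = c(100, 100),
                          pad = 3) {
  n <- length(lon)
  if (length(lat) != n) stop("lon and lat must have equal length", call. = FALSE)
  if (n < 2 || nrow(unique(cbind(lon, lat))) < 2) {
    stop("need at least 2 points with distinct coordinates", call. = FALSE)
  }
  if (is.null(bandwidth)) {
    bandwidth <- c(bandwidth_nrd(lon), bandwidth_nrd(lat))
    if (any(bandwidth <= 0)) {
      stop("bandwidth rule degenerate (zero spread on an axis); supply an explicit bandwidth",
           call. = FALSE)
    }
  }
  if (any(bandwidth <= 0)) stop("bandwidth must be positive", call. = FALSE)
  hx <- bandwidth[1]; hy <- bandwidth[2]
  gx <- seq(min(lon) - pad * hx, max(lon) + pad * hx, length.out = grid_size[1])
  gy <- seq(min(lat) - pad * hy, max(lat) + pad * hy, length.out = grid_size[2])
  # f(x, y) = (1/n) sum_i phi((x - xi)/hx)/hx * phi((y - yi)/hy)/hy
  ax <- outer(gx, lon, function(g, p) stats::dnorm((g - p) / hx) / hx)
  ay <- outer(gy, lat, function(g, p) stats::dnorm((g - p) / hy) / hy)
  dens <- (ax %*% t(ay)) / n
  structure(
    list(grid_lon = gx, grid_lat = gy, density = dens,
         bandwidth = c(h_lon = hx, h_lat = hy), n = n),
    class = "density_surface"
  )
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("Kernel density surface: %d x %d grid, bandwidth (%.4g, %.4g) deg, n = %d\n",
              length(x$grid_lon), length(x$grid_lat),
              x$bandwidth[1], x$bandwidth[2], x$n))
  invisible(x)
}

#' Numeric integral of a density surface over its grid
#'
#' Cell-sum approximation; close to 1 when the grid pads the data
#' bounding box by three or more bandwidths.
#'
#' @param surface a `density_surface`.
#' @return scalar integral estimate.
#' @export
density_integral <- function(surface) {
  dx <- mean(diff(surface$grid_lon))
  dy <- mean(diff(surface$grid_lat))
  sum(surface$density) * dx * dy
}

# GeoJSON polygons --------------------------------------------------------

#' Read named polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features in
#' WGS84.  Each feature must carry a name property (`name`, `NAME`, or
#' the first character property found).
#'
#' @param path GeoJSON file path.
#' @param name_property property holding the unit name (default "name").
#' @return named list of polygons; each polygon is a list of rings, each
#'   ring a two-column matrix (lon, lat).  Outer and hole rings are all
#'   kept (containment uses the even-odd rule, so holes work naturally).
#' @export
read_geojson_polygons <- function(path, name_property = "name") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  polys <- list()
  for (feat in gj$features) {
    props <- feat$properties
    nm <- props[[name_property]]
    if (is.null(nm)) {
      chr <- Filter(is.character, props)
      if (length(chr) == 0) stop("feature lacks a name property", call. = FALSE)
      nm <- chr[[1]]
    }
    geom <- feat$geometry
    ring_sets <- switch(
      geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop(sprintf("unsupported geometry type '%s' in feature '%s'",
                   geom$type, nm), call. = FALSE)
    )
    rings <- list()
    for (rs in ring_sets) {
      for (ring in rs) {
        rings[[length(rings) + 1]] <-
          do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      }
    }
    polys[[nm]] <- rings
  }
  polys
}

# Even-odd point-in-polygon with on-edge counted as inside.
.point_in_ring <- function(px, py, ring, eps = 1e-12) {
  x <- ring[, 1]; y <- ring[, 2]
  nv <- length(x)
  j <- nv
  inside <- FALSE
  for (i in seq_len(nv)) {
    # on-vertex / on-edge check
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    cross <- (px - x[i]) * dy - (py - y[i]) * dx
    if (abs(cross) < eps &&
        px >= min(x[i], x[j]) - eps && px <= max(x[i], x[j]) + eps &&
        py >= min(y[i], y[j]) - eps && py <= max(y[i], y[j]) + eps) {
      return(TRUE)
    }
    if ((y[i] > py) != (y[j] > py)) {
      xint <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

.validate_polygon <- function(poly, name) {
  for (ring in poly) {
    if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3 ||
        any(!is.finite(ring))) {
      stop(sprintf("invalid ring in polygon '%s'", name), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Point-in-polygon test (even-odd rule, edges inside)
#'
#' @param px,py point coordinates (vectors).
#' @param polygon a list of rings (two-column matrices).  A point inside
#'   an odd number of rings is inside the polygon.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  vapply(seq_along(px), function(i) {
    hits <- vapply(polygon, function(ring) .point_in_ring(px[i], py[i], ring),
                   logical(1))
    # edge membership in any ring counts as inside; otherwise even-odd
    on_edge <- any(vapply(polygon, function(ring) {
      .ring_on_edge(px[i], py[i], ring)
    }, logical(1)))
    if (on_edge) TRUE else (sum(hits) %% 2) == 1
  }, logical(1))
}

.ring_on_edge <- function(px, py, ring, eps = 1e-12) {
  x <- ring[, 1]; y <- ring[, 2]
  nv <- length(x)
  j <- nv
  for (i in seq_len(nv)) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    cross <- (px - x[i]) * dy - (py - y[i]) * dx
    if (abs(cross) < eps &&
        px >= min(x[i], x[j]) - eps && px <= max(x[i], x[j]) + eps &&
        py >= min(y[i], y[j]) - eps && py <= max(y[i], y[j]) + eps) {
      return(TRUE)
    }
    j <- i
  }
  FALSE
}

#' Round half away from zero
#'
#' Integer-percent rounding convention used in the region tables
#' (2.5 -> 3), unlike R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Count specimens per named spatial unit
#'
#' Assigns each georeferenced point to the named polygons containing it.
#' Provinces and ecoregions are treated as partitions: a point on a
#' shared boundary counts for exactly one unit (the lexicographically
#' first containing unit).  Centres of endemism and important plant
#' areas may overlap, so a point can count for several units.  Points in
#' no polygon are tallied as `"unassigned"`.  Percentages are relative
#' to the total number of points and rounded half away from zero to
#' integer percent.
#'
#' @param lon,lat point coordinates.
#' @param polygons named list of polygons (see
#'   [read_geojson_polygons()]).
#' @param category one of `"province"`, `"ecoregion"`, `"CoE"`, `"IPA"`.
#' @return data frame `unit_name`, `category`, `n_specimens`, `pct`.
#' @export
assign_regions <- function(lon, lat, polygons,
                           category = c("province", "ecoregion", "CoE", "IPA")) {
  category <- match.arg(category)
  partition <- category %in% c("province", "ecoregion")
  nms <- sort(names(polygons))
  for (nm in nms) .validate_polygon(polygons[[nm]], nm)
  total <- length(lon)
  counts <- stats::setNames(integer(length(nms)), nms)
  unassigned <- 0L
  for (i in seq_along(lon)) {
    inside <- nms[vapply(nms, function(nm) {
      point_in_polygon(lon[i], lat[i], polygons[[nm]])
    }, logical(1))]
    if (length(inside) == 0) {
      unassigned <- unassigned + 1L
    } else if (partition) {
      counts[inside[1]] <- counts[inside[1]] + 1L
    } else {
      counts[inside] <- counts[inside] + 1L
    }
  }
  out <- data.frame(
    unit_name = c(nms, "unassigned"),
    category = category,
    n_specimens = c(as.integer(counts), unassigned),
    stringsAsFactors = FALSE
  )
  out$pct <- round_half_up(100 * out$n_specimens / total)
  rownames(out) <- NULL
  out
}
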