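# Presence/pseudo-absence predictor table construction.

#' Canonical land-cover category levels
#'
#' The six ecological land-use/land-cover categories used throughout:
#' agriculture and croplands, forest and tree cover, grassland and
#' shrubland, wetland and riparian zones, urban and bare areas, water
#' bodies.  Integer raster codes 1-6 map onto these levels in order;
#' the first level is the reference category under dummy coding.
#'
#' @return character vector of 6 level names.
#' @export
lulc_levels <- function() {
  c("agriculture_croplands", "forest_tree_cover", "grassland_shrubland",
    "wetland_riparian", "urban_bare", "water_bodies")
}

#' Sample pseudo-absence points in the presence bounding box
#'
#' Draws `n` points uniformly over the bounding box of the presence
#' coordinates, optionally rejection-resampling into a mask polygon
#' and/or into locations where a validity predicate holds (e.g., cells
#' with non-missing predictor values).  Deterministic for a given seed.
#'
#' @param presences data frame or matrix with `lon`, `lat` columns
#'   (>= 2 points spanning a non-degenerate box).
#' @param n number of points (default: one per presence, the balanced
#'   1:1 design).
#' @param seed integer RNG seed.
#' @param mask optional polygon (list of rings) points must fall in.
#' @param valid_fun optional `function(lon, lat) -> logical` validity
#'   predicate.
#' @param max_attempts rejection budget (default `1000 * n`).
#' @return data frame with columns `lon`, `lat`.
#' @export
sample_pseudo_absences <- function(presences, n = NULL, seed = 1,
                                   mask = NULL, valid_fun = NULL,
                                   max_attempts = NULL) {
  pts <- as.data.frame(presences)
  if (nrow(pts) < 2) stop("need at least 2 presences", call. = FALSE)
  bb <- c(range(pts$lon), range(pts$lat))
  if (bb[1] == bb[2] || bb[3] == bb[4]) {
    stop("presence bounding box is degenerate", call. = FALSE)
  }
  if (is.null(n)) n <- nrow(pts)
  if (is.null(max_attempts)) max_attempts <- 1000 * n
  set.seed(seed)
  out_lon <- numeric(0); out_lat <- numeric(0)
  attempts <- 0L
  while (length(out_lon) < n) {
    need <- n - length(out_lon)
    batch <- min(max(need * 2L, 100L), max_attempts - attempts)
    if (batch <= 0) {
      stop(sprintf("pseudo-absence rejection budget exhausted after %d attempts",
                   attempts), call. = FALSE)
    }
    lon <- stats::runif(batch, bb[1], bb[2])
    lat <- stats::runif(batch, bb[3], bb[4])
    attempts <- attempts + batch
    keep <- rep(TRUE, batch)
    if (!is.null(mask)) keep <- keep & point_in_polygon(lon, lat, mask)
    if (!is.null(valid_fun)) keep <- keep & valid_fun(lon, lat)
    out_lon <- c(out_lon, lon[keep])
    out_lat <- c(out_lat, lat[keep])
  }
  data.frame(lon = out_lon[seq_len(n)], lat = out_lat[seq_len(n)])
}

#' Build the presence/pseudo-absence modelling table
#'
#' One row per point with the binary response (presence = 1,
#' pseudo-absence = 0) and the predictors: elevation (m), slope
#' (degrees), land-cover category (factor over [lulc_levels()]),
#' distance to the nearest road and harbour (m).  Rows with any missing
#' predictor are dropped with a message giving the count.
#'
#' @param presences,absences data frames with `lon`, `lat`.
#' @param elev,slope,lulc co-aligned `geo_raster` layers (`lulc` coded
#'   1-6).
#' @param roads list of polyline matrices (lon, lat).
#' @param harbours two-column matrix of harbour points.
#' @param spacing road densification spacing in metres passed to
#'   [distance_to_nearest()].
#' @return data frame `lon`, `lat`, `presence`, `elevation`, `slope`,
#'   `lulc`, `dist_road`, `dist_harbour`.
#' @export
build_model_table <- function(presences, absences, elev, slope, lulc,
                              roads, harbours, spacing = 100) {
  pts <- rbind(
    data.frame(lon = presences$lon, lat = presences$lat, presence = 1L),
    data.frame(lon = absences$lon, lat = absences$lat, presence = 0L)
  )
  pts$elevation <- extract_at_points(elev, pts$lon, pts$lat)
  pts$slope <- extract_at_points(slope, pts$lon, pts$lat)
  lulc_code <- extract_at_points(lulc, pts$lon, pts$lat)
  pts$lulc <- factor(lulc_levels()[lulc_code], levels = lulc_levels())
  pts$dist_road <- distance_to_nearest(pts$lon, pts$lat, roads,
                                       spacing = spacing)
  pts$dist_harbour <- distance_to_nearest(pts$lon, pts$lat, harbours)
  complete <- stats::complete.cases(
    pts[, c("elevation", "slope", "lulc", "dist_road", "dist_harbour")]
  )
  if (any(!complete)) {
    message(sprintf("dropped %d row(s) with missing predictor values",
                    sum(!complete)))
  }
  out <- pts[complete, , drop = FALSE]
  rownames(out) <- NULL
  out
}
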