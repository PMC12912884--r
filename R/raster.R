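# Minimal in-memory geographic raster (WGS84, north-up, square cells)
# with plain-text (ESRI ASCII grid) I/O.  values is an nrow x ncol
# matrix; row 1 is the northernmost row, column 1 the westernmost.

#' Construct a geographic raster
#'
#' @param values numeric matrix; row 1 = northernmost row.
#' @param xmin,ymin coordinates of the lower-left corner (degrees).
#' @param cell square cell size in degrees (> 0).
#' @param crs CRS tag (WGS84 assumed throughout).
#' @return object of class `geo_raster`.
#' @export
geo_raster <- function(values, xmin, ymin, cell, crs = "EPSG:4326") {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (cell <= 0) stop("cell size must be positive", call. = FALSE)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cell = cell,
         nrow = nrow(values), ncol = ncol(values), crs = crs),
    class = "geo_raster"
  )
}

#' @export
print.geo_raster <- function(x, ...) {
  cat(sprintf("geo_raster: %d x %d cells of %.5g deg, extent [%.4g, %.4g] x [%.4g, %.4g] (%s)\n",
              x$nrow, x$ncol, x$cell,
              x$xmin, x$xmin + x$ncol * x$cell,
              x$ymin, x$ymin + x$nrow * x$cell, x$crs))
  invisible(x)
}

raster_xmax <- function(r) r$xmin + r$ncol * r$cell
raster_ymax <- function(r) r$ymin + r$nrow * r$cell

#' Cell-centre coordinates of a raster
#'
#' @param r a `geo_raster`.
#' @return list with `x` (west-to-east column centres) and `y`
#'   (north-to-south row centres, matching row order of `values`).
#' @export
raster_centres <- function(r) {
  list(
    x = r$xmin + (seq_len(r$ncol) - 0.5) * r$cell,
    y = raster_ymax(r) - (seq_len(r$nrow) - 0.5) * r$cell
  )
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster interchange format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header followed by rows north to
#' south).
#'
#' @param path file path.
#' @return a `geo_raster` (nodata cells become `NA`).
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  geo_raster(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
             cell = hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param r a `geo_raster`.
#' @param path output path.
#' @param nodata value used for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$ncol),
    sprintf("nrows %d", r$nrow),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cell),
    sprintf("NODATA_value %g", nodata)
  ), con)
  m <- r$values
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Align a raster onto a template grid by nearest neighbour
#'
#' Each template cell takes the value of the source cell whose centre is
#' nearest to the template cell centre (equivalently, the source cell
#' containing that centre); nodata propagates and template cells outside
#' the source extent become `NA`.
#'
#' @param src source `geo_raster`.
#' @param template `geo_raster` defining the output grid.
#' @return `geo_raster` on the template grid.
#' @export
align_raster <- function(src, template) {
  sx_max <- raster_xmax(src); sy_max <- raster_ymax(src)
  tx_max <- raster_xmax(template); ty_max <- raster_ymax(template)
  if (template$xmin >= sx_max || tx_max <= src$xmin ||
      template$ymin >= sy_max || ty_max <= src$ymin) {
    stop("source and template extents are disjoint", call. = FALSE)
  }
  cc <- raster_centres(template)
  col_idx <- floor((cc$x - src$xmin) / src$cell) + 1
  row_idx <- floor((sy_max - cc$y) / src$cell) + 1
  out <- matrix(NA_real_, template$nrow, template$ncol)
  ok_col <- col_idx >= 1 & col_idx <= src$ncol
  ok_row <- row_idx >= 1 & row_idx <= src$nrow
  for (i in which(ok_row)) {
    out[i, ok_col] <- src$values[row_idx[i], col_idx[ok_col]]
  }
  geo_raster(out, xmin = template$xmin, ymin = template$ymin,
             cell = template$cell, crs = template$crs)
}

# metres per degree of latitude (and of longitude at the equator)
.m_per_deg <- 111320

#' Slope in degrees from an elevation raster (Horn's method)
#'
#' 3x3 Horn finite differences on a geographic grid: cell sizes are
#' converted to metres (latitude: 111,320 m per degree; longitude scaled
#' by the cosine of each row's latitude); slope =
#' atan(sqrt(gx^2 + gy^2)) in degrees.  Border cells use a replicated
#' edge.  Translation-invariant: adding a constant to the elevation
#' leaves the slope unchanged.
#'
#' @param elev elevation `geo_raster` in metres.
#' @return slope `geo_raster` in degrees (range 0-90).
#' @export
slope_from_elevation <- function(elev) {
  if (elev$nrow < 3 || elev$ncol < 3) {
    stop("raster must be at least 3 x 3", call. = FALSE)
  }
  z <- elev$values
  nr <- nrow(z); nc <- ncol(z)
  # replicate borders
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  lat <- raster_centres(elev)$y
  dy <- elev$cell * .m_per_deg
  dx <- elev$cell * .m_per_deg * cos(lat * pi / 180)   # per row
  # neighbours (zp index shifted by 1)
  nw <- zp[1:nr, 1:nc];       n_ <- zp[1:nr, 2:(nc + 1)];       ne <- zp[1:nr, 3:(nc + 2)]
  w_ <- zp[2:(nr + 1), 1:nc];                                  e_ <- zp[2:(nr + 1), 3:(nc + 2)]
  sw <- zp[3:(nr + 2), 1:nc]; s_ <- zp[3:(nr + 2), 2:(nc + 1)]; se <- zp[3:(nr + 2), 3:(nc + 2)]
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * matrix(dx, nr, nc))
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * dy)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  geo_raster(slope, xmin = elev$xmin, ymin = elev$ymin, cell = elev$cell,
             crs = elev$crs)
}

#' Reclassify a categorical raster
#'
#' Pure value lookup, e.g., collapsing a detailed land-cover product
#' into six ecological categories (agriculture/cropland, forest/tree
#' cover, grassland/shrubland, wetland/riparian, urban/bare, water).
#'
#' @param src categorical `geo_raster`.
#' @param mapping data frame with columns `from`, `to`; must cover every
#'   class present in `src`.
#' @return reclassified `geo_raster`; nodata preserved.
#' @export
reclassify_lulc <- function(src, mapping) {
  v <- src$values
  present <- sort(unique(v[!is.na(v)]))
  unmapped <- setdiff(present, mapping$from)
  if (length(unmapped) > 0) {
    stop(sprintf("unmapped LULC class code(s): %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  idx <- match(v, mapping$from)
  out <- matrix(mapping$to[idx], nrow(v), ncol(v))
  geo_raster(out, xmin = src$xmin, ymin = src$ymin, cell = src$cell,
             crs = src$crs)
}

#' Extract raster values at point locations
#'
#' A point takes the value of the cell containing it; cell ownership is
#' half-open so a point on a shared edge belongs to the cell to its
#' east/south.  Points outside the extent yield `NA` with a warning.
#'
#' @param r a `geo_raster`.
#' @param lon,lat point coordinates.
#' @return numeric vector of cell values.
#' @export
extract_at_points <- function(r, lon, lat) {
  col_idx <- floor((lon - r$xmin) / r$cell) + 1
  row_idx <- floor((raster_ymax(r) - lat) / r$cell) + 1
  ok <- col_idx >= 1 & col_idx <= r$ncol & row_idx >= 1 & row_idx <= r$nrow
  out <- rep(NA_real_, length(lon))
  out[ok] <- r$values[cbind(row_idx[ok], col_idx[ok])]
  if (any(!ok)) {
    warning(sprintf("%d point(s) outside the raster extent; returned NA",
                    sum(!ok)))
  }
  out
}
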