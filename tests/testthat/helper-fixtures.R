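# Shared fixture builders: everything is generated in code.

# Minimal canonical record table with overridable columns.
make_records <- function(n = 3, ...) {
  ds <- data.frame(
    specimen_id = sprintf("S%03d", seq_len(n)),
    accepted_name = sprintf("Genus sp%02d", seq_len(n)),
    name_status = rep("accepted", n),
    type_status = rep("holotype", n),
    collectors_raw = rep("Torre", n),
    collection_year = rep(1950L, n),
    publication_year = rep(1960L, n),
    province = rep("Maputo", n),
    latitude = seq(-20, -19, length.out = n),
    longitude = seq(34, 35, length.out = n),
    native_status = rep("strict_endemic", n),
    growth_form = rep("tree", n),
    iucn = rep("LC", n),
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) ds[[nm]] <- dots[[nm]]
  ds
}

write_records_csv <- function(ds) {
  path <- tempfile(fileext = ".csv")
  write_specimen_table(ds, path)
  path
}

# axis-aligned rectangle polygon (single ring, closed)
rect_poly <- function(xmin, xmax, ymin, ymax) {
  list(rbind(
    c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax), c(xmin, ymin)
  ))
}

# independent Horn stencil, explicit loops, interior cells only
horn_slope_reference <- function(z, cell, lat_rows) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  dy <- cell * 111320
  for (i in 2:(nr - 1)) {
    dx <- cell * 111320 * cos(lat_rows[i] * pi / 180)
    for (j in 2:(nc - 1)) {
      gx <- ((z[i - 1, j + 1] + 2 * z[i, j + 1] + z[i + 1, j + 1]) -
               (z[i - 1, j - 1] + 2 * z[i, j - 1] + z[i + 1, j - 1])) / (8 * dx)
      gy <- ((z[i - 1, j - 1] + 2 * z[i - 1, j] + z[i - 1, j + 1]) -
               (z[i + 1, j - 1] + 2 * z[i + 1, j] + z[i + 1, j + 1])) / (8 * dy)
      out[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    }
  }
  out
}

# small shared landscape for predictor/GLM tests (built once per run)
tiny_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_landscape(seed = 11, extent = c(33, 36, -20, -16),
                               cell_size = 0.1)
    }
    cache
  }
})
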