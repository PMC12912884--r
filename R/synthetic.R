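# Synthetic landscapes, presence points and collection histories with
# known ground truth, so every pipeline stage is testable offline.

#' Ground truth for the synthetic world
#'
#' Bundles the generative parameters: logistic coefficients for the
#' accessibility/environment model (intercept, elevation per m, slope
#' per degree, land-cover class code, distance to road and harbour per
#' m), the mean collection-to-publication lag in years (gamma, shape 2),
#' the lognormal collector-productivity parameters, and the rate of
#' missing collection years.  The default coefficient signs follow the
#' empirically expected pattern (positive elevation/slope/land-cover
#' effects, negative distance effects); magnitudes are synthetic
#' defaults chosen for a realistic rare-presence regime, not empirical
#' estimates.
#'
#' @param beta_true named numeric vector of generative coefficients.
#' @param lag_mean mean description lag in years (default 18).
#' @param productivity_mu,productivity_sigma lognormal parameters of
#'   per-collector specimen productivity.
#' @param missing_year_rate fraction of records with the collection year
#'   removed.
#' @param seed integer seed; identical truth objects yield bit-identical
#'   outputs.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(beta_true = c(intercept = -3.5,
                                          elevation = 0.0012,
                                          slope = 0.8,
                                          lulc = 0.2,
                                          dist_road = -4e-05,
                                          dist_harbour = -7e-06),
                            lag_mean = 18,
                            productivity_mu = 0,
                            productivity_sigma = 1.5,
                            missing_year_rate = 0.1,
                            seed = 1) {
  structure(list(
    beta_true = beta_true, lag_mean = lag_mean,
    productivity_mu = productivity_mu,
    productivity_sigma = productivity_sigma,
    missing_year_rate = missing_year_rate, seed = seed
  ), class = "synthetic_truth")
}

# bilinear upsampling of a coarse matrix onto nr x nc
.upsample_bilinear <- function(coarse, nr, nc) {
  cr <- nrow(coarse); cc <- ncol(coarse)
  ri <- seq(1, cr, length.out = nr)
  ci <- seq(1, cc, length.out = nc)
  r0 <- pmin(floor(ri), cr - 1); r1 <- r0 + 1; rf <- ri - r0
  c0 <- pmin(floor(ci), cc - 1); c1 <- c0 + 1; cf <- ci - c0
  m00 <- coarse[r0, c0, drop = FALSE]; m01 <- coarse[r0, c1, drop = FALSE]
  m10 <- coarse[r1, c0, drop = FALSE]; m11 <- coarse[r1, c1, drop = FALSE]
  rfm <- matrix(rf, nr, nc); cfm <- matrix(cf, nr, nc, byrow = TRUE)
  m00 * (1 - rfm) * (1 - cfm) + m01 * (1 - rfm) * cfm +
    m10 * rfm * (1 - cfm) + m11 * rfm * cfm
}

.gaussian_bump_field <- function(x, y, n_bumps, amp_range, width_range) {
  cx <- stats::runif(n_bumps, min(x), max(x))
  cy <- stats::runif(n_bumps, min(y), max(y))
  a <- stats::runif(n_bumps, amp_range[1], amp_range[2])
  s <- stats::runif(n_bumps, width_range[1], width_range[2])
  field <- matrix(0, length(y), length(x))
  for (k in seq_len(n_bumps)) {
    field <- field + a[k] *
      outer(exp(-(y - cy[k])^2 / (2 * s[k]^2)),
            exp(-(x - cx[k])^2 / (2 * s[k]^2)))
  }
  field
}

#' Generate a synthetic landscape
#'
#' Builds the raster and vector layers the predictor pipeline consumes:
#' a non-negative elevation raster (seeded Gaussian massifs plus
#' smoothed noise), its Horn slope, a six-class land-cover raster
#' (quantile slicing of a second smoothed field, so classes are close
#' to equifrequent), `n_roads` random polylines crossing the extent and
#' `n_harbours` points on the eastern edge (the coast analogy).
#'
#' @param seed integer seed.
#' @param extent `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param cell_size cell size in degrees (default 0.05, roughly the
#'   2.5-arc-minute resolution of global elevation products).
#' @param n_roads,n_harbours feature counts.
#' @return list with `elevation`, `slope`, `lulc` (`geo_raster`s),
#'   `roads` (list of polyline matrices), `harbours` (matrix), `extent`,
#'   `cell_size`, `seed`.
#' @export
make_landscape <- function(seed = 1, extent = c(32, 38, -24, -14),
                           cell_size = 0.05, n_roads = 8, n_harbours = 5) {
  if (cell_size >= min(extent[2] - extent[1], extent[4] - extent[3])) {
    stop("cell_size must be smaller than the extent span", call. = FALSE)
  }
  set.seed(seed)
  nc <- round((extent[2] - extent[1]) / cell_size)
  nr <- round((extent[4] - extent[3]) / cell_size)
  x <- extent[1] + (seq_len(nc) - 0.5) * cell_size
  y <- extent[4] - (seq_len(nr) - 0.5) * cell_size   # north to south

  bumps <- .gaussian_bump_field(x, y, n_bumps = 12,
                                amp_range = c(150, 900),
                                width_range = c(0.3, 1.5))
  noise <- .upsample_bilinear(matrix(stats::runif(20 * 20, 0, 150), 20, 20),
                              nr, nc)
  elevation <- geo_raster(pmax(bumps + noise - 100, 0),
                          xmin = extent[1], ymin = extent[3], cell = cell_size)

  lulc_field <- .gaussian_bump_field(x, y, n_bumps = 15,
                                     amp_range = c(-1, 1),
                                     width_range = c(0.3, 1.2)) +
    .upsample_bilinear(matrix(stats::rnorm(25 * 25), 25, 25), nr, nc)
  qs <- stats::quantile(lulc_field, probs = seq(0, 1, length.out = 7))
  qs[1] <- -Inf; qs[7] <- Inf
  lulc <- geo_raster(
    matrix(as.integer(cut(lulc_field, qs, labels = FALSE)), nr, nc),
    xmin = extent[1], ymin = extent[3], cell = cell_size
  )

  roads <- lapply(seq_len(n_roads), function(k) {
    vertical <- stats::runif(1) < 0.5
    if (vertical) {
      xs <- stats::runif(2, extent[1], extent[2])
      p0 <- c(xs[1], extent[3]); p1 <- c(xs[2], extent[4])
    } else {
      ys <- stats::runif(2, extent[3], extent[4])
      p0 <- c(extent[1], ys[1]); p1 <- c(extent[2], ys[2])
    }
    tt <- seq(0, 1, length.out = 6)
    mid <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
    jit <- 0.15 * min(extent[2] - extent[1], extent[4] - extent[3])
    mid[2:5, 1] <- mid[2:5, 1] + stats::runif(4, -jit, jit)
    mid[2:5, 2] <- mid[2:5, 2] + stats::runif(4, -jit, jit)
    mid
  })
  harbours <- cbind(lon = rep(extent[2], n_harbours),
                    lat = sort(stats::runif(n_harbours, extent[3], extent[4])))

  list(elevation = elevation, slope = slope_from_elevation(elevation),
       lulc = lulc, roads = roads, harbours = harbours,
       extent = extent, cell_size = cell_size, seed = seed)
}

# Predictor values of the synthetic world at arbitrary points, using the
# same extraction and distance rules as the modelling pipeline.
.landscape_predictors <- function(landscape, lon, lat, spacing = 10000) {
  data.frame(
    lon = lon, lat = lat,
    elevation = extract_at_points(landscape$elevation, lon, lat),
    slope = extract_at_points(landscape$slope, lon, lat),
    lulc_code = extract_at_points(landscape$lulc, lon, lat),
    dist_road = distance_to_nearest(lon, lat, landscape$roads,
                                    spacing = spacing),
    dist_harbour = distance_to_nearest(lon, lat, landscape$harbours)
  )
}

.linear_predictor <- function(pred, beta_true) {
  beta_true[["intercept"]] +
    beta_true[["elevation"]] * pred$elevation +
    beta_true[["slope"]] * pred$slope +
    beta_true[["lulc"]] * pred$lulc_code +
    beta_true[["dist_road"]] * pred$dist_road +
    beta_true[["dist_harbour"]] * pred$dist_harbour
}

#' Simulate presence points from the logistic collection model
#'
#' Rejection sampling: candidate points are drawn uniformly over the
#' landscape extent and accepted with probability
#' inverse-logit(eta(candidate)), where eta is the generative linear
#' predictor; exactly `n` accepted points are returned.  The realised
#' mean acceptance probability is recorded (`attr(., "p_bar")`); under
#' this presence/background design the mean acceptance probability is
#' part of the ground truth, because a logistic fit on presences vs
#' uniform pseudo-absences identifies the intercept only up to
#' `-log(p_bar)`.
#'
#' @param landscape output of [make_landscape()].
#' @param beta_true named generative coefficient vector (see
#'   [synthetic_truth()]).
#' @param n number of presence points.
#' @param seed integer seed.
#' @param spacing road densification spacing in metres; use the same
#'   value when building the model table so generative and fitted
#'   predictors coincide exactly.
#' @return data frame `lon`, `lat` with attributes `p_bar` (mean
#'   acceptance probability over candidates) and `beta_true`.
#' @export
simulate_presences <- function(landscape, beta_true = synthetic_truth()$beta_true,
                               n = 500, seed = 1, spacing = 10000) {
  set.seed(seed)
  ext <- landscape$extent
  acc_lon <- numeric(0); acc_lat <- numeric(0)
  n_cand <- 0L
  p_sum <- 0
  batch <- max(2L * n, 1000L)
  repeat {
    if (n_cand > 0) {
      rate <- max(length(acc_lon) / n_cand, 1e-4)
      batch <- min(500000L, max(2000L,
                                ceiling(1.2 * (n - length(acc_lon)) / rate)))
    }
    lon <- stats::runif(batch, ext[1], ext[2])
    lat <- stats::runif(batch, ext[3], ext[4])
    pred <- .landscape_predictors(landscape, lon, lat, spacing = spacing)
    eta <- .linear_predictor(pred, beta_true)
    p <- stats::plogis(eta)
    u <- stats::runif(batch)
    keep <- u < p
    acc_lon <- c(acc_lon, lon[keep]); acc_lat <- c(acc_lat, lat[keep])
    n_cand <- n_cand + batch
    p_sum <- p_sum + sum(p)
    if (length(acc_lon) >= n) break
    if (n_cand >= 1000L * n && length(acc_lon) / n_cand < 1e-4) {
      stop("acceptance rate below 1e-4; rescale the intercept of beta_true",
           call. = FALSE)
    }
  }
  out <- data.frame(lon = acc_lon[seq_len(n)], lat = acc_lat[seq_len(n)])
  attr(out, "p_bar") <- p_sum / n_cand
  attr(out, "beta_true") <- beta_true
  out
}

.province_names <- c("Cabo Delgado", "Gaza", "Inhambane", "Manica", "Maputo",
                     "Nampula", "Niassa", "Sofala", "Tete", "Zambezia")
# sampling weights echoing the empirical province totals of the
# reference use case (southern/central bias)
.province_weights <- c(19, 7, 12, 34, 50, 31, 12, 40, 14, 39)

.growth_forms_p <- c(annual_or_biennial_herb = 27, perennial_herb = 26,
                     perennial_climbing_herb = 1, shrub_or_subshrub = 44,
                     tree = 25, woody_climber = 3)
.native_status_p <- c(strict_endemic = 44, near_endemic = 18,
                      native_non_endemic = 64)
.iucn_p <- c(CR = 4, EN = 6, VU = 14, NT = 1, LC = 46, DD = 9, NE = 46)

#' Simulate a type-specimen collection history
#'
#' Generates a canonical record table with known ground truth:
#' per-collector productivity is lognormal (heavy-tailed, so a few
#' collectors dominate), activity windows fall uniformly within
#' 1820-2010, provinces are drawn from a 10-unit partition with a
#' south/central bias, each taxon's protologue year is its first
#' collection year plus a gamma-distributed lag (shape 2, scale
#' `lag_mean / 2`), collection years are deleted at
#' `missing_year_rate`, and configurable fractions of taxa/records are
#' marked as synonyms and neotypes to exercise the filters.
#'
#' @param truth a [synthetic_truth()].
#' @param n_collectors number of collectors (>= 1; default 64).
#' @param n_specimens number of specimen records (default 273).
#' @param n_taxa number of taxa specimens are allocated to (default
#'   roughly 60% of specimens).
#' @param synonym_rate fraction of taxa whose name is a synonym.
#' @param neotype_rate fraction of records marked neotype.
#' @param georef_rate fraction of records with coordinates.
#' @param extent bounding box for the simulated coordinates.
#' @return canonical record data frame with attribute `truth`.
#' @export
simulate_collection_history <- function(truth = synthetic_truth(),
                                        n_collectors = 64,
                                        n_specimens = 273,
                                        n_taxa = max(1, round(0.6 * n_specimens)),
                                        synonym_rate = 0.35,
                                        neotype_rate = 0.02,
                                        georef_rate = 0.945,
                                        extent = c(32, 38, -24, -14)) {
  if (n_collectors < 1) stop("n_collectors must be >= 1", call. = FALSE)
  set.seed(truth$seed)
  collectors <- sprintf("Collector %02d", seq_len(n_collectors))
  prod_w <- stats::rlnorm(n_collectors, truth$productivity_mu,
                          truth$productivity_sigma)
  rec_collector <- sample(collectors, n_specimens, replace = TRUE,
                          prob = prod_w)
  # activity windows within 1820-2010
  w1 <- stats::runif(n_collectors, 1820, 2010)
  w2 <- stats::runif(n_collectors, 1820, 2010)
  win <- cbind(pmin(w1, w2), pmax(w1, w2))
  rownames(win) <- collectors
  year <- vapply(rec_collector, function(cn) {
    round(stats::runif(1, win[cn, 1], win[cn, 2]))
  }, numeric(1))

  taxa <- sprintf("Genus species%03d", seq_len(n_taxa))
  taxon_w <- stats::rgamma(n_taxa, shape = 1.2)
  rec_taxon <- sample(taxa, n_specimens, replace = TRUE, prob = taxon_w)
  first_year <- tapply(year, rec_taxon, min)
  lag <- round(stats::rgamma(length(first_year), shape = 2,
                             scale = truth$lag_mean / 2))
  pub_year <- stats::setNames(as.integer(first_year + lag), names(first_year))

  taxon_status <- stats::setNames(
    ifelse(stats::runif(n_taxa) < synonym_rate, "synonym", "accepted"), taxa
  )
  taxon_gf <- stats::setNames(
    sample(names(.growth_forms_p), n_taxa, TRUE, .growth_forms_p), taxa)
  taxon_ns <- stats::setNames(
    sample(names(.native_status_p), n_taxa, TRUE, .native_status_p), taxa)
  taxon_iucn <- stats::setNames(
    sample(names(.iucn_p), n_taxa, TRUE, .iucn_p), taxa)

  # type status: earliest record of each taxon is the holotype
  type_status <- rep("isotype", n_specimens)
  ord <- order(rec_taxon, year)
  is_first <- !duplicated(rec_taxon[ord])
  type_status[ord][is_first] <- "holotype"
  extra <- sample(c("syntype", "paratype", "isotype"), n_specimens, TRUE,
                  prob = c(0.2, 0.2, 0.6))
  type_status[type_status != "holotype"] <- extra[type_status != "holotype"]
  neo <- stats::runif(n_specimens) < neotype_rate
  type_status[neo & type_status != "holotype"] <- "neotype"

  province <- sample(.province_names, n_specimens, TRUE, .province_weights)
  georef <- stats::runif(n_specimens) < georef_rate
  lon <- ifelse(georef, stats::runif(n_specimens, extent[1], extent[2]), NA)
  lat <- ifelse(georef, stats::runif(n_specimens, extent[3], extent[4]), NA)
  year_missing <- stats::runif(n_specimens) < truth$missing_year_rate

  ds <- data.frame(
    specimen_id = sprintf("SYN%04d", seq_len(n_specimens)),
    accepted_name = rec_taxon,
    name_status = unname(taxon_status[rec_taxon]),
    type_status = type_status,
    collectors_raw = rec_collector,
    collection_year = ifelse(year_missing, NA_integer_, as.integer(year)),
    publication_year = unname(pub_year[rec_taxon]),
    province = province,
    latitude = lat,
    longitude = lon,
    native_status = unname(taxon_ns[rec_taxon]),
    growth_form = unname(taxon_gf[rec_taxon]),
    iucn = unname(taxon_iucn[rec_taxon]),
    stringsAsFactors = FALSE
  )
  attr(ds, "truth") <- truth
  attr(ds, "provenance") <- "synthetic"
  ds
}
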