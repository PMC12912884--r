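# End-to-end orchestration: one config, staged outputs, a hashed manifest.

#' Diversity summary of accepted taxa
#'
#' Tabulates distinct accepted taxa by native status, growth form and
#' IUCN category.  Only records whose name is currently accepted enter
#' the summary (synonymised names do not represent distinct biological
#' entities); each taxon is counted once, attributes taken from its
#' first record.  A missing IUCN value is reported as `NE`
#' (not evaluated).  Percentages are relative to the total number of
#' accepted taxa, rounded half away from zero, so each category block
#' sums to 100 up to rounding.
#'
#' @param ds canonical record data frame.
#' @return data frame `category`, `level`, `n`, `pct`, plus attribute
#'   `total_accepted`.
#' @export
diversity_summary <- function(ds) {
  acc <- ds[!is.na(ds$name_status) & ds$name_status == "accepted", ,
            drop = FALSE]
  taxa <- acc[!duplicated(acc$accepted_name), , drop = FALSE]
  total <- nrow(taxa)
  taxa$iucn[is.na(taxa$iucn)] <- "NE"
  block <- function(field, levels) {
    v <- factor(taxa[[field]], levels = levels)
    n <- as.integer(table(v))
    data.frame(category = field, level = levels, n = n,
               pct = round_half_up(100 * n / max(total, 1)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    block("native_status", .native_status_levels),
    block("growth_form", .growth_form_levels),
    block("iucn", .iucn_levels)
  )
  rownames(out) <- NULL
  attr(out, "total_accepted") <- total
  out
}

#' Assemble a pipeline configuration
#'
#' @param records path to the specimen CSV, or a canonical record data
#'   frame.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in every output and used for any
#'   stochastic stage.
#' @param overrides,aliases optional paths or data frames (year
#'   overrides, collector aliases).
#' @param weights [index_weights()] for the collector index.
#' @param min_year earliest year retained in temporal work.
#' @param polygons optional named list: category name ->
#'   GeoJSON path or polygon list, for region assignment.
#' @param landscape optional synthetic landscape (see
#'   [make_landscape()]) or list of layer paths with elements
#'   `elevation`, `lulc` (ASCII grids), `roads`, `harbours` (GeoJSON);
#'   enables the predictor + GLM stages.
#' @param specs candidate model list for [compare_models()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(records, out_dir, seed = 1, overrides = NULL,
                            aliases = NULL, weights = index_weights(),
                            min_year = 1820, polygons = NULL,
                            landscape = NULL, specs = candidate_specs()) {
  if (is.character(records) && !file.exists(records)) {
    stop(sprintf("records file does not exist: %s", records), call. = FALSE)
  }
  structure(list(records = records, out_dir = out_dir, seed = seed,
                 overrides = overrides, aliases = aliases, weights = weights,
                 min_year = min_year, polygons = polygons,
                 landscape = landscape, specs = specs),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.write_stage_csv <- function(df, dir, file) {
  path <- file.path(dir, file)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes validation, the collector index with sensitivity analysis,
#' the temporal series and lags, the diversity summary, the density
#' surface, optional region assignment, and (when a landscape is
#' configured) pseudo-absence sampling, predictor-table construction
#' and AICc model comparison.  Every output is written under
#' `config$out_dir` and listed, with an MD5 content hash, in
#' `manifest.csv`; the resolved configuration is written beside the
#' outputs.  Any stage failure aborts with the stage name; the partial
#' manifest of completed stages is preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data frame.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.csv")
  files <- character(0)
  results <- list()
  flush_manifest <- function() {
    mf <- data.frame(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE)
    utils::write.csv(mf, manifest_path, row.names = FALSE)
    mf
  }
  on.exit(if (length(files) > 0) flush_manifest(), add = TRUE)

  ds <- .stage("records", {
    if (is.character(config$records)) read_specimen_table(config$records)
    else config$records
  })
  overrides <- if (is.character(config$overrides)) {
    read_year_overrides(config$overrides)
  } else config$overrides
  aliases <- if (is.character(config$aliases)) {
    utils::read.csv(config$aliases, stringsAsFactors = FALSE)
  } else config$aliases

  results$validation <- .stage("validate", validate_records(ds))
  files <- c(files, {
    p <- file.path(config$out_dir, "validation.json")
    validation_report_json(results$validation, p)
    p
  })

  results$collectors <- .stage("collectors", {
    m <- collector_metrics(ds, overrides = overrides, aliases = aliases)
    collector_importance(m, config$weights)
  })
  files <- c(files, .write_stage_csv(results$collectors, config$out_dir,
                                     "collectors.csv"))
  results$sensitivity <- .stage("sensitivity", {
    m <- collector_metrics(ds, overrides = overrides, aliases = aliases)
    weight_sensitivity(m, config$weights)
  })
  files <- c(files, {
    p <- file.path(config$out_dir, "sensitivity.json")
    writeLines(jsonlite::toJSON(results$sensitivity, auto_unbox = TRUE,
                                digits = NA), p)
    p
  })

  results$temporal <- .stage("temporal", {
    accumulation_curves(ds, min_year = config$min_year, overrides = overrides)
  })
  files <- c(files, .write_stage_csv(results$temporal, config$out_dir,
                                     "temporal_decades.csv"))
  results$lags <- .stage("lags", {
    time_lags(temporal_subset(ds, overrides = overrides),
              min_year = config$min_year)
  })
  files <- c(files, .write_stage_csv(results$lags$lags, config$out_dir,
                                     "time_lags.csv"))

  results$diversity <- .stage("diversity", diversity_summary(ds))
  files <- c(files, .write_stage_csv(results$diversity, config$out_dir,
                                     "diversity_summary.csv"))

  geo <- filter_georeferenced(ds)
  if (nrow(geo) >= 2) {
    results$density <- .stage("density",
                              kde2d_surface(geo$longitude, geo$latitude))
    files <- c(files, {
      p <- file.path(config$out_dir, "density.asc")
      # surface stored as a north-up grid
      dens <- t(results$density$density)[rev(seq_along(results$density$grid_lat)), ]
      r <- geo_raster(dens,
                      xmin = min(results$density$grid_lon),
                      ymin = min(results$density$grid_lat),
                      cell = mean(diff(results$density$grid_lon)))
      write_asc(r, p)
      p
    })
  }

  if (!is.null(config$polygons)) {
    for (cat in names(config$polygons)) {
      polys <- config$polygons[[cat]]
      if (is.character(polys)) polys <- read_geojson_polygons(polys)
      rc <- .stage(paste0("regions_", cat),
                   assign_regions(geo$longitude, geo$latitude, polys,
                                  category = cat))
      results$regions[[cat]] <- rc
      files <- c(files, .write_stage_csv(rc, config$out_dir,
                                         sprintf("regions_%s.csv", cat)))
    }
  }

  if (!is.null(config$landscape)) {
    ls <- config$landscape
    results$model <- .stage("glm", {
      pres <- data.frame(lon = geo$longitude, lat = geo$latitude)
      abs <- sample_pseudo_absences(pres, seed = config$seed)
      tab <- build_model_table(pres, abs, ls$elevation, ls$slope, ls$lulc,
                               ls$roads, ls$harbours)
      compare_models(tab, config$specs)
    })
    files <- c(files, .write_stage_csv(results$model$table, config$out_dir,
                                       "model_comparison.csv"))
    files <- c(files, {
      p <- file.path(config$out_dir, "fits.json")
      fits <- lapply(results$model$fits, function(f) {
        list(beta = as.list(f$beta), se = as.list(f$se), z = as.list(f$z),
             p = as.list(f$p), loglik = f$loglik, n_obs = f$n_obs, k = f$k,
             aicc = f$aicc, mcfadden_r2 = f$mcfadden_r2, auc = f$auc,
             converged = f$converged, n_iter = f$n_iter)
      })
      writeLines(jsonlite::toJSON(fits, auto_unbox = TRUE, digits = NA), p)
      p
    })
  }

  files <- c(files, {
    p <- file.path(config$out_dir, "config.txt")
    writeLines(c(
      sprintf("seed=%d", config$seed),
      sprintf("min_year=%d", config$min_year),
      sprintf("weights=%s", paste(unclass(config$weights), collapse = ",")),
      sprintf("records=%s",
              if (is.character(config$records)) config$records else "<data frame>")
    ), p)
    p
  })
  manifest <- flush_manifest()
  on.exit(NULL)
  results$manifest <- manifest
  invisible(results)
}
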