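# Published summary counts for the reference use case (Fabaceae type
# specimens from Mozambique) and the arithmetic derived from them.

#' Published per-category counts of accepted Fabaceae type taxa
#'
#' The printed distribution of the accepted type taxa of the reference
#' use case across native status, growth form and IUCN category,
#' shipped as a plain-text fixture.
#'
#' @return data frame `category`, `level`, `n`.
#' @export
reference_type_counts <- function() {
  utils::read.csv(system.file("extdata", "fabaceae_type_counts.csv",
                              package = "typebias"),
                  stringsAsFactors = FALSE)
}

#' Published specimen counts per spatial unit
#'
#' Printed counts of georeferenced type specimens across ecoregions,
#' centres of endemism and important plant areas for the reference use
#' case.
#'
#' @return data frame `category`, `unit_name`, `n`.
#' @export
reference_region_counts <- function() {
  utils::read.csv(system.file("extdata", "fabaceae_region_counts.csv",
                              package = "typebias"),
                  stringsAsFactors = FALSE)
}

#' Summary arithmetic over per-category taxon counts
#'
#' Derives the headline diversity figures from a per-category count
#' table: total accepted taxa (native-status block total), the percent
#' of strict endemics, the percent of taxa with an IUCN evaluation
#' (any category other than not-evaluated), and the percent threatened
#' (CR + EN + VU).  Percentages are rounded half away from zero to
#' integer percent.
#'
#' @param counts data frame `category`, `level`, `n` (default: the
#'   shipped reference counts).
#' @return list `total_accepted`, `pct_strict_endemic`,
#'   `pct_iucn_evaluated`, `pct_threatened`.
#' @export
summary_from_counts <- function(counts = reference_type_counts()) {
  ns <- counts[counts$category == "native_status", ]
  iucn <- counts[counts$category == "iucn", ]
  total <- sum(ns$n)
  strict <- ns$n[ns$level == "strict_endemic"]
  ne <- iucn$n[iucn$level == "NE"]
  threatened <- sum(iucn$n[iucn$level %in% c("CR", "EN", "VU")])
  list(
    total_accepted = total,
    pct_strict_endemic = round_half_up(100 * strict / total),
    pct_iucn_evaluated = round_half_up(100 * (total - ne) / total),
    pct_threatened = round_half_up(100 * threatened / total)
  )
}

#' Total georeferenced specimens implied by a partition's region counts
#'
#' For a spatially exhaustive category (the ecoregion partition), the
#' per-unit counts sum to the georeferenced total.
#'
#' @param counts data frame `category`, `unit_name`, `n`.
#' @param category partition category to sum (default "ecoregion").
#' @return integer total.
#' @export
georeferenced_total_from_regions <- function(counts = reference_region_counts(),
                                             category = "ecoregion") {
  sum(counts$n[counts$category == category])
}

#' Dataset-level reproduction statistics
#'
#' Recomputes, from a full curated specimen table, the headline
#' dataset statistics: records read, georeferenced records, distinct
#' collectors, share of specimens credited to the ten most important
#' collectors, the top collector's specimen count and activity span,
#' the overall mean collection-to-publication lag, and the top province
#' with its specimen count.  Intended for checking a supplied curated
#' dataset against its published summary.
#'
#' @param ds canonical record data frame (from
#'   [read_specimen_table()]).
#' @param overrides optional year-override table.
#' @param aliases optional collector alias table.
#' @return list of statistics.
#' @export
dataset_reproduction_stats <- function(ds, overrides = NULL, aliases = NULL) {
  geo <- filter_georeferenced(ds)
  metrics <- collector_metrics(ds, overrides = overrides, aliases = aliases)
  ranked <- collector_importance(metrics)
  k <- min(10, nrow(ranked))
  top10_share <- sum(ranked$nesp[seq_len(k)]) / nrow(ds)
  top <- ranked[which.max(ranked$nesp), ]
  lag <- time_lags(temporal_subset(ds, overrides = overrides))
  prov <- sort(table(ds$province), decreasing = TRUE)
  yrs <- apply_year_overrides(ds, overrides)
  credited <- vapply(seq_len(nrow(ds)), function(i) {
    top$name %in% canonicalize_collector(
      disaggregate_collectors(ds$collectors_raw[i]), aliases)
  }, logical(1))
  span <- range(yrs[credited], na.rm = TRUE)
  list(
    n_records = nrow(ds),
    n_georeferenced = nrow(geo),
    n_collectors = nrow(metrics),
    top10_share = top10_share,
    top_collector = top$name,
    top_collector_nesp = top$nesp,
    top_collector_first_year = span[1],
    top_collector_last_year = span[2],
    mean_lag = lag$mean_lag,
    top_province = names(prov)[1],
    top_province_n = as.integer(prov[1])
  )
}
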